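#' @keywords internal
#' @useDynLib spinalloop, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

#' Sorted spike event times for one neuron
#'
#' Container for the sorted event times of a single neuron, the trigger
#' source for spike-triggered averages and peri-event histograms.  Times are
#' stored in seconds at 0.1 ms resolution, strictly increasing.
#'
#' @param times numeric vector of event times (s).
#' @param neuron_id character scalar identifying the neuron.
#' @param t_max optional session end time (s); times beyond it are an error.
#' @return An object of class `spike_train`: a numeric vector of times with
#'   attributes `neuron_id`.
#' @export
spike_train <- function(times, neuron_id = "unit1", t_max = NULL) {
  times <- round(as.numeric(times), 4)  # 0.1 ms resolution
  times <- sort(unique(times[is.finite(times)]))
  if (any(times < 0)) stop("spike times must be nonnegative")
  if (!is.null(t_max) && length(times) && max(times) > t_max)
    stop("spike times beyond session bounds")
  structure(times, neuron_id = as.character(neuron_id), class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %s: %d spikes", attr(x, "neuron_id"), length(x)))
  if (length(x)) cat(sprintf(" over [%.2f, %.2f] s", min(x), max(x)))
  cat("\n")
  invisible(x)
}

#' Multichannel sampled EMG recording
#'
#' @param samples numeric matrix, time x channel.
#' @param sample_rate sampling rate (Hz), > 0.
#' @param channel_meta data.frame with columns `muscle`, `role`
#'   (`"extensor"` or `"flexor"`) and logical `target`; one row per channel.
#' @param t0 time (s) of the first sample.
#' @return An `emg_recording` object (list).
#' @export
emg_recording <- function(samples, sample_rate, channel_meta, t0 = 0) {
  samples <- as.matrix(samples)
  if (!is.numeric(sample_rate) || sample_rate <= 0)
    stop("sample_rate must be > 0")
  if (!all(is.finite(samples))) stop("samples must be finite")
  stopifnot(is.data.frame(channel_meta),
            all(c("muscle", "role", "target") %in% names(channel_meta)))
  if (nrow(channel_meta) != ncol(samples))
    stop("channel_meta rows must equal channel count")
  if (!all(channel_meta$role %in% c("extensor", "flexor")))
    stop("channel roles must be 'extensor' or 'flexor'")
  colnames(samples) <- channel_meta$muscle
  structure(list(samples = samples, sample_rate = sample_rate,
                 channel_meta = channel_meta, t0 = t0),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %d channels (%s), %.1f s @ %g Hz\n",
              ncol(x$samples), paste(x$channel_meta$muscle, collapse = ", "),
              nrow(x$samples) / x$sample_rate, x$sample_rate))
  invisible(x)
}

#' Time vector of an EMG recording
#' @param emg an [emg_recording()].
#' @return numeric vector of sample times (s).
#' @export
emg_times <- function(emg) {
  emg$t0 + (seq_len(nrow(emg$samples)) - 1L) / emg$sample_rate
}

#' Extract one EMG channel by muscle name
#' @param emg an [emg_recording()].
#' @param channel muscle name.
#' @return numeric vector of samples.
#' @export
emg_channel <- function(emg, channel) {
  j <- match(channel, emg$channel_meta$muscle)
  if (is.na(j)) stop(sprintf("channel '%s' not found", channel))
  emg$samples[, j]
}

# event columns a trial row carries, in their required temporal order
.trial_events <- c("rest_start", "cue_on", "cue_off", "go", "movement_onset",
                   "hold_start", "release_go", "passive_onset", "reward")

#' Validate a task-trial table
#'
#' Checks the per-trial event-time ordering invariants: present events are
#' strictly increasing in the canonical order, successful trials carry all
#' events, and short-hold error trials carry no reward.
#'
#' @param trials data.frame with columns `trial_id`, `direction`, `outcome`
#'   and the event-time columns (seconds; `NA` for missing events).
#' @return `trials`, invisibly; errors on violation.
#' @export
validate_trials <- function(trials) {
  stopifnot(all(c("trial_id", "direction", "outcome") %in% names(trials)))
  if (!all(trials$direction %in% c("flexion", "extension")))
    stop("direction must be 'flexion' or 'extension'")
  ok_out <- c("success", "no_movement", "wrong_direction", "short_hold")
  if (!all(trials$outcome %in% ok_out)) stop("unknown trial outcome")
  for (i in seq_len(nrow(trials))) {
    ev <- as.numeric(trials[i, .trial_events])
    pres <- ev[!is.na(ev)]
    if (any(diff(pres) <= 0))
      stop(sprintf("trial %s: event times not strictly ordered",
                   trials$trial_id[i]))
    if (trials$outcome[i] == "success" && anyNA(ev))
      stop(sprintf("trial %s: success trial missing events", trials$trial_id[i]))
    if (trials$outcome[i] == "short_hold" && !is.na(trials$reward[i]))
      stop(sprintf("trial %s: short_hold trial has a reward", trials$trial_id[i]))
  }
  invisible(trials)
}

#' Epoch intervals of a trial
#'
#' Returns the half-open `[start, end)` intervals of the named task epochs
#' for one trial row.  Pre-movement epochs are `rest` (initial central hold),
#' `cue` (cue presentation) and `delay` (instructed delay); movement epochs
#' are `active_movement`, `active_hold` and `passive_movement`.
#'
#' @param trial one-row data.frame (a row of a trial table).
#' @return data.frame with columns `epoch`, `start`, `end` (absent epochs
#'   dropped).
#' @export
trial_epochs <- function(trial) {
  e <- function(a, b, nm) {
    if (is.na(a) || is.na(b)) return(NULL)
    data.frame(epoch = nm, start = a, end = b)
  }
  out <- rbind(
    e(trial$rest_start, trial$cue_on, "rest"),
    e(trial$cue_on, trial$cue_off, "cue"),
    e(trial$cue_off, trial$go, "delay"),
    e(trial$movement_onset, trial$hold_start, "active_movement"),
    e(trial$hold_start, trial$release_go, "active_hold"),
    e(trial$passive_onset,
      if (!is.na(trial$reward)) trial$reward - 0.8 else
        if (!is.na(trial$passive_onset)) trial$passive_onset + 0.4 else NA,
      "passive_movement"))
  out
}

#' Assign each time to a trial epoch
#'
#' @param times numeric vector of event times (s).
#' @param trials trial table.
#' @param epochs which epochs to consider.
#' @return data.frame with columns `time`, `trial_id`, `epoch` (`NA` where a
#'   time falls in no requested epoch).
#' @export
assign_epoch <- function(times, trials,
                         epochs = c("rest", "cue", "delay", "active_movement",
                                    "active_hold", "passive_movement")) {
  out <- data.frame(time = times, trial_id = NA_character_,
                    epoch = NA_character_)
  for (i in seq_len(nrow(trials))) {
    ep <- trial_epochs(trials[i, ])
    ep <- ep[ep$epoch %in% epochs, , drop = FALSE]
    for (j in seq_len(nrow(ep))) {
      hit <- times >= ep$start[j] & times < ep$end[j]
      out$trial_id[hit] <- trials$trial_id[i]
      out$epoch[hit] <- ep$epoch[j]
    }
  }
  out
}
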