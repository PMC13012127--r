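# Stimulus-evoked response analysis: peristimulus time histograms,
# volley-referenced central latency and the monosynaptic criterion,
# per-epoch response probability and evoked peak area (the neuron's
# input-output gain), and per-trial higher/lower-gain labeling.

#' Peristimulus time histogram
#'
#' Bins spike times relative to each stimulus and normalizes per stimulus,
#' so a bin value is the probability of a spike in that bin per stimulus.
#' Baseline statistics come from the pre-stimulus bins.
#'
#' @param spikes a [spike_train()] (or numeric times, s).
#' @param stim_times stimulus times (s); at least 10.
#' @param bin_ms bin width (ms).
#' @param range_ms window around the stimulus (ms).
#' @return Object of class `psth`: `bin_edges_ms`, `counts` (probability per
#'   stimulus per bin), `density` (probability per ms), `n_stimuli`,
#'   `baseline_mean`, `baseline_sd`, `onset_ms` (`NA` when no onset),
#'   `offset_ms`, `bin_ms`.
#' @export
compute_psth <- function(spikes, stim_times, bin_ms = 0.2,
                         range_ms = c(-10, 10)) {
  if (!length(stim_times)) stop("empty stimulus list")
  if (length(stim_times) < 10) stop("need at least 10 stimuli")
  st <- as.numeric(spikes)
  edges <- seq(range_ms[1], range_ms[2], by = bin_ms)
  rel <- unlist(lapply(stim_times, function(s) {
    d <- (st - s) * 1000
    d[d >= range_ms[1] & d < range_ms[2]]
  }))
  counts <- if (length(rel))
    as.numeric(table(cut(rel, edges, right = FALSE, include.lowest = FALSE)))
  else rep(0, length(edges) - 1L)
  counts <- counts / length(stim_times)
  pre <- edges[-length(edges)] < 0
  bm <- mean(counts[pre]); bs <- stats::sd(counts[pre])
  # onset: first post-stimulus bin above baseline + 2 SD, two consecutive
  post <- which(edges[-length(edges)] >= 0)
  above <- counts[post] > bm + 2 * bs
  i_on <- .first_run(above, 2L)
  onset <- if (is.na(i_on)) NA_real_ else edges[post[i_on]]
  offset <- NA_real_
  if (!is.na(i_on)) {
    below <- !above
    below[seq_len(i_on)] <- FALSE
    i_off <- .first_run(below, 2L)
    offset <- if (is.na(i_off)) range_ms[2] else edges[post[i_off]]
  }
  structure(list(bin_edges_ms = edges, counts = counts,
                 density = counts / bin_ms, n_stimuli = length(stim_times),
                 baseline_mean = bm, baseline_sd = bs,
                 onset_ms = onset, offset_ms = offset, bin_ms = bin_ms),
            class = "psth")
}

#' @export
print.psth <- function(x, ...) {
  cat(sprintf("<psth> %d stimuli, bin %.2g ms, onset %s\n", x$n_stimuli,
              x$bin_ms,
              if (is.na(x$onset_ms)) "none" else sprintf("%.2f ms", x$onset_ms)))
  invisible(x)
}

#' Central latency and the monosynaptic criterion
#'
#' The central latency is the PSTH response onset minus the afferent volley
#' arrival; a latency below `criterion_ms` marks a putative monosynaptic
#' linkage.
#'
#' @param psth a `psth` from [compute_psth()].
#' @param volley_ms volley arrival (ms after the stimulus).
#' @param criterion_ms monosynaptic criterion (ms).
#' @return list with `central_latency_ms` (`NA` when no onset) and
#'   `monosynaptic` (FALSE when no onset).
#' @export
central_latency <- function(psth, volley_ms, criterion_ms = 1.5) {
  if (is.na(psth$onset_ms))
    return(list(central_latency_ms = NA_real_, monosynaptic = FALSE))
  lat <- psth$onset_ms - volley_ms
  list(central_latency_ms = lat, monosynaptic = lat < criterion_ms)
}

# TRUE for each stimulus followed by >= 1 spike within (0, window_ms]
.stim_responded <- function(spikes, stim_times, window_ms = 5) {
  st <- as.numeric(spikes)
  vapply(stim_times, function(s)
    any(st > s & st <= s + window_ms / 1000), logical(1))
}

#' Per-epoch stimulus response probability
#'
#' Fraction of stimuli in each task epoch followed by at least one spike
#' within `(0, window_ms]` of the stimulus.
#'
#' @param spikes a [spike_train()].
#' @param stims data.frame with columns `time` and `epoch`.
#' @param window_ms response window (ms).
#' @param epochs epochs reported.
#' @return data.frame with `epoch`, `n_stim`, `probability` (`NA`, not 0,
#'   for an epoch with no stimuli).
#' @export
response_probability <- function(spikes, stims, window_ms = 5,
                                 epochs = c("rest", "cue", "delay")) {
  resp <- .stim_responded(spikes, stims$time, window_ms)
  out <- data.frame(epoch = epochs, n_stim = 0L, probability = NA_real_)
  for (i in seq_along(epochs)) {
    sel <- !is.na(stims$epoch) & stims$epoch == epochs[i]
    out$n_stim[i] <- sum(sel)
    if (any(sel)) out$probability[i] <- mean(resp[sel])
  }
  out
}

#' Evoked peak area per task epoch
#'
#' The onset and offset of the mean evoked response are taken from the
#' pooled (all-epoch) PSTH, and the baseline-subtracted response area
#' between them is computed separately for the stimuli of each epoch.  The
#' area (probability x ms integrated as density) is the neuron's
#' input-output gain in that epoch.
#'
#' @param spikes a [spike_train()].
#' @param stims data.frame with `time` and `epoch`.
#' @param bin_ms,range_ms PSTH parameters.
#' @param epochs epochs reported.
#' @return list with `onset_ms`, `offset_ms` (pooled) and data.frame
#'   `areas` (`epoch`, `n_stim`, `peak_area`).  Errors when the pooled
#'   response has no onset.
#' @export
evoked_peak_area <- function(spikes, stims, bin_ms = 0.2,
                             range_ms = c(-10, 10),
                             epochs = c("rest", "cue", "delay")) {
  pooled <- compute_psth(spikes, stims$time, bin_ms, range_ms)
  if (is.na(pooled$onset_ms))
    stop("pooled evoked response has no detectable onset")
  on <- pooled$onset_ms; off <- pooled$offset_ms
  area_of <- function(p) {
    ctr <- p$bin_edges_ms[-length(p$bin_edges_ms)]
    sel <- ctr >= on & ctr < off
    sum((p$density[sel] - p$baseline_mean / p$bin_ms) * p$bin_ms)
  }
  out <- data.frame(epoch = epochs, n_stim = 0L, peak_area = NA_real_)
  for (i in seq_along(epochs)) {
    sel <- !is.na(stims$epoch) & stims$epoch == epochs[i]
    out$n_stim[i] <- sum(sel)
    if (sum(sel) >= 10)
      out$peak_area[i] <- area_of(
        compute_psth(spikes, stims$time[sel], bin_ms, range_ms))
  }
  list(onset_ms = on, offset_ms = off, areas = out)
}

#' Label trials as higher- or lower-gain
#'
#' A trial is "higher-gain" when at least one nerve stimulus delivered in
#' its pre-movement epochs (rest, cue, delay) evokes a spike within
#' `(0, window_ms]`; "lower-gain" when none does; excluded (`NA`) when the
#' trial received no qualifying stimulus.
#'
#' @param trials trial table.
#' @param stims data.frame with `time`, `trial_id`, `epoch`.
#' @param spikes a [spike_train()].
#' @param window_ms response window (ms).
#' @return data.frame with `trial_id`, `n_stim`, `n_responded`, `label`
#'   (`"higher"`, `"lower"`, or `NA` for excluded trials).
#' @export
label_trial_gain <- function(trials, stims, spikes, window_ms = 5) {
  pre <- !is.na(stims$epoch) & stims$epoch %in% c("rest", "cue", "delay")
  resp <- .stim_responded(spikes, stims$time, window_ms)
  out <- data.frame(trial_id = trials$trial_id, n_stim = 0L,
                    n_responded = 0L, label = NA_character_)
  for (i in seq_len(nrow(out))) {
    sel <- pre & stims$trial_id == out$trial_id[i]
    out$n_stim[i] <- sum(sel)
    if (!any(sel)) next
    out$n_responded[i] <- sum(resp[sel])
    out$label[i] <- if (out$n_responded[i] > 0) "higher" else "lower"
  }
  out
}
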