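# Synthetic sessions: motor-unit shot-noise EMG modulated by task epochs, an
# interneuron driven by delayed feedback from its target muscle plus a
# descending envelope, a postspike-facilitation kernel injected into the
# target channel, and nerve-stimulation events whose per-trial response
# probability ("gain") covaries with the prospective EMG burst.

#' Default configuration for a synthetic session
#'
#' All generating parameters of [generate_session()] with defaults that match
#' the task structure under study: 0.8 s central hold (rest), 0.2--0.5 s cue,
#' 1 s instructed delay, movement within 1.5 s of the go cue, 1.5 s active
#' hold, passive return, reward.  Short-hold error trials truncate the hold
#' uniformly at 20--60% of its 1.5 s span and carry no reward.
#'
#' @param n_trials data.frame with columns `direction`, `outcome`, `n`.
#' @param muscles data.frame with columns `muscle`, `role`, `target`.
#' @param sample_rate EMG sampling rate (Hz).
#' @param baseline_rate,burst_rate motor-unit event rates (events/s) at rest
#'   and during the agonist burst.
#' @param noise_sd additive Gaussian noise SD (EMG units; MUAP peak is 1).
#' @param muap_width_ms biphasic motor-unit waveform width (ms).
#' @param psf postspike-facilitation kernel injected into the target channel:
#'   list with `amplitude` (EMG units), `onset_ms`, `width_ms` (PWHM).
#' @param feedback_gain interneuron drive (Hz) per unit of target-muscle rate
#'   envelope (events/s); `feedback_delay_ms` its latency.
#' @param feedback_delay_ms latency (ms) of the muscle-to-interneuron drive.
#' @param descending list with `rest_rate` (Hz, tonic) and `delay_boost`
#'   (Hz added during the instructed delay).
#' @param stim nerve-stimulation settings: `n_per_trial` stimuli spread over
#'   the rest/cue/delay epochs, per-trial response probability `gain` (scalar
#'   in \[0,1\]), `response_latency_ms` (< 5), `volley_ms` (volley lag after
#'   the stimulus), `intensity` (multiple of volley threshold, in
#'   \[1, 1.2\]), `nerve`.
#' @param coupling higher- vs lower-gain trial coupling: the target-muscle
#'   burst amplitude and duration multipliers are drawn from
#'   `N(1 + amp_shift, sd)` / `N(1 + dur_shift, sd)` on higher-gain trials and
#'   `N(1, sd)` otherwise.
#' @param trial_jitter independent per-trial, per-muscle burst variability:
#'   log-normal amplitude factor (`amp_sd`), Gaussian onset shift
#'   (`onset_sd_s`, s), log-normal duration factor (`dur_sd`).  This is what
#'   keeps synergist envelopes from being collinear across trials.
#' @param burst_shape phasic-tonic burst profile: the burst rate starts at
#'   `(1 + phasic_frac)` times the tonic level and decays to it with time
#'   constant `tau_s` (s), like real agonist EMG; the nominal burst spans
#'   `dur_frac` of the movement-to-release interval (hold EMG decays before
#'   the release cue), so duration multipliers stay below the offset-search
#'   bound.
#' @param cue_range,rt_range uniform ranges (s) for cue duration and reaction
#'   time.
#' @param rest_s,delay_s,movement_s,hold_s,intertrial_s epoch durations (s).
#' @param short_hold_frac uniform range of the retained fraction of the hold
#'   on short-hold error trials.
#' @param burst_lead_s EMG burst onset lead before movement onset (s).
#' @param torque_plateau,torque_tau torque step plateau (N m) and the time
#'   constant (s) of its critically damped second-order rise.
#' @param base_duration_s session duration (s) when there are no trials.
#' @return A named list of class `session_config`.
#' @export
session_config <- function(
    n_trials = data.frame(direction = c("extension", "flexion"),
                          outcome = "success", n = c(20L, 20L)),
    muscles = data.frame(
      muscle = c("ECU", "ECR", "EDC", "FCR"),
      role = c("extensor", "extensor", "extensor", "flexor"),
      target = c(TRUE, FALSE, FALSE, FALSE)),
    sample_rate = 2000,
    baseline_rate = 20, burst_rate = 150, noise_sd = 0.1,
    muap_width_ms = 3,
    psf = list(amplitude = 0.15, onset_ms = 6, width_ms = 4),
    feedback_gain = 0.2, feedback_delay_ms = 10,
    descending = list(rest_rate = 5, delay_boost = 5),
    stim = list(n_per_trial = 3L, gain = 0.3, response_latency_ms = 1.7,
                volley_ms = 0.7, intensity = 1.1, nerve = "DR"),
    coupling = list(amp_shift = 0.2, dur_shift = 0.2, sd = 0.05),
    trial_jitter = list(amp_sd = 0.06, onset_sd_s = 0.035, dur_sd = 0.06),
    burst_shape = list(phasic_frac = 1.2, tau_s = 0.25, dur_frac = 0.75),
    cue_range = c(0.2, 0.5), rt_range = c(0.2, 0.35),
    rest_s = 0.8, delay_s = 1.0, movement_s = 0.3, hold_s = 1.5,
    intertrial_s = 0.5, short_hold_frac = c(0.2, 0.6),
    burst_lead_s = 0.08,
    torque_plateau = 0.2, torque_tau = 0.08,
    base_duration_s = 10) {
  cfg <- as.list(environment())
  class(cfg) <- "session_config"
  .validate_config(cfg)
  cfg
}

.validate_config <- function(cfg) {
  chk <- function(ok, name, why)
    if (!ok) stop(sprintf("invalid config parameter '%s': %s", name, why),
                  call. = FALSE)
  chk(all(cfg$n_trials$n >= 0), "n_trials", "counts must be nonnegative")
  chk(cfg$sample_rate > 0, "sample_rate", "must be > 0")
  chk(cfg$baseline_rate >= 0, "baseline_rate", "must be nonnegative")
  chk(cfg$burst_rate >= 0, "burst_rate", "must be nonnegative")
  chk(cfg$noise_sd >= 0, "noise_sd", "must be nonnegative")
  chk(all(unlist(cfg$trial_jitter) >= 0), "trial_jitter",
      "jitter scales must be nonnegative")
  chk(cfg$psf$onset_ms > 0, "psf$onset_ms", "must be > 0")
  chk(cfg$psf$width_ms > 0, "psf$width_ms", "must be > 0")
  g <- cfg$stim$gain
  chk(all(g >= 0 & g <= 1), "stim$gain", "must lie in [0, 1]")
  chk(cfg$stim$response_latency_ms < 5, "stim$response_latency_ms",
      "must be < 5 ms (the response-labeling window)")
  chk(cfg$stim$response_latency_ms > 0, "stim$response_latency_ms",
      "must be > 0")
  chk(cfg$feedback_gain >= 0, "feedback_gain", "must be nonnegative")
  chk(cfg$feedback_delay_ms >= 0, "feedback_delay_ms", "must be nonnegative")
  chk(cfg$descending$rest_rate >= 0, "descending$rest_rate",
      "must be nonnegative")
  chk(sum(cfg$muscles$target) <= 1, "muscles", "at most one target channel")
  invisible(cfg)
}

#' Biphasic motor-unit action potential waveform
#'
#' One-cycle biphasic waveform (Gaussian derivative) of the given width,
#' peak-normalized to 1.
#'
#' @param sample_rate Hz.
#' @param width_ms total waveform width (ms).
#' @return numeric vector (odd length, centered).
#' @export
muap_waveform <- function(sample_rate, width_ms = 3) {
  half <- max(1L, round(width_ms / 2 * sample_rate / 1000))
  t <- (-half):half / sample_rate * 1000          # ms
  s <- width_ms / 6
  w <- -t / s^2 * exp(-t^2 / (2 * s^2))
  w / max(abs(w))
}

#' Synthesize one EMG channel as motor-unit shot noise
#'
#' Draws inhomogeneous-Poisson motor-unit event counts per sample
#' (`rpois(rate * dt)`), convolves them with a biphasic waveform, and adds
#' Gaussian noise.  The mean rectified amplitude increases with the rate.
#'
#' @param rate_envelope per-sample event rate (events/s), nonnegative.
#' @param muap_shape waveform placed at each event (centered); see
#'   [muap_waveform()].
#' @param sample_rate Hz.
#' @param seed integer seed (`NULL` to use the current RNG state).
#' @param noise_sd additive Gaussian noise SD.
#' @return numeric vector the length of `rate_envelope`, with attribute
#'   `n_events` (total motor-unit events drawn).
#' @export
synthesize_muap_train <- function(rate_envelope, muap_shape, sample_rate,
                                  seed = NULL, noise_sd = 0) {
  if (any(rate_envelope < 0))
    stop("rate_envelope must be nonnegative everywhere")
  if (!all(is.finite(muap_shape))) stop("muap_shape must be finite")
  if (!is.null(seed)) set.seed(seed)
  n <- length(rate_envelope)
  counts <- stats::rpois(n, rate_envelope / sample_rate)
  x <- .place_waveform(counts, muap_shape, centered = TRUE)
  if (noise_sd > 0) x <- x + stats::rnorm(n, 0, noise_sd)
  attr(x, "n_events") <- sum(counts)
  x
}

# open linear convolution via FFT, padded to a highly composite length so
# the transform never lands on a near-prime size
.conv_open <- function(x, y) {
  n <- length(x); m <- length(y)
  N <- stats::nextn(n + m - 1L, c(2, 3, 5))
  fx <- stats::fft(c(x, numeric(N - n)))
  fy <- stats::fft(c(y, numeric(N - m)))
  Re(stats::fft(fx * fy, inverse = TRUE))[seq_len(n + m - 1L)] / N
}

# convolve an impulse/count train with a waveform; centered alignment places
# the waveform midpoint at the impulse sample
.place_waveform <- function(counts, shape, centered = TRUE) {
  n <- length(counts)
  m <- length(shape)
  full <- .conv_open(as.numeric(counts), as.numeric(shape))
  off <- if (centered) (m - 1L) %/% 2L else 0L
  full[seq_len(n) + off]
}

#' Sampled postspike-facilitation kernel waveform
#'
#' Raised-cosine bump of peak amplitude `amplitude`, starting `onset_ms`
#' after the spike, with peak width at half-maximum `width_ms` (full base
#' width `2 * width_ms`).
#'
#' @param kernel list with `amplitude`, `onset_ms`, `width_ms`.
#' @param sample_rate Hz.
#' @return numeric vector covering lags `[0, onset_ms + 2 * width_ms]`.
#' @export
psf_waveform <- function(kernel, sample_rate) {
  on_n <- round(kernel$onset_ms * sample_rate / 1000)
  w_n <- max(2L, round(2 * kernel$width_ms * sample_rate / 1000))
  bump <- kernel$amplitude * 0.5 * (1 - cos(2 * pi * seq_len(w_n - 1) / w_n))
  c(rep(0, on_n), bump)
}

#' Inject a postspike-facilitation kernel into one EMG channel
#'
#' Adds the kernel waveform to the named channel starting `onset_ms` after
#' each spike; other channels are untouched.
#'
#' @param emg an [emg_recording()].
#' @param spikes a [spike_train()].
#' @param channel muscle name of the channel to modify.
#' @param kernel list with `amplitude` (EMG units), `onset_ms`, `width_ms`.
#' @return A modified [emg_recording()].
#' @export
apply_postspike_kernel <- function(emg, spikes, channel, kernel) {
  j <- match(channel, emg$channel_meta$muscle)
  if (is.na(j)) stop(sprintf("channel '%s' not found", channel))
  if (kernel$amplitude == 0 || length(spikes) == 0) return(emg)
  n <- nrow(emg$samples)
  idx <- round((as.numeric(spikes) - emg$t0) * emg$sample_rate) + 1L
  idx <- idx[idx >= 1L & idx <= n]
  imp <- numeric(n)
  tb <- table(idx)
  imp[as.integer(names(tb))] <- as.numeric(tb)
  wav <- psf_waveform(kernel, emg$sample_rate)
  emg$samples[, j] <- emg$samples[, j] + .place_waveform(imp, wav,
                                                         centered = FALSE)
  emg
}

#' Draw interneuron spikes from descending drive plus delayed muscle feedback
#'
#' Spikes are drawn by thinning from the intensity
#' `lambda(t) = descending(t) + feedback_gain * envelope(t - delay)`.
#'
#' @param envelope per-sample activity envelope of the feedback source
#'   (e.g. the target muscle's motor-unit rate), nonnegative.
#' @param feedback_gain nonnegative scalar (Hz of interneuron drive per
#'   envelope unit).
#' @param feedback_delay_ms feedback latency (ms), >= 0.
#' @param descending per-sample descending rate (Hz), nonnegative; recycled
#'   if scalar.
#' @param sample_rate Hz.
#' @param seed integer seed (`NULL` to use the current RNG state).
#' @param t0 time of the first envelope sample (s).
#' @param neuron_id label for the returned train.
#' @return A [spike_train()].
#' @export
drive_agin <- function(envelope, feedback_gain, feedback_delay_ms,
                       descending, sample_rate, seed = NULL, t0 = 0,
                       neuron_id = "agIN") {
  if (feedback_gain < 0) stop("feedback_gain must be nonnegative")
  if (feedback_delay_ms < 0) stop("feedback_delay_ms must be nonnegative")
  if (any(envelope < 0) || any(descending < 0))
    stop("envelopes must be nonnegative")
  if (!is.null(seed)) set.seed(seed)
  n <- length(envelope)
  d <- round(feedback_delay_ms * sample_rate / 1000)
  fb <- c(rep(0, d), envelope)[seq_len(n)]
  lam <- rep_len(descending, n) + feedback_gain * fb
  lam_max <- max(lam)
  if (lam_max <= 0) return(spike_train(numeric(0), neuron_id))
  dur <- n / sample_rate
  n_cand <- stats::rpois(1, lam_max * dur)
  cand <- sort(stats::runif(n_cand, 0, dur))
  lam_at <- lam[pmin(n, floor(cand * sample_rate) + 1L)]
  keep <- stats::runif(n_cand) < lam_at / lam_max
  spike_train(t0 + cand[keep], neuron_id)
}

#' Stimulus-evoked interneuron spikes
#'
#' Each stimulus independently evokes one spike at
#' `time + response_latency_ms` with probability equal to its trial's gain.
#'
#' @param stims data.frame with columns `time` and `trial_id`.
#' @param per_trial_gain named numeric vector of response probabilities in
#'   \[0,1\], names matching `trial_id` (or a scalar).
#' @param response_latency_ms evoked-spike latency (ms), must be < 5.
#' @param seed integer seed (`NULL` to use the current RNG state).
#' @return data.frame `stims` with added columns `evoked` (logical) and
#'   `spike_time` (`NA` when not evoked).
#' @export
generate_stim_responses <- function(stims, per_trial_gain,
                                    response_latency_ms, seed = NULL) {
  if (response_latency_ms >= 5)
    stop("response_latency_ms must be < 5 ms (the labeling window)")
  if (any(per_trial_gain < 0 | per_trial_gain > 1))
    stop("per_trial_gain must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  g <- if (length(per_trial_gain) == 1) rep(per_trial_gain, nrow(stims))
       else unname(per_trial_gain[as.character(stims$trial_id)])
  stims$evoked <- stats::runif(nrow(stims)) < g
  stims$spike_time <- ifelse(stims$evoked,
                             stims$time + response_latency_ms / 1000, NA_real_)
  stims
}

# critically damped second-order unit step response
.step2 <- function(t, tau) {
  r <- numeric(length(t))
  p <- which(t > 0)
  tp <- t[p] / tau
  r[p] <- 1 - (1 + tp) * exp(-tp)
  r
}

#' Generate a seeded synthetic session
#'
#' Builds a mutually time-consistent set of task trials, multichannel EMG,
#' interneuron spike train, and nerve-stimulation events, and records every
#' generating parameter (including the per-trial higher/lower-gain labels and
#' burst multipliers) as ground truth.  Identical `(config, seed)` yield
#' bit-identical sessions.
#'
#' @param config a [session_config()].
#' @param seed integer seed.
#' @return An object of class `ag_session`: list with elements `trials`,
#'   `emg` ([emg_recording()]), `spikes` (list of [spike_train()]), `stims`,
#'   `torque`, `ground_truth`, `duration`, `config`.
#' @export
generate_session <- function(config = session_config(), seed = 1) {
  .validate_config(config)
  set.seed(seed)
  cfg <- config
  fs <- cfg$sample_rate

  ## ---- trials ----
  tdef <- cfg$n_trials[cfg$n_trials$n > 0, , drop = FALSE]
  rows <- list(); t_cur <- 0.25; k <- 0
  for (i in seq_len(nrow(tdef))) for (r in seq_len(tdef$n[i])) {
    k <- k + 1
    dirn <- tdef$direction[i]; outc <- tdef$outcome[i]
    rest_start <- t_cur
    cue_on <- rest_start + cfg$rest_s
    cue_off <- cue_on + stats::runif(1, cfg$cue_range[1], cfg$cue_range[2])
    go <- cue_off + cfg$delay_s
    mo <- hs <- rg <- po <- rw <- hold_end <- NA_real_
    if (outc == "no_movement") {
      t_end <- go + 0.35
    } else {
      mo <- go + stats::runif(1, cfg$rt_range[1], cfg$rt_range[2])
      hs <- mo + cfg$movement_s
      if (outc == "success") {
        rg <- hs + cfg$hold_s
        po <- rg + 0.2
        rw <- po + 0.4 + 0.8
        hold_end <- rg
        t_end <- rw + 0.2
      } else if (outc == "short_hold") {
        hold_end <- hs + cfg$hold_s *
          stats::runif(1, cfg$short_hold_frac[1], cfg$short_hold_frac[2])
        t_end <- hold_end + 0.6
      } else {  # wrong_direction
        hold_end <- hs
        t_end <- hs + 0.5
      }
    }
    rows[[k]] <- data.frame(
      trial_id = sprintf("t%03d", k), direction = dirn, outcome = outc,
      rest_start = rest_start, cue_on = cue_on, cue_off = cue_off, go = go,
      movement_onset = mo, hold_start = hs, release_go = rg,
      passive_onset = po, reward = rw, hold_end = hold_end, t_end = t_end)
    t_cur <- t_end + cfg$intertrial_s
  }
  trials <- if (k > 0) do.call(rbind, rows) else
    data.frame(trial_id = character(0), direction = character(0),
               outcome = character(0), rest_start = numeric(0),
               cue_on = numeric(0), cue_off = numeric(0), go = numeric(0),
               movement_onset = numeric(0), hold_start = numeric(0),
               release_go = numeric(0), passive_onset = numeric(0),
               reward = numeric(0), hold_end = numeric(0), t_end = numeric(0))
  duration <- if (k > 0) max(trials$t_end) + 0.5 else cfg$base_duration_s
  n_samp <- round(duration * fs)
  tt <- (seq_len(n_samp) - 1) / fs
  validate_trials(trials)

  ## ---- stimulation events and evoked responses (drawn before envelopes so
  ##      the higher/lower-gain label can shape the burst) ----
  stims <- NULL
  if (k > 0 && cfg$stim$n_per_trial > 0) {
    st <- list()
    for (i in seq_len(k)) {
      lo <- trials$rest_start[i] + 0.05
      hi <- trials$go[i] - 0.01
      st[[i]] <- data.frame(
        time = sort(stats::runif(cfg$stim$n_per_trial, lo, hi)),
        trial_id = trials$trial_id[i])
    }
    stims <- do.call(rbind, st)
    stims$nerve_id <- cfg$stim$nerve
    stims$intensity <- cfg$stim$intensity
    stims$volley_time <- stims$time + cfg$stim$volley_ms / 1000
    ep <- assign_epoch(stims$time, trials, c("rest", "cue", "delay"))
    stims$epoch <- ep$epoch
    gains <- rep(cfg$stim$gain, length.out = k)
    names(gains) <- trials$trial_id
    stims <- generate_stim_responses(stims, gains,
                                     cfg$stim$response_latency_ms)
  } else {
    stims <- data.frame(time = numeric(0), trial_id = character(0),
                        nerve_id = character(0), intensity = numeric(0),
                        volley_time = numeric(0), epoch = character(0),
                        evoked = logical(0), spike_time = numeric(0))
    gains <- stats::setNames(rep(cfg$stim$gain, length.out = k),
                             trials$trial_id)
  }
  lab <- tapply(stims$evoked, stims$trial_id, any)
  trials$true_label <- ifelse(trials$trial_id %in% names(lab)[unlist(lab)],
                              "higher", "lower")
  if (nrow(stims) == 0) trials$true_label <- rep(NA_character_, k)

  ## ---- per-trial burst multipliers (coupled to the true label) ----
  mult_amp <- mult_dur <- rep(1, k)
  if (k > 0) {
    hi <- !is.na(trials$true_label) & trials$true_label == "higher"
    mult_amp <- stats::rnorm(k, 1 + ifelse(hi, cfg$coupling$amp_shift, 0),
                             cfg$coupling$sd)
    mult_dur <- stats::rnorm(k, 1 + ifelse(hi, cfg$coupling$dur_shift, 0),
                             cfg$coupling$sd)
    mult_amp <- pmax(0.2, mult_amp); mult_dur <- pmax(0.2, mult_dur)
  }
  trials$amp_mult <- mult_amp; trials$dur_mult <- mult_dur

  ## ---- rate envelopes and EMG channels ----
  nm <- nrow(cfg$muscles)
  env <- matrix(cfg$baseline_rate, n_samp, nm)
  colnames(env) <- cfg$muscles$muscle
  target_j <- which(cfg$muscles$target)
  for (i in seq_len(k)) {
    if (is.na(trials$movement_onset[i])) next
    agonist <- trials$direction[i]
    if (trials$outcome[i] == "wrong_direction")
      agonist <- setdiff(c("flexion", "extension"), agonist)
    role <- if (agonist == "extension") "extensor" else "flexor"
    for (j in which(cfg$muscles$role == role)) {
      jit <- cfg$trial_jitter
      # burst multipliers act on the rectified-EMG *amplitude* scale; the
      # rectified amplitude of shot-noise EMG grows as the square root of
      # the motor-unit rate, so the rate carries the squared factor
      fac <- exp(stats::rnorm(1, 0, jit$amp_sd))
      b0 <- trials$movement_onset[i] - cfg$burst_lead_s +
        stats::rnorm(1, 0, jit$onset_sd_s)
      dur_b <- (trials$hold_end[i] - trials$movement_onset[i]) *
        cfg$burst_shape$dur_frac * exp(stats::rnorm(1, 0, jit$dur_sd))
      if (length(target_j) && j == target_j) {
        fac <- fac * trials$amp_mult[i]
        dur_b <- dur_b * trials$dur_mult[i]
      }
      b1 <- trials$movement_onset[i] + dur_b
      i0 <- max(1L, floor(b0 * fs) + 1L)
      i1 <- min(n_samp, floor(b1 * fs))
      if (i1 > i0) {
        u <- (seq.int(i0, i1) - i0) / fs
        shape <- 1 + cfg$burst_shape$phasic_frac *
          exp(-u / cfg$burst_shape$tau_s)
        env[i0:i1, j] <- cfg$burst_rate * (fac * shape)^2
      }
    }
  }
  # soften burst edges (30 ms raised-cosine) so envelopes are physiological
  edge <- max(3L, round(0.03 * fs))
  win <- 0.5 * (1 - cos(2 * pi * seq_len(edge) / (edge + 1)))
  win <- win / sum(win)
  for (j in seq_len(nm)) env[, j] <- .place_waveform(env[, j], win,
                                                     centered = TRUE)
  env[env < 0] <- 0
  muap <- muap_waveform(fs, cfg$muap_width_ms)
  samples <- matrix(0, n_samp, nm)
  n_events <- integer(nm)
  for (j in seq_len(nm)) {
    ch <- synthesize_muap_train(env[, j], muap, fs,
                                noise_sd = cfg$noise_sd)
    n_events[j] <- attr(ch, "n_events")
    samples[, j] <- ch
  }
  emg <- emg_recording(samples, fs, cfg$muscles, t0 = 0)

  ## ---- interneuron spikes ----
  desc <- rep(cfg$descending$rest_rate, n_samp)
  for (i in seq_len(k)) {
    i0 <- max(1L, floor(trials$cue_off[i] * fs) + 1L)
    i1 <- min(n_samp, floor(trials$go[i] * fs))
    if (i1 > i0) desc[i0:i1] <- desc[i0:i1] + cfg$descending$delay_boost
  }
  # feedback reflects the realized activity of the target muscle (rectified,
  # ~20 ms smoothed EMG), rescaled to the rate-envelope units so
  # feedback_gain keeps its Hz-per-(events/s) meaning
  if (length(target_j)) {
    box <- max(2L, round(0.02 * fs))
    act <- .place_waveform(abs(samples[, target_j]), rep(1 / box, box),
                           centered = TRUE)
    act[act < 0] <- 0
    fb_env <- act * mean(env[, target_j]) / mean(act)
  } else {
    fb_env <- rep(0, n_samp)
  }
  bg <- drive_agin(fb_env, cfg$feedback_gain, cfg$feedback_delay_ms, desc,
                   fs, t0 = 0)
  evoked_times <- stims$spike_time[!is.na(stims$spike_time)]
  all_times <- c(as.numeric(bg), evoked_times)
  # 0.1 ms rounding can push a final spike just past the session end
  all_times <- all_times[all_times <= duration]
  spk <- spike_train(all_times, "agIN", t_max = duration + 1e-3)

  ## ---- postspike kernel into the target channel ----
  if (length(target_j) && cfg$psf$amplitude != 0)
    emg <- apply_postspike_kernel(emg, spk, cfg$muscles$muscle[target_j],
                                  cfg$psf)

  ## ---- torque ----
  torque <- numeric(n_samp)
  for (i in seq_len(k)) {
    if (is.na(trials$movement_onset[i])) next
    sgn <- if (trials$direction[i] == "flexion") 1 else -1
    if (trials$outcome[i] == "wrong_direction") sgn <- -sgn
    rel <- if (!is.na(trials$passive_onset[i])) trials$passive_onset[i] else
      trials$hold_end[i]
    # contribution is negligible a couple of seconds past the release
    i0 <- max(1L, floor(trials$movement_onset[i] * fs))
    i1 <- min(n_samp, ceiling((rel + 2) * fs))
    w <- i0:i1
    torque[w] <- torque[w] + sgn * cfg$torque_plateau *
      (.step2(tt[w] - trials$movement_onset[i], cfg$torque_tau) -
         .step2(tt[w] - rel, cfg$torque_tau))
  }

  gt <- list(psf_kernel = cfg$psf,
             feedback_gain = cfg$feedback_gain,
             feedback_delay_ms = cfg$feedback_delay_ms,
             descending = cfg$descending,
             noise_sd = cfg$noise_sd,
             per_trial_gain = gains,
             trial_label = stats::setNames(trials$true_label, trials$trial_id),
             amp_mult = stats::setNames(trials$amp_mult, trials$trial_id),
             dur_mult = stats::setNames(trials$dur_mult, trials$trial_id),
             rate_envelopes = env,
             muap_events = n_events,
             seed = seed)

  structure(list(trials = trials, emg = emg, spikes = list(agIN = spk),
                 stims = stims, torque = torque, ground_truth = gt,
                 duration = duration, config = cfg),
            class = "ag_session")
}

#' @export
print.ag_session <- function(x, ...) {
  cat(sprintf(
    "<ag_session> %.1f s, %d trials, %d EMG channels, %d agIN spikes, %d stimuli\n",
    x$duration, nrow(x$trials), ncol(x$emg$samples),
    length(x$spikes$agIN), nrow(x$stims)))
  invisible(x)
}
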