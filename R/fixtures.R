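# Frozen study conditions for the package's three closure analyses.  Each
# returns a session_config; the choices (trial counts, gains, kernel sizes)
# are documented in the methods vignette and used identically by the tests
# and by scripts/acceptance.R.

#' Study conditions for the decoding closure
#'
#' Twelve successful extension trials with the default four-muscle set and
#' a moderate postspike kernel; the interneuron is driven by the realized
#' activity of its target muscle, so the sparse decoder should assign it
#' the largest muscle weight.
#'
#' @return a [session_config()].
#' @export
config_decoding_study <- function() {
  session_config(
    n_trials = data.frame(direction = "extension", outcome = "success",
                          n = 12L),
    psf = list(amplitude = 0.3, onset_ms = 6, width_ms = 4))
}

#' Study conditions for the reconstruction closure
#'
#' Ninety successful extension trials (the scale of the largest recorded
#' session), a strong postspike kernel on the target extensor, and an
#' interneuron tightly coupled to its target muscle.
#'
#' @return a [session_config()].
#' @export
config_reconstruction_study <- function() {
  session_config(
    n_trials = data.frame(direction = "extension", outcome = "success",
                          n = 90L),
    psf = list(amplitude = 0.4, onset_ms = 6, width_ms = 4),
    feedback_gain = 0.3)
}

#' Study conditions for the trial-gain closure
#'
#' One hundred successful extension trials of the target muscle alone, two
#' nerve stimuli per trial at response probability 0.10, and no injected
#' kernel: the analysis asks only whether higher-gain-labeled trials
#' carry the larger, longer prospective bursts.
#'
#' @return a [session_config()].
#' @export
config_trial_gain_study <- function() {
  session_config(
    n_trials = data.frame(direction = "extension", outcome = "success",
                          n = 100L),
    muscles = data.frame(muscle = "ECU", role = "extensor", target = TRUE),
    psf = list(amplitude = 0, onset_ms = 6, width_ms = 4),
    stim = list(n_per_trial = 2L, gain = 0.10, response_latency_ms = 1.7,
                volley_ms = 0.7, intensity = 1.1, nerve = "DR"))
}

#' Run the trial-gain rank-bias analysis on one session
#'
#' Labels each trial higher/lower-gain from its evoked responses, measures
#' the target-muscle burst of every trial, and tests the top-decile bias of
#' the normalized amplitude and duration ranks of the higher-gain subset.
#'
#' @param session an `ag_session` with stimulation events.
#' @param channel target muscle.
#' @return list with `labels`, `bursts`, `amp_test`, `dur_test`
#'   (see [rank_bias_test()]).
#' @export
trial_gain_analysis <- function(session, channel = "ECU") {
  lab <- label_trial_gain(session$trials, session$stims,
                          session$spikes$agIN)
  bt <- burst_table(session, channel)
  ok <- !is.na(bt$mean_amp) & !is.na(lab$label)
  ra <- normalized_rank(bt$mean_amp[ok])
  rd <- normalized_rank(bt$duration_s[ok])
  hi <- lab$label[ok] == "higher"
  list(labels = lab, bursts = bt,
       amp_test = rank_bias_test(ra[hi]),
       dur_test = rank_bias_test(rd[hi]),
       amp_test_lower = rank_bias_test(ra[!hi]),
       dur_test_lower = rank_bias_test(rd[!hi]))
}

#' Decode one session's interneuron from its muscle envelopes
#'
#' Preprocesses every channel (20 Hz envelope low-pass), builds the causal
#' 1--50 ms lagged design over the extension movement epochs, fits the ARD
#' model, and summarizes per-muscle weights.
#'
#' @param session an `ag_session`.
#' @param lowpass envelope low-pass (Hz).
#' @return list with `design`, `model`, `weights`.
#' @export
decode_session <- function(session, lowpass = 20) {
  fs <- session$emg$sample_rate
  env <- vapply(session$emg$channel_meta$muscle, function(m)
    preprocess_emg(emg_channel(session$emg, m), fs, lowpass = lowpass),
    numeric(nrow(session$emg$samples)))
  d <- build_design(env, session$spikes$agIN, movement_intervals(session), fs)
  m <- fit_ard(d)
  list(design = d, model = m,
       weights = summarize_weights(m, session$emg$channel_meta))
}

#' Reconstruct one muscle's task EMG from the session's interneuron
#'
#' Full pipeline: STA with detrending on the named channel, 15-ms snippet,
#' movement-aligned PETH, convolution reconstruction, and comparison with
#' the trial-averaged original over the detected burst.
#'
#' @param session an `ag_session`.
#' @param channel muscle to reconstruct.
#' @param burst_window_ms optional `c(onset, offset)` (ms relative to
#'   movement onset); detected from the target channel when `NULL`.
#' @param smooth_ms smoothing of the trial-averaged original (ms).
#' @param min_triggers STA trigger requirement.
#' @return list with `sta`, `snippet`, `peth`, `recon`, `original`, `R`,
#'   `area_ratio_pct`, `burst_window_ms`.
#' @export
reconstruct_session <- function(session, channel, burst_window_ms = NULL,
                                smooth_ms = 20, min_triggers = 2000) {
  spk <- session$spikes$agIN
  mo <- session$trials$movement_onset
  if (is.null(burst_window_ms)) {
    tgt <- session$emg$channel_meta$muscle[session$emg$channel_meta$target]
    bt <- burst_table(session, tgt)
    burst_window_ms <- c(
      stats::median((bt$onset_s - mo) * 1000, na.rm = TRUE),
      stats::median((bt$offset_s - mo) * 1000, na.rm = TRUE))
  }
  sta <- smooth_and_detrend(
    compute_sta(spk, session$emg, channel, min_triggers = min_triggers),
    session$emg)
  snip <- extract_snippet(sta)
  peth <- compute_peth(spk, mo)
  recon <- reconstruct_emg(peth, snip)
  orig <- average_aligned_emg(session$emg, channel, mo,
                              smooth_ms = smooth_ms)
  cmp <- compare_to_original(recon, orig, burst_window_ms)
  list(sta = sta, snippet = snip, peth = peth, recon = recon,
       original = orig, R = cmp$R, area_ratio_pct = cmp$area_ratio_pct,
       burst_window_ms = burst_window_ms)
}
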