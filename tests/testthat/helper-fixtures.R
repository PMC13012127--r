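# Small fixtures built in code.  All randomness is locally seeded.

one_channel_meta <- function(muscle = "ECU", role = "extensor",
                             target = TRUE) {
  data.frame(muscle = muscle, role = role, target = target)
}

# white-noise single-channel recording
noise_emg <- function(dur_s, fs = 2000, sd = 1, seed = 1,
                      meta = one_channel_meta()) {
  set.seed(seed)
  emg_recording(matrix(stats::rnorm(round(dur_s * fs), 0, sd)), fs, meta)
}

# uniform random spike train over (margin, dur - margin)
uniform_spikes <- function(n, dur_s, seed = 1, margin = 1) {
  set.seed(seed)
  spike_train(sort(stats::runif(n, margin, dur_s - margin)))
}

# recording with motor-unit background plus an injected postspike kernel
kernel_session <- function(n_spikes = 5200, dur_s = 260, fs = 2000,
                           amplitude = 0.8, onset_ms = 6, width_ms = 4,
                           mu_rate = 40, noise_sd = 0.3, seed = 11) {
  set.seed(seed)
  n <- round(dur_s * fs)
  base <- synthesize_muap_train(rep(mu_rate, n), muap_waveform(fs), fs,
                                noise_sd = noise_sd)
  emg <- emg_recording(matrix(as.numeric(base)), fs, one_channel_meta())
  spk <- spike_train(sort(stats::runif(n_spikes, 1, dur_s - 1)))
  emg <- apply_postspike_kernel(emg, spk, "ECU",
                                list(amplitude = amplitude,
                                     onset_ms = onset_ms,
                                     width_ms = width_ms))
  list(emg = emg, spikes = spk)
}

# a minimal but complete detrended STA object for geometric tests
synthetic_sta <- function(detrended, lags_ms, baseline_mean = 1,
                          baseline_sd_dt = 1e-6, fs = 2000) {
  structure(list(trigger_count = 5000, lags_ms = lags_ms,
                 mean_waveform = detrended + baseline_mean,
                 detrended_waveform = detrended,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd_dt,
                 dt_baseline_mean = 0, dt_baseline_sd = baseline_sd_dt,
                 sample_rate = fs, channel = "ECU",
                 window_ms = range(lags_ms)),
            class = "sta_result")
}
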