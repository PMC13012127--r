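test_that("invalid configurations are rejected with the parameter named", {
  expect_error(session_config(baseline_rate = -1), "baseline_rate")
  expect_error(session_config(stim = list(n_per_trial = 2L, gain = 1.5,
                                          response_latency_ms = 1.7,
                                          volley_ms = 0.7, intensity = 1.1,
                                          nerve = "DR")), "gain")
  expect_error(session_config(stim = list(n_per_trial = 2L, gain = 0.5,
                                          response_latency_ms = 6,
                                          volley_ms = 0.7, intensity = 1.1,
                                          nerve = "DR")), "latency")
})

test_that("an empty trial list yields EMG of the requested duration and no stimuli", {
  cfg <- session_config(
    n_trials = data.frame(direction = "extension", outcome = "success", n = 0L),
    base_duration_s = 12)
  s <- generate_session(cfg, seed = 1)
  expect_equal(nrow(s$trials), 0)
  expect_equal(nrow(s$emg$samples), 12 * cfg$sample_rate)
  expect_equal(nrow(s$stims), 0)
})

test_that("identical (config, seed) produce bit-identical sessions", {
  cfg <- session_config(
    n_trials = data.frame(direction = c("extension", "flexion"),
                          outcome = c("success", "short_hold"), n = c(3L, 2L)))
  a <- generate_session(cfg, seed = 99)
  b <- generate_session(cfg, seed = 99)
  expect_identical(a$emg$samples, b$emg$samples)
  expect_identical(as.numeric(a$spikes$agIN), as.numeric(b$spikes$agIN))
  expect_identical(a$stims, b$stims)
  expect_identical(a$trials, b$trials)
  c2 <- generate_session(cfg, seed = 100)
  expect_false(identical(a$emg$samples, c2$emg$samples))
})

test_that("generated trials satisfy the event-ordering invariants", {
  cfg <- session_config(n_trials = data.frame(
    direction = c("extension", "flexion", "extension", "extension"),
    outcome = c("success", "success", "short_hold", "no_movement"),
    n = c(3L, 3L, 3L, 2L)))
  s <- generate_session(cfg, seed = 4)
  expect_silent(validate_trials(s$trials))
  sh <- s$trials[s$trials$outcome == "short_hold", ]
  expect_true(all(is.na(sh$reward)))
  expect_true(all(s$stims$volley_time >= s$stims$time))
  expect_true(all(s$stims$intensity >= 1 & s$stims$intensity <= 1.2))
})

test_that("motor-unit synthesis matches its Poisson mean and grows with rate", {
  fs <- 2000
  # zero rate, zero noise: silent channel
  expect_true(all(synthesize_muap_train(rep(0, 1000), muap_waveform(fs),
                                        fs, seed = 1) == 0))
  # constant 100/s over 10 s: mean event count within 1% of 1000 over seeds
  counts <- vapply(1:100, function(sd)
    attr(synthesize_muap_train(rep(100, 10 * fs), muap_waveform(fs), fs,
                               seed = sd), "n_events"), numeric(1))
  expect_lt(abs(mean(counts) - 1000) / 1000, 0.01)
  # doubling the rate strictly increases the mean rectified amplitude
  a1 <- mean(abs(synthesize_muap_train(rep(100, 10 * fs), muap_waveform(fs),
                                       fs, seed = 7)))
  a2 <- mean(abs(synthesize_muap_train(rep(200, 10 * fs), muap_waveform(fs),
                                       fs, seed = 7)))
  expect_gt(a2, a1)
  expect_error(synthesize_muap_train(c(1, -1), muap_waveform(fs), fs),
               "nonnegative")
})

test_that("postspike kernel injection is an exact impulse response", {
  fs <- 2000
  emg <- emg_recording(matrix(0, 2 * fs, 1), fs, one_channel_meta())
  spk <- spike_train(0.5)
  kern <- list(amplitude = 1, onset_ms = 6, width_ms = 4)
  out <- apply_postspike_kernel(emg, spk, "ECU", kern)
  wav <- psf_waveform(kern, fs)
  idx <- round(0.5 * fs) + 1L
  expect_equal(out$samples[idx:(idx + length(wav) - 1L), 1], wav,
               tolerance = 1e-10)
  expect_lt(max(abs(out$samples[1:(idx - 1L), 1])), 1e-9)
  # amplitude 0 leaves the recording untouched
  out0 <- apply_postspike_kernel(emg, spk, "ECU",
                                 list(amplitude = 0, onset_ms = 6,
                                      width_ms = 4))
  expect_identical(out0$samples, emg$samples)
  expect_error(apply_postspike_kernel(emg, spk, "nope", kern), "not found")
})

test_that("brute-force averaging around spikes recovers the kernel onset", {
  ks <- kernel_session(n_spikes = 5000, dur_s = 250, seed = 3)
  x <- abs(emg_channel(ks$emg, "ECU"))
  fs <- ks$emg$sample_rate
  idx <- round(as.numeric(ks$spikes) * fs) + 1L
  lags <- 0:40   # 0..20 ms
  avg <- vapply(lags, function(l) mean(x[idx + l]), numeric(1))
  base <- mean(avg[1:8])   # pre-onset lags (< 4 ms)
  peak_lag_ms <- lags[which.max(avg)] / fs * 1000
  # kernel onset 6 ms, PWHM 4 ms: peak at 6 + 4 = 10 ms; rise begins at 6
  expect_lt(abs(peak_lag_ms - 10), 1.5)
  rise <- which(avg - base > 0.5 * (max(avg) - base))[1]
  expect_lt(abs(lags[rise] / fs * 1000 - (6 + 2)), 1)
})

test_that("drive_agin reproduces its Poisson mean and respects the contract", {
  fs <- 2000
  n <- 10 * fs
  counts <- vapply(1:200, function(sd)
    length(drive_agin(rep(0, n), 0, 0, rep(30, n), fs, seed = sd)),
    numeric(1))
  expect_lt(abs(mean(counts) - 300) / 300, 0.02)
  expect_length(drive_agin(rep(0, n), 1, 10, rep(0, n), fs, seed = 1), 0)
  expect_error(drive_agin(rep(1, n), -0.1, 10, rep(0, n), fs), "nonnegative")
})

test_that("feedback-driven spiking peaks at the imposed delay", {
  fs <- 2000
  n <- 200 * fs
  set.seed(5)
  # slowly wandering envelope, delay 20 ms
  env <- 60 * (1 + sin(2 * pi * seq_len(n) / fs / 1.3))
  spk <- drive_agin(env, 1, 20, rep(0, n), fs, seed = 6)
  rate <- tabulate(floor(as.numeric(spk) * 1000) + 1L, nbins = 200 * 1000)
  env_ms <- env[seq(1, n, by = 2)]
  lags <- -40:40
  cc <- vapply(lags, function(l) {
    i <- seq_len(length(rate) - 80) + 40
    stats::cor(rate[i], env_ms[i - l])
  }, numeric(1))
  best <- lags[which.max(cc)]
  expect_lt(abs(best - 20), 3)
})

test_that("stimulus responses are per-trial Bernoulli draws", {
  stims <- data.frame(time = seq(1, 500), trial_id = rep("t1", 500))
  g1 <- generate_stim_responses(stims, c(t1 = 1), 1.7, seed = 1)
  expect_true(all(g1$evoked))
  expect_equal(g1$spike_time, g1$time + 0.0017)
  g0 <- generate_stim_responses(stims, c(t1 = 0), 1.7, seed = 1)
  expect_false(any(g0$evoked))
  g4 <- generate_stim_responses(stims, c(t1 = 0.4), 1.7, seed = 2)
  ci <- stats::binom.test(sum(g4$evoked), 500, 0.4)$conf.int
  expect_true(ci[1] <= 0.4 && 0.4 <= ci[2])
  expect_error(generate_stim_responses(stims, c(t1 = 0.4), 5), "< 5 ms")
})

test_that("higher-gain label frequency matches the closed-form probability", {
  # P(any of k stimuli evokes) = 1 - (1 - g)^k, checked over 200 seeded draws
  g <- 0.5; k <- 3; n_trial <- 20
  stims <- data.frame(time = seq_len(n_trial * k),
                      trial_id = rep(sprintf("t%02d", seq_len(n_trial)),
                                     each = k))
  gains <- stats::setNames(rep(g, n_trial), unique(stims$trial_id))
  frac <- vapply(1:200, function(sd) {
    r <- generate_stim_responses(stims, gains, 1.7, seed = sd)
    mean(tapply(r$evoked, r$trial_id, any))
  }, numeric(1))
  p_lab <- 1 - (1 - g)^k
  tot <- round(mean(frac) * n_trial * 200)
  ci <- stats::binom.test(tot, n_trial * 200, p_lab)$conf.int
  expect_true(ci[1] <= p_lab && p_lab <= ci[2])
  # and the generator's recorded label agrees with its own evoked draws
  s <- generate_session(session_config(
    n_trials = data.frame(direction = "extension", outcome = "success",
                          n = 10L)), seed = 2)
  lab <- tapply(s$stims$evoked, s$stims$trial_id, any)
  expect_identical(
    as.vector(ifelse(lab[s$trials$trial_id], "higher", "lower")),
    s$trials$true_label)
})

test_that("session event tables and YAML configs round-trip", {
  cfg <- session_config(n_trials = data.frame(direction = "extension",
                                              outcome = "success", n = 2L))
  s <- generate_session(cfg, seed = 8)
  d <- withr::local_tempdir()
  export_session_events(s, d)
  ev <- utils::read.csv(file.path(d, "trials.csv"))
  expect_equal(nrow(ev), 9 * 2)   # all events present on success trials
  expect_true(all(c("kind", "time_s", "trial_id", "attrs") %in% names(ev)))
  yml <- file.path(d, "cfg.yaml")
  write_session_config(cfg, yml)
  cfg2 <- read_session_config(yml)
  expect_equal(cfg2$n_trials, cfg$n_trials)
  expect_equal(cfg2$stim$gain, cfg$stim$gain)
})
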