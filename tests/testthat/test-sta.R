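test_that("the STA equals an independent brute-force segment average", {
  ks <- kernel_session(n_spikes = 800, dur_s = 45, seed = 2)
  sta <- compute_sta(ks$spikes, ks$emg, "ECU", min_triggers = 100)
  x <- abs(emg_channel(ks$emg, "ECU"))
  fs <- ks$emg$sample_rate
  idx <- round(as.numeric(sta$accepted_times) * fs) + 1L
  bf <- vapply(-100:100, function(l) mean(x[idx + l]), numeric(1))
  expect_equal(sta$mean_waveform, bf, tolerance = 1e-12)
  expect_equal(length(sta$lags_ms), 201L)
  expect_equal(sta$lags_ms[101], 0)
})

test_that("constant EMG above the noise floor gives a flat STA at that level", {
  fs <- 2000
  emg <- emg_recording(matrix(3, 20 * fs, 1), fs, one_channel_meta())
  spk <- uniform_spikes(50, 20, seed = 3)
  sta <- compute_sta(spk, emg, "ECU", min_triggers = 10, noise_rms = 1)
  expect_true(all(abs(sta$mean_waveform - 3) < 1e-12))
})

test_that("triggers failing the RMS acceptance rule are rejected and counted", {
  fs <- 2000
  x <- c(rep(0.1, 10 * fs), rep(5, 10 * fs))   # quiet then active half
  emg <- emg_recording(matrix(x), fs, one_channel_meta())
  spk <- spike_train(c(seq(2, 8, by = 0.5), seq(12, 18, by = 0.5)))
  sta <- compute_sta(spk, emg, "ECU", min_triggers = 2, noise_rms = 0.1)
  expect_equal(sta$trigger_count, 13L)   # only spikes in the active half
  expect_true(all(sta$accepted_times > 10))
  expect_error(compute_sta(spk, emg, "ECU", min_triggers = 1000,
                           noise_rms = 0.1), "insufficient triggers")
})

test_that("shifted-average detrending removes a linear ramp", {
  fs <- 2000
  n <- 60 * fs
  set.seed(9)
  ramp <- seq(0, 4, length.out = n)
  emg <- emg_recording(matrix(ramp + abs(stats::rnorm(n, 0, 0.05))), fs,
                       one_channel_meta())
  spk <- uniform_spikes(1500, 60, seed = 10)
  sta <- compute_sta(spk, emg, "ECU", min_triggers = 500, noise_rms = 0)
  det <- smooth_and_detrend(sta, emg)
  # raw STA spans the ramp; detrended waveform is flat near zero
  expect_gt(diff(range(sta$mean_waveform)), 0.005)
  expect_lt(max(abs(det$detrended_waveform)), 0.005)
  # an already-flat waveform is essentially unchanged
  flat <- emg_recording(matrix(rep(2, n)), fs, one_channel_meta())
  sta_f <- smooth_and_detrend(compute_sta(spk, flat, "ECU",
                                          min_triggers = 500,
                                          noise_rms = 0.5), flat)
  expect_lt(max(abs(sta_f$detrended_waveform)), 1e-6 * 2)
  expect_error(smooth_and_detrend(sta, emg, shifts_ms = 10), "at least 2")
})

test_that("ramp plus kernel recovers the kernel within 10% of kernel-only", {
  mk <- function(with_ramp, seed = 12) {
    fs <- 2000; dur <- 120; n <- dur * fs
    set.seed(seed)
    base <- abs(stats::rnorm(n, 0, 0.2))
    if (with_ramp) base <- base + seq(0, 2, length.out = n)
    emg <- emg_recording(matrix(base), fs, one_channel_meta())
    spk <- uniform_spikes(3000, dur, seed = seed + 1)
    emg <- apply_postspike_kernel(emg, spk, "ECU",
                                  list(amplitude = 0.5, onset_ms = 6,
                                       width_ms = 4))
    sta <- smooth_and_detrend(compute_sta(spk, emg, "ECU",
                                          min_triggers = 1000,
                                          noise_rms = 0), emg)
    max(sta$detrended_waveform[sta$lags_ms > 0])
  }
  a0 <- mk(FALSE); a1 <- mk(TRUE)
  expect_lt(abs(a1 - a0) / a0, 0.10)
})

test_that("the fragment test is exact-degenerate and Bonferroni-correct", {
  # the Bonferroni threshold for 12 muscles
  expect_equal(signif(0.05 / 12, 3), 0.00417)
  ks <- kernel_session(n_spikes = 600, dur_s = 90, amplitude = 0, seed = 5)
  sta <- compute_sta(ks$spikes, ks$emg, "ECU", min_triggers = 400,
                     rms_accept = 0, noise_rms = 0)
  # identical test and baseline windows: p = 1 by construction
  deg <- fragment_significance(sta, test_window_ms = c(-30, -10),
                               baseline_window_ms = c(-30, -10))
  expect_equal(deg$p_value, 1)
  expect_error(fragment_significance(sta, n_fragments = 40),
               "< 20")
})

test_that("fragment-test rejection rate is calibrated on null sessions", {
  set.seed(61)
  fs <- 2000
  meta <- one_channel_meta()
  pvals <- vapply(1:300, function(i) {
    x <- matrix(stats::rnorm(90 * fs), ncol = 1)
    emg <- emg_recording(x, fs, meta)
    spk <- spike_train(sort(stats::runif(440, 1, 89)))
    sta <- compute_sta(spk, emg, "ECU", min_triggers = 400,
                       rms_accept = 0, noise_rms = 0)
    fragment_significance(sta)$p_value
  }, numeric(1))
  rej <- mean(pvals < 0.05)
  ci <- stats::binom.test(sum(pvals < 0.05), 300, 0.05)$conf.int
  expect_true(ci[1] <= 0.05 && 0.05 <= ci[2])
  expect_gt(rej, 0)   # the test is not degenerate either
})

test_that("effect measurement recovers injected kernels and exact geometry", {
  ks <- kernel_session(n_spikes = 5200, dur_s = 260, amplitude = 0.8,
                       onset_ms = 6, width_ms = 4, seed = 11)
  sta <- smooth_and_detrend(compute_sta(ks$spikes, ks$emg, "ECU",
                                        min_triggers = 2000), ks$emg)
  eff <- measure_effect(sta)
  expect_equal(eff$sign, "facilitation")
  expect_lt(abs(eff$onset_ms - 6), 1)
  expect_lt(abs(eff$pwhm_ms - 4), 1)
  expect_gt(eff$magnitude_pct, 0)
  # symmetric triangle of half-height width w has PWHM exactly w
  fs <- 2000
  lags <- seq(-50, 50, by = 0.5)
  tri <- pmax(0, 1 - abs(lags - 8) / 4)   # peak at 8 ms, half-width 4 ms
  sta_t <- synthetic_sta(tri, lags)
  eff_t <- measure_effect(sta_t)
  expect_equal(eff_t$pwhm_ms, 4, tolerance = 1e-9)
  expect_equal(eff_t$peak_ms, 8)
  # a negative kernel flips the sign and the magnitude
  eff_n <- measure_effect(synthetic_sta(-tri, lags))
  expect_equal(eff_n$sign, "suppression")
  expect_lt(eff_n$magnitude_pct, 0)
  expect_equal(eff_n$pwhm_ms, 4, tolerance = 1e-9)
})

test_that("PSE vs synchrony classification follows the latency and width rules", {
  eff <- function(onset, pwhm)
    structure(list(muscle = "ECU", sign = "facilitation", onset_ms = onset,
                   peak_ms = onset + 1, pwhm_ms = pwhm, magnitude_pct = 10,
                   p_value = 0.001, label = "unclassified"),
              class = "postspike_effect")
  expect_equal(classify_effect(eff(6, 4))$label, "PSE")
  expect_equal(classify_effect(eff(2, 4))$label, "synchrony")
  expect_equal(classify_effect(eff(6, 9))$label, "synchrony")
  none <- eff(NA_real_, NA_real_)
  expect_equal(classify_effect(none)$label, "none")
})

test_that("detection probability is nondecreasing in kernel amplitude", {
  detect <- function(amp, seed) {
    ks <- kernel_session(n_spikes = 450, dur_s = 70, amplitude = amp,
                         mu_rate = 30, noise_sd = 0.3, seed = seed)
    sta <- compute_sta(ks$spikes, ks$emg, "ECU", min_triggers = 400,
                       rms_accept = 0, noise_rms = 0)
    fragment_significance(sta)$significant
  }
  amps <- c(0.05, 0.2, 0.6)
  rate <- vapply(amps, function(a)
    mean(vapply(1:25, function(sd) detect(a, 100 + sd), logical(1))),
    numeric(1))
  expect_true(all(diff(rate) >= 0))
  expect_gt(rate[3], rate[1])
  expect_gt(rate[3], 0.8)
})

test_that("crosstalk screening flags copies but not independent channels", {
  fs <- 2000; dur <- 50; n <- dur * fs
  set.seed(31)
  meta2 <- data.frame(muscle = c("A", "B"), role = "extensor",
                      target = FALSE)
  spk <- uniform_spikes(300, dur, seed = 32)
  # a motor-unit-like neuron: every spike adds a large MUAP to channel A
  a <- as.numeric(synthesize_muap_train(rep(15, n), muap_waveform(fs), fs,
                                        noise_sd = 0.05))
  idx <- round(as.numeric(spk) * fs) + 1L
  imp <- numeric(n); imp[idx] <- 1
  mu <- 3 * muap_waveform(fs)
  a <- a + as.numeric(stats::filter(c(imp, numeric(9)), rev(mu),
                                    sides = 1))[4:(n + 3)]
  a[is.na(a)] <- 0
  b_copy <- 0.5 * a
  set.seed(33)
  b_noise <- a + stats::rnorm(n, 0, stats::sd(a))     # SNR 0 dB
  b_indep <- as.numeric(synthesize_muap_train(rep(15, n), muap_waveform(fs),
                                              fs, noise_sd = 0.05))
  flag_of <- function(b) {
    emg <- emg_recording(cbind(a, b), fs, meta2)
    screen_crosstalk(emg, "A", "B", spk)$flag
  }
  expect_true(flag_of(b_copy))
  expect_true(flag_of(b_noise))
  expect_false(flag_of(b_indep))
})

test_that("the 50-spike unrectified STA screen separates motoneurons", {
  fs <- 2000; dur <- 40; n <- dur * fs
  set.seed(41)
  spk <- uniform_spikes(60, dur, seed = 42)
  base <- stats::rnorm(n, 0, 0.2)
  idx <- round(as.numeric(spk) * fs) + 1L
  imp <- numeric(n); imp[idx] <- 1
  mu_sig <- as.numeric(stats::filter(c(imp, numeric(9)),
                                     rev(3 * muap_waveform(fs)),
                                     sides = 1))[4:(n + 3)]
  mu_sig[is.na(mu_sig)] <- 0
  emg_mn <- emg_recording(matrix(base + mu_sig), fs, one_channel_meta())
  expect_true(screen_motor_unit(spk, emg_mn, "ECU")$flag)
  emg_pm <- emg_recording(matrix(base), fs, one_channel_meta())
  expect_false(screen_motor_unit(spk, emg_pm, "ECU")$flag)
  expect_error(screen_motor_unit(spike_train(1:10), emg_pm, "ECU"),
               "at least 50")
})

test_that("neuron categorization combines input and output correctly", {
  meta <- data.frame(muscle = c("EDC", "ECU", "FCR"),
                     role = c("extensor", "extensor", "flexor"),
                     target = FALSE)
  pse <- function(m, sgn) structure(
    list(muscle = m, sign = sgn, onset_ms = 6, peak_ms = 8, pwhm_ms = 4,
         magnitude_pct = if (sgn == "facilitation") 8 else -8,
         p_value = 1e-4, label = "PSE"), class = "postspike_effect")
  cls <- classify_neuron(TRUE, 1.2, list(pse("EDC", "facilitation"),
                                         pse("ECU", "facilitation")), meta)
  expect_equal(cls$pattern, "autogenic")
  expect_equal(cls$polarity, "excitatory")
  expect_true(cls$is_agIN)
  cls2 <- classify_neuron(TRUE, 1.2, list(pse("FCR", "suppression")), meta)
  expect_equal(cls2$pattern, "heterogenetic")
  expect_equal(cls2$polarity, "inhibitory")
  expect_false(cls2$is_agIN)
  cls3 <- classify_neuron(TRUE, 1.2, list(), meta)
  expect_equal(cls3$pattern, "none")
  expect_false(cls3$is_agIN)
  # no monosynaptic input blocks agIN status even with autogenic output
  cls4 <- classify_neuron(FALSE, 3, list(pse("ECU", "facilitation")), meta)
  expect_false(cls4$is_agIN)
})
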