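test_that("EMG preprocessing matches rectified-sine closed forms", {
  fs <- 2000
  t <- seq(0, 10, by = 1 / fs)
  a <- 2
  env <- preprocess_emg(a * sin(2 * pi * 100 * t), fs)
  steady <- env[(3 * fs):(7 * fs)]
  expect_lt(abs(mean(steady) - 2 * a / pi) / (2 * a / pi), 0.05)
  # DC is removed by the band-pass
  dc <- preprocess_emg(rep(1.5, length(t)), fs)
  expect_lt(max(abs(dc[(fs):(9 * fs)])), 0.01)
  # 400 Hz is attenuated by at least 20 dB relative to 100 Hz
  env4 <- preprocess_emg(a * sin(2 * pi * 400 * t), fs)
  att <- 20 * log10(mean(steady) / mean(env4[(3 * fs):(7 * fs)]))
  expect_gt(att, 20)
  expect_error(preprocess_emg(stats::rnorm(100), 400), "sample_rate")
})

test_that("burst detection finds rectangular bursts with small bias", {
  fs <- 2000
  dur <- 4
  mk_env <- function() {
    x <- rep(0.1, dur * fs)
    x[(0.5 * fs):(1.5 * fs)] <- 1
    x
  }
  rest <- list(mean = 0.1, sd = 0.02)
  b <- detect_burst(mk_env(), fs, rest, movement_onset = 0.55,
                    variant = "hold")
  expect_s3_class(b, "emg_burst")
  expect_lt(abs(b$onset_time - 0.5), 0.03)
  expect_lt(abs(b$duration - 1.0), 0.06)
  expect_equal(b$offset_time - b$onset_time, b$duration)
  # sub-threshold envelope: no burst
  expect_null(detect_burst(rep(0.1, dur * fs), fs, rest, 0.55))
  # sharp-drop variant: offset at the local peak with the steepest drop
  x <- rep(0.1, dur * fs)
  tt <- seq_len(dur * fs) / fs
  x <- x + 1.0 * exp(-((tt - 0.8)^2) / (2 * 0.01)) +
    0.35 * exp(-((tt - 1.6)^2) / (2 * 0.01))
  b2 <- detect_burst(x, fs, rest, movement_onset = 0.75,
                     variant = "sharp_drop")
  expect_lt(abs(b2$offset_time - 0.8), 0.05)
})

test_that("burst duration bias is below 5% on rectangular envelope bursts", {
  fs <- 2000
  durs <- c(0.5, 1.0, 1.5)
  bias <- vapply(durs, function(d) {
    set.seed(round(100 * d))
    n <- 5 * fs
    env <- 0.1 + abs(stats::rnorm(n, 0, 0.01))
    env[(1 * fs):((1 + d) * fs)] <- env[(1 * fs):((1 + d) * fs)] + 1
    rest <- list(mean = mean(env[1:(0.9 * fs)]),
                 sd = stats::sd(env[1:(0.9 * fs)]))
    b <- detect_burst(env, fs, rest, movement_onset = 1.05)
    abs(b$duration - d) / d
  }, numeric(1))
  expect_true(all(bias < 0.05))
})

test_that("normalized ranks are uniform and session-wise", {
  expect_equal(normalized_rank(c(5, 1, 3)), c(3, 1, 2) / 3)
  expect_equal(normalized_rank(7), 1)
  # ties break by stable order
  expect_equal(normalized_rank(c(2, 2, 1)), c(2, 3, 1) / 3)
  # pooled sessions of different sizes stay flat in expectation
  set.seed(11)
  counts <- matrix(0, 500, 10)
  for (r in 1:500) {
    v1 <- stats::rnorm(40); v2 <- stats::rnorm(25)
    rk <- normalized_rank(c(v1, v2), c(rep(1, 40), rep(2, 25)))
    counts[r, ] <- table(cut(rk, seq(0, 1, 0.1)))
  }
  tot <- colSums(counts)
  for (b in 1:10) {
    ci <- stats::binom.test(tot[b], 500 * 65, 0.1)$conf.int
    expect_true(ci[1] <= 0.105 && 0.095 <= ci[2])
  }
})

test_that("the top-bin binomial tail matches an explicit summation", {
  h <- rank_bias_test(c(seq(0.05, 0.95, length.out = 13),
                        rep(0.95, 0), rep(0.99, 7)))
  expect_equal(h$n, 20)
  expect_equal(sum(h$counts), 20)
  # exact tail by direct summation for all n <= 50
  tail_sum <- function(k, n) sum(choose(n, k:n) * 0.1^(k:n) * 0.9^(n - k:n))
  for (n in c(5, 20, 50)) {
    rk <- c(rep(0.95, 3), stats::runif(n - 3, 0, 0.9))
    got <- rank_bias_test(rk)$top_bin_p
    expect_equal(got, tail_sum(3, n), tolerance = 1e-12)
  }
  # zero top-bin occupancy: p = P(X >= 0) = 1
  expect_equal(rank_bias_test(rep(0.5, 20))$top_bin_p, 1)
  expect_error(rank_bias_test(numeric(0)), "empty")
})

test_that("epoch firing rates reflect the generating drive", {
  s <- generate_session(session_config(
    n_trials = data.frame(direction = c("extension", "flexion"),
                          outcome = "success", n = c(10L, 10L))), seed = 21)
  er <- epoch_firing_rates(s$spikes$agIN, s$trials)
  ext <- function(ep) er$rate_hz[er$direction == "extension" & er$epoch == ep]
  flx <- function(ep) er$rate_hz[er$direction == "flexion" & er$epoch == ep]
  expect_gt(ext("active_movement"), ext("rest"))
  expect_gt(ext("active_movement"), flx("active_movement"))
  expect_true(all(er$rate_hz >= 0, na.rm = TRUE))
})

test_that("the population direction-bias test gives exact tail probabilities", {
  lab <- c(rep("extension", 13), "flexion")
  r <- direction_bias_test(lab)
  expect_equal(r$n_biased, 14)
  expect_equal(r$p_value, 15 / 16384)
  expect_lt(r$p_value, 0.001)
  r7 <- direction_bias_test(c(rep("extension", 7), rep("flexion", 7)))
  expect_equal(r7$p_value,
               sum(choose(14, 7:14)) / 2^14, tolerance = 1e-12)
  expect_equal(round(r7$p_value, 3), 0.605)
  r14 <- direction_bias_test(rep("extension", 14))
  expect_equal(r14$p_value, 1 / 16384)
  # unbiased neurons are excluded from n
  r_u <- direction_bias_test(c(rep("extension", 13), "flexion", "unbiased"))
  expect_equal(r_u$n_biased, 14)
})

test_that("per-neuron direction bias detects the extension preference", {
  s <- generate_session(session_config(
    n_trials = data.frame(direction = c("extension", "flexion"),
                          outcome = "success", n = c(12L, 12L))), seed = 22)
  db <- direction_bias(s$spikes$agIN, s$trials)
  expect_equal(db$bias, "extension")
  expect_lt(db$p_value, 0.05)
  expect_gt(db$rate_extension, db$rate_flexion)
})

test_that("the paired success-vs-error gain comparison behaves at its edges", {
  x <- c(0.2, 0.3, 0.25, 0.4)
  same <- compare_gain_success_error(x, x)
  expect_equal(same$p_value, 1)
  expect_equal(same$mean_difference, 0)
  shift <- compare_gain_success_error(x + 0.1, x)
  expect_equal(shift$mean_difference, 0.1)
  expect_lt(shift$p_value, 0.001)
  set.seed(23)
  a <- stats::runif(12, 0.2, 0.5)
  d12 <- compare_gain_success_error(a + 0.05, a)
  expect_lt(d12$p_value, 0.001)
  expect_equal(d12$n_smaller_on_error, 12L)
  expect_error(compare_gain_success_error(1, numeric(0)), "equal length")
  expect_error(compare_gain_success_error(1, 2), "at least 2")
})

test_that("movement-aligned firing onset lands in the correct 10-ms bin", {
  set.seed(24)
  onsets <- seq(10, 10 + 39 * 5, by = 5)
  jit <- stats::runif(40, -0.012, 0.012)
  spk_pre <- spike_train(c(onsets - 0.030 + jit,
                           sort(stats::runif(60, 5, 215))))
  r <- firing_onset_latency(spk_pre, onsets)
  expect_true(r$latency_ms >= -50 && r$latency_ms <= -20)
  spk_at <- spike_train(c(onsets + abs(jit),
                          sort(stats::runif(60, 5, 215))))
  r0 <- firing_onset_latency(spk_at, onsets)
  expect_true(r0$latency_ms >= -10 && r0$latency_ms < 10)
  # no modulation: no onset
  set.seed(25)
  flat <- spike_train(sort(stats::runif(400, 5, 215)))
  expect_true(is.na(firing_onset_latency(flat, onsets)$latency_ms))
  expect_error(firing_onset_latency(flat, onsets[1:5]), "at least 10")
})
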