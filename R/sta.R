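# Spike-triggered averaging of rectified EMG: trigger acceptance by the RMS
# rule, five-point smoothing, incremented-shifted-average detrending,
# multiple-fragment significance testing, postspike-effect measurement and
# PSE/synchrony classification, crosstalk and motor-unit screens, and
# input-output categorization of the neuron.

# RMS of the quietest 100-ms windows of a channel: the noise floor against
# which the 1.25x trigger-acceptance rule is evaluated
.noise_rms <- function(x, sample_rate, win_s = 0.1, frac = 0.1) {
  w <- max(2L, round(win_s * sample_rate))
  nwin <- length(x) %/% w
  if (nwin < 2) return(sqrt(mean(x^2)))
  m <- matrix(x[seq_len(nwin * w)], w, nwin)
  r <- sqrt(colMeans(m^2))
  mean(sort(r)[seq_len(max(1L, ceiling(frac * nwin)))])
}

# trigger-aligned segment matrix (triggers x lags) of a channel
.segments <- function(x, sample_rate, spike_times, t0, window_ms) {
  i0 <- round(window_ms[1] * sample_rate / 1000)
  i1 <- round(window_ms[2] * sample_rate / 1000)
  centers <- round((spike_times - t0) * sample_rate) + 1L
  keep <- centers + i0 >= 1L & centers + i1 <= length(x)
  centers <- centers[keep]
  lags <- i0:i1
  seg <- matrix(x[rep(centers, each = length(lags)) + lags],
                nrow = length(centers), byrow = TRUE)
  list(segments = seg, lags_ms = lags / sample_rate * 1000,
       spike_times = spike_times[keep])
}

#' Spike-triggered average of rectified EMG
#'
#' Averages rectified-EMG segments aligned to each accepted spike.  A spike
#' is accepted as a trigger only if the RMS of the EMG from 30 ms before to
#' 50 ms after it exceeds `rms_accept` times the channel's RMS noise floor.
#'
#' @param spikes a [spike_train()] (or numeric times).
#' @param emg an [emg_recording()]; the channel is rectified internally.
#' @param channel muscle name.
#' @param window_ms averaging window around the trigger (ms).
#' @param rms_accept RMS acceptance factor.
#' @param min_triggers minimum accepted trigger count; fewer is an error
#'   ("insufficient triggers"), so a skipped neuron is never silent.
#' @param noise_rms RMS noise level of the channel; estimated from the
#'   quietest deciles of the recording when `NULL`.
#' @return Object of class `sta_result`: `trigger_count`, `lags_ms`,
#'   `mean_waveform`, `segments` (accepted triggers x lags, rectified),
#'   `baseline_mean`/`baseline_sd` (raw waveform over pre-trigger lags
#'   -30..-10 ms), `sample_rate`, `channel`, `accepted_times`.
#' @export
compute_sta <- function(spikes, emg, channel, window_ms = c(-50, 50),
                        rms_accept = 1.25, min_triggers = 2000,
                        noise_rms = NULL) {
  x <- abs(emg_channel(emg, channel))
  fs <- emg$sample_rate
  st <- as.numeric(spikes)
  if (is.null(noise_rms)) noise_rms <- .noise_rms(x, fs)
  # acceptance segment: -30..+50 ms
  acc <- .segments(x, fs, st, emg$t0, c(-30, 50))
  seg_rms <- sqrt(rowMeans(acc$segments^2))
  ok <- seg_rms > rms_accept * noise_rms
  accepted <- acc$spike_times[ok]
  if (length(accepted) < min_triggers)
    stop(sprintf("insufficient triggers: %d accepted < %d required",
                 length(accepted), min_triggers))
  sg <- .segments(x, fs, accepted, emg$t0, window_ms)
  mw <- colMeans(sg$segments)
  bl <- sg$lags_ms >= -30 & sg$lags_ms <= -10
  structure(list(trigger_count = nrow(sg$segments), lags_ms = sg$lags_ms,
                 mean_waveform = mw, segments = sg$segments,
                 baseline_mean = mean(mw[bl]), baseline_sd = stats::sd(mw[bl]),
                 sample_rate = fs, channel = channel,
                 accepted_times = sg$spike_times, window_ms = window_ms),
            class = "sta_result")
}

#' @export
print.sta_result <- function(x, ...) {
  cat(sprintf("<sta_result> %s: %d triggers, lags %.0f..%.0f ms%s\n",
              x$channel, x$trigger_count, min(x$lags_ms), max(x$lags_ms),
              if (!is.null(x$detrended_waveform)) ", detrended" else ""))
  invisible(x)
}

#' @export
plot.sta_result <- function(x, ...) {
  y <- if (!is.null(x$detrended_waveform)) x$detrended_waveform else
    x$mean_waveform
  graphics::plot(x$lags_ms, y, type = "l", xlab = "lag (ms)",
                 ylab = "rectified EMG", main = x$channel, ...)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

#' Smooth and detrend a spike-triggered average
#'
#' Applies a flat five-point finite-impulse-response smoother, then subtracts
#' the slow baseline trend estimated by the incremented-shifted-averages
#' method: STAs are recomputed with all triggers shifted by `+/- shifts_ms`
#' and their mean (smoothed identically) is taken as the trend.
#'
#' @param sta a `sta_result` from [compute_sta()].
#' @param emg the [emg_recording()] the STA was computed from.
#' @param shifts_ms positive shift magnitudes (ms); at least 2.
#' @return `sta` with added `smoothed_waveform`, `trend`,
#'   `detrended_waveform`, and detrended baseline statistics
#'   `dt_baseline_mean`/`dt_baseline_sd` (lags -30..-10 ms).
#' @export
smooth_and_detrend <- function(sta, emg, shifts_ms = c(10, 20, 30)) {
  if (length(shifts_ms) < 2) stop("need at least 2 shift magnitudes")
  x <- abs(emg_channel(emg, sta$channel))
  fs <- sta$sample_rate
  sm5 <- function(v) {
    s <- stats::filter(v, rep(1 / 5, 5), sides = 2)
    s[is.na(s)] <- v[is.na(s)]
    as.numeric(s)
  }
  smoothed <- sm5(sta$mean_waveform)
  shifted <- lapply(c(-shifts_ms, shifts_ms) / 1000, function(dt) {
    sg <- .segments(x, fs, sta$accepted_times + dt, emg$t0, sta$window_ms)
    sm5(colMeans(sg$segments))
  })
  trend <- Reduce(`+`, shifted) / length(shifted)
  det <- smoothed - trend
  bl <- sta$lags_ms >= -30 & sta$lags_ms <= -10
  det <- det - mean(det[bl])
  sta$smoothed_waveform <- smoothed
  sta$trend <- trend
  sta$detrended_waveform <- det
  sta$dt_baseline_mean <- mean(det[bl])
  sta$dt_baseline_sd <- stats::sd(det[bl])
  sta
}

#' Multiple-fragment significance test of an STA effect
#'
#' Splits the accepted triggers into `n_fragments` contiguous blocks, takes
#' each fragment's mean rectified EMG over the test window and over the
#' pre-trigger baseline window, and compares the paired per-fragment means
#' with a two-tailed paired t test.
#'
#' @param sta a `sta_result` (segments retained).
#' @param test_window_ms post-trigger test window (ms); the default is the
#'   12-ms window spanning 3--15 ms.
#' @param baseline_window_ms pre-trigger baseline window (ms).
#' @param n_fragments number of contiguous trigger blocks.
#' @param alpha significance threshold; the default is Bonferroni-corrected
#'   for 12 muscles.
#' @return list with `p_value`, `significant`, `statistic`, `n_fragments`,
#'   `fragment_test_means`, `fragment_baseline_means`, `alpha`.
#' @export
fragment_significance <- function(sta, test_window_ms = c(3, 15),
                                  baseline_window_ms = c(-30, -10),
                                  n_fragments = 20, alpha = 0.05 / 12) {
  n <- nrow(sta$segments)
  per <- n %/% n_fragments
  if (per < 20)
    stop(sprintf("only %d triggers per fragment (< 20)", per))
  tw <- sta$lags_ms >= test_window_ms[1] & sta$lags_ms <= test_window_ms[2]
  bw <- sta$lags_ms >= baseline_window_ms[1] &
    sta$lags_ms <= baseline_window_ms[2]
  frag <- rep(seq_len(n_fragments), each = per)
  idx <- seq_len(n_fragments * per)
  tm <- tapply(rowMeans(sta$segments[idx, tw, drop = FALSE]), frag, mean)
  bm <- tapply(rowMeans(sta$segments[idx, bw, drop = FALSE]), frag, mean)
  d <- tm - bm
  if (stats::sd(d) < 1e-12 * (abs(mean(tm)) + 1e-300)) {
    p <- 1; stat <- 0
  } else {
    tt <- stats::t.test(tm, bm, paired = TRUE)
    p <- tt$p.value; stat <- unname(tt$statistic)
  }
  list(p_value = p, significant = p < alpha, statistic = stat,
       n_fragments = n_fragments, fragment_test_means = as.numeric(tm),
       fragment_baseline_means = as.numeric(bm), alpha = alpha)
}

# first index of a run of length >= len in logical vector v, NA if none
.first_run <- function(v, len) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= len)
  if (!length(hit)) return(NA_integer_)
  ends[hit[1]] - r$lengths[hit[1]] + 1L
}

# lag (ms) where y crosses `half` between samples, linearly interpolated,
# scanning from index i in direction dir until the crossing
.interp_cross <- function(lags, y, half, i, dir) {
  j <- i
  while (j + dir >= 1 && j + dir <= length(y) && y[j + dir] > half) j <- j + dir
  if (j + dir < 1 || j + dir > length(y)) return(lags[j])
  y0 <- y[j]; y1 <- y[j + dir]
  lags[j] + (lags[j + dir] - lags[j]) * (y0 - half) / (y0 - y1)
}

#' Measure a postspike effect from a detrended STA
#'
#' Onset is the first post-trigger lag at which the detrended waveform
#' exceeds the baseline by `k_sd` baseline SDs (in the peak's direction) for
#' at least `sustain_ms`; the peak is the extremum in the test window; PWHM
#' is the width at half of the peak height (linearly interpolated); the
#' magnitude is the peak height as a percentage of the raw pre-trigger
#' baseline mean.
#'
#' @param sta a detrended `sta_result` (see [smooth_and_detrend()]).
#' @param test_window_ms window searched for the peak (ms).
#' @param k_sd onset threshold in baseline SDs.
#' @param sustain_ms minimum supra-threshold duration for onset (ms).
#' @return Object of class `postspike_effect`: list with `muscle`, `sign`
#'   (`"facilitation"`/`"suppression"`), `onset_ms`, `peak_ms`, `pwhm_ms`,
#'   `magnitude_pct`, `label` (`"none"` until classified).  When no
#'   sustained crossing is found, `label` is `"none"` and the latencies are
#'   `NA`.
#' @export
measure_effect <- function(sta, test_window_ms = c(3, 15), k_sd = 2,
                           sustain_ms = 0.5) {
  if (is.null(sta$detrended_waveform))
    stop("detrend the STA first (smooth_and_detrend)")
  y <- sta$detrended_waveform
  lags <- sta$lags_ms
  tw <- lags >= test_window_ms[1] & lags <= test_window_ms[2]
  pk_i <- which(tw)[which.max(abs(y[tw]))]
  pk <- y[pk_i]
  sgn <- if (pk >= 0) "facilitation" else "suppression"
  thr <- k_sd * sta$dt_baseline_sd
  post <- which(lags > 0 & lags <= max(lags))
  above <- if (pk >= 0) y[post] > thr else y[post] < -thr
  need <- max(1L, ceiling(sustain_ms * sta$sample_rate / 1000))
  i_on <- .first_run(above, need)
  none <- structure(list(muscle = sta$channel, sign = sgn, onset_ms = NA_real_,
                         peak_ms = NA_real_, pwhm_ms = NA_real_,
                         magnitude_pct = NA_real_, p_value = NA_real_,
                         label = "none"), class = "postspike_effect")
  if (is.na(i_on)) return(none)
  onset <- lags[post[i_on]]
  half <- abs(pk) / 2
  ay <- if (pk >= 0) y else -y   # effect-direction waveform
  left <- .interp_cross(lags, ay, half, pk_i, -1L)
  right <- .interp_cross(lags, ay, half, pk_i, +1L)
  pwhm <- right - left
  structure(list(muscle = sta$channel, sign = sgn, onset_ms = onset,
                 peak_ms = lags[pk_i], pwhm_ms = pwhm,
                 magnitude_pct = 100 * pk / sta$baseline_mean,
                 p_value = NA_real_, label = "unclassified"),
            class = "postspike_effect")
}

#' @export
print.postspike_effect <- function(x, ...) {
  cat(sprintf(
    "<postspike_effect> %s %s: onset %.2f ms, PWHM %.2f ms, %.1f%% [%s]\n",
    x$muscle, x$sign, x$onset_ms, x$pwhm_ms, x$magnitude_pct, x$label))
  invisible(x)
}

#' Classify a measured effect as postspike effect or synchrony
#'
#' A measured effect is a postspike effect (PSE, i.e. attributable to a
#' direct synaptic linkage) when its onset latency exceeds `onset_min_ms`
#' and its peak width at half-maximum is below `pwhm_max_ms`; otherwise it
#' is labeled a synchrony effect.
#'
#' @param effect a `postspike_effect` from [measure_effect()].
#' @param onset_min_ms minimum onset latency (ms).
#' @param pwhm_max_ms maximum PWHM (ms).
#' @return `effect` with `label` set to `"PSE"`, `"synchrony"`, or `"none"`.
#' @export
classify_effect <- function(effect, onset_min_ms = 3.5, pwhm_max_ms = 7) {
  if (is.na(effect$onset_ms)) { effect$label <- "none"; return(effect) }
  effect$label <- if (effect$onset_ms > onset_min_ms &&
                      effect$pwhm_ms < pwhm_max_ms) "PSE" else "synchrony"
  effect
}

#' Screen a channel pair for EMG crosstalk
#'
#' Flags crosstalk when (i) the peak of the normalized cross-correlation of
#' the unrectified channels within `max_lag_ms` exceeds `r_threshold`, and
#' (ii) STAs recomputed on third-differenced EMG show a narrow near-zero-lag
#' peak in both channels.  The narrowness bound defaults to the width of a
#' motor-unit waveform (3 ms): genuine cross-channel leakage of the same
#' motor units cannot be wider than the units themselves.
#'
#' @param emg an [emg_recording()].
#' @param channel_a,channel_b muscle names.
#' @param spikes a [spike_train()] used for the differentiated-STA check.
#' @param max_lag_ms cross-correlation search lag (ms).
#' @param r_threshold correlation threshold.
#' @param narrow_ms maximum half-maximum width of the differentiated-STA
#'   peak (ms).
#' @return list with `flag` and the diagnostics `peak_correlation`,
#'   `sta_peak_narrow_a`, `sta_peak_narrow_b`.
#' @export
screen_crosstalk <- function(emg, channel_a, channel_b, spikes,
                             max_lag_ms = 1, r_threshold = 0.3,
                             narrow_ms = 3) {
  a <- emg_channel(emg, channel_a)
  b <- emg_channel(emg, channel_b)
  fs <- emg$sample_rate
  ml <- max(1L, round(max_lag_ms * fs / 1000))
  cc <- stats::ccf(a, b, lag.max = ml, plot = FALSE)
  peak_r <- max(abs(cc$acf))
  narrow <- function(x) {
    d3 <- diff(x, differences = 3)
    st <- tryCatch(
      compute_sta(spikes, emg_recording(matrix(abs(d3)),
                                        fs,
                                        data.frame(muscle = "d3",
                                                   role = "extensor",
                                                   target = FALSE),
                                        t0 = emg$t0 + 1.5 / fs),
                  "d3", window_ms = c(-10, 10), min_triggers = 2,
                  noise_rms = 0),
      error = function(e) NULL)
    if (is.null(st)) return(FALSE)
    y <- st$mean_waveform - stats::median(st$mean_waveform)
    pk <- which.max(y)
    if (abs(st$lags_ms[pk]) > 1) return(FALSE)
    half <- y[pk] / 2
    w <- sum(y > half) / fs * 1000
    w < narrow_ms
  }
  na <- narrow(a); nb <- narrow(b)
  list(flag = peak_r > r_threshold && na && nb,
       peak_correlation = peak_r,
       sta_peak_narrow_a = na, sta_peak_narrow_b = nb)
}

#' Screen a neuron for a motor-unit signature
#'
#' Putative motoneurons reveal themselves by a large unrectified-EMG STA
#' peak with as few as 50 trigger spikes.
#'
#' @param spikes a [spike_train()]; at least `n_spikes` required.
#' @param emg an [emg_recording()] (unrectified).
#' @param channel muscle name.
#' @param n_spikes number of spikes used (first `n_spikes`).
#' @param k_sd flag threshold in baseline SDs of the unrectified STA.
#' @return list with `flag`, `peak_sd_ratio`.
#' @export
screen_motor_unit <- function(spikes, emg, channel, n_spikes = 50, k_sd = 5) {
  st <- as.numeric(spikes)
  if (length(st) < n_spikes)
    stop(sprintf("need at least %d spikes", n_spikes))
  x <- emg_channel(emg, channel)
  sg <- .segments(x, emg$sample_rate, st[seq_len(n_spikes)], emg$t0,
                  c(-50, 50))
  mw <- colMeans(sg$segments)
  bl <- sg$lags_ms >= -30 & sg$lags_ms <= -10
  bsd <- stats::sd(mw[bl])
  post <- sg$lags_ms >= -2 & sg$lags_ms <= 10
  ratio <- max(abs(mw[post] - mean(mw[bl]))) / bsd
  list(flag = is.finite(ratio) && ratio > k_sd, peak_sd_ratio = ratio)
}

#' Categorize a neuron from its input and output profile
#'
#' Combines the monosynaptic-input flag with the PSE-labeled postspike
#' effects: a neuron whose only PSE target muscles are wrist extensors is
#' `autogenic`, only flexors `heterogenetic`, both `both`; polarity follows
#' the effect signs.  An autogenic, excitatory neuron with monosynaptic
#' input is an agIN.
#'
#' @param monosynaptic_input logical: putative monosynaptic afferent input.
#' @param central_latency_ms central latency (ms), or `NA`.
#' @param effects list of classified `postspike_effect`s.
#' @param channel_meta data.frame mapping `muscle` to `role`.
#' @return Object of class `neuron_classification`: list with
#'   `monosynaptic_input`, `central_latency_ms`, `effects`, `pattern`,
#'   `polarity`, `is_agIN`.
#' @export
classify_neuron <- function(monosynaptic_input, central_latency_ms,
                            effects, channel_meta) {
  pse <- Filter(function(e) identical(e$label, "PSE"), effects)
  if (!length(pse)) {
    pattern <- "none"; polarity <- "none"
  } else {
    roles <- vapply(pse, function(e)
      channel_meta$role[match(e$muscle, channel_meta$muscle)], character(1))
    pattern <- if (all(roles == "extensor")) "autogenic"
    else if (all(roles == "flexor")) "heterogenetic" else "both"
    signs <- vapply(pse, function(e) e$sign, character(1))
    polarity <- if (all(signs == "facilitation")) "excitatory"
    else if (all(signs == "suppression")) "inhibitory" else "mixed"
  }
  structure(list(monosynaptic_input = isTRUE(monosynaptic_input),
                 central_latency_ms = central_latency_ms,
                 effects = effects, pattern = pattern, polarity = polarity,
                 is_agIN = isTRUE(monosynaptic_input) &&
                   pattern == "autogenic" && polarity == "excitatory"),
            class = "neuron_classification")
}

#' @export
print.neuron_classification <- function(x, ...) {
  cat(sprintf(
    "<neuron_classification> mono=%s pattern=%s polarity=%s agIN=%s\n",
    x$monosynaptic_input, x$pattern, x$polarity, x$is_agIN))
  invisible(x)
}
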