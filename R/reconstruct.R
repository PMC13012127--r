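# Reconstruction of a muscle's task EMG from a single interneuron: the
# postspike-effect snippet (first 15 ms of the detrended STA) convolved with
# the movement-aligned PETH, compared with the trial-averaged original EMG
# by correlation and area ratio, and the neurons-needed extrapolation.

#' Extract the postspike-effect snippet from a detrended STA
#'
#' The snippet is the detrended, baseline-subtracted STA over lags
#' `(0, 15]` ms — the per-spike contribution of the neuron to its target
#' muscle.  If the waveform is still at more than half its extreme value at
#' the 15-ms edge the snippet is flagged as truncated.
#'
#' @param sta a detrended `sta_result` (see [smooth_and_detrend()]).
#' @param length_ms snippet length (ms).
#' @return Object of class `sta_snippet`: `values` (EMG units),
#'   `lags_ms`, `sample_rate`, `truncated`.
#' @export
extract_snippet <- function(sta, length_ms = 15) {
  if (is.null(sta$detrended_waveform))
    stop("detrend the STA first (smooth_and_detrend)")
  if (max(sta$lags_ms) < length_ms)
    stop(sprintf("STA window shorter than %g ms", length_ms))
  sel <- sta$lags_ms > 0 & sta$lags_ms <= length_ms
  v <- sta$detrended_waveform[sel]
  trunc_flag <- length(v) > 0 && abs(v[length(v)]) > 0.5 * max(abs(v))
  structure(list(values = v, lags_ms = sta$lags_ms[sel],
                 sample_rate = sta$sample_rate, truncated = trunc_flag),
            class = "sta_snippet")
}

#' Movement-aligned peri-event time histogram of firing rate
#'
#' @param spikes a [spike_train()].
#' @param movement_onsets per-trial alignment times (s); at least 10.
#' @param bin_ms bin width (ms).
#' @param window_ms window around the alignment time (ms).
#' @return Object of class `peth`: `bin_edges_ms`, `rate_hz`
#'   (spikes/s averaged over trials), `n_trials`, `bin_ms`.
#' @export
compute_peth <- function(spikes, movement_onsets, bin_ms = 5,
                         window_ms = c(-500, 2000)) {
  movement_onsets <- movement_onsets[!is.na(movement_onsets)]
  if (!length(movement_onsets)) stop("no alignment trials")
  if (length(movement_onsets) < 10) stop("need at least 10 trials")
  st <- as.numeric(spikes)
  edges <- seq(window_ms[1], window_ms[2], by = bin_ms)
  rel <- unlist(lapply(movement_onsets, function(o) {
    d <- (st - o) * 1000
    d[d >= window_ms[1] & d < window_ms[2]]
  }))
  counts <- as.numeric(table(cut(rel, edges, right = FALSE)))
  structure(list(bin_edges_ms = edges,
                 rate_hz = counts / length(movement_onsets) / (bin_ms / 1000),
                 n_trials = length(movement_onsets), bin_ms = bin_ms),
            class = "peth")
}

#' Upsample a PETH to the EMG sampling grid
#'
#' Zero-order hold to the EMG rate followed by a boxcar smoother one PETH
#' bin wide, preserving bin areas.
#'
#' @param peth a `peth`.
#' @param sample_rate target rate (Hz).
#' @return numeric rate series (spikes/s) on the EMG grid covering the PETH
#'   window.
#' @export
upsample_peth <- function(peth, sample_rate) {
  per <- round(peth$bin_ms / 1000 * sample_rate)
  r <- rep(peth$rate_hz, each = per)
  box <- rep(1 / per, per)
  .place_waveform(r, box, centered = TRUE)
}

#' Reconstruct EMG by convolving a PETH with a postspike-effect snippet
#'
#' The PETH (spikes/s) is upsampled to the EMG grid and linearly convolved
#' with the snippet, scaled by the sample duration, so the output estimates
#' the EMG generated if every spike contributed one snippet.
#'
#' @param peth a `peth` from [compute_peth()].
#' @param snippet a `sta_snippet` from [extract_snippet()] (or a numeric
#'   waveform at the EMG rate).
#' @param sample_rate EMG sampling rate (Hz); defaults to the snippet's.
#' @return Object of class `emg_reconstruction`: `values` (EMG units),
#'   `time_ms` (relative to the alignment event), `sample_rate`.
#' @export
reconstruct_emg <- function(peth, snippet, sample_rate = NULL) {
  v <- if (inherits(snippet, "sta_snippet")) snippet$values else
    as.numeric(snippet)
  if (!length(v)) stop("empty snippet")
  if (is.null(sample_rate))
    sample_rate <- if (inherits(snippet, "sta_snippet")) snippet$sample_rate
    else stop("sample_rate required for a bare snippet")
  up <- upsample_peth(peth, sample_rate)
  full <- .conv_open(up, v) / sample_rate
  t0 <- peth$bin_edges_ms[1]
  structure(list(values = full,
                 time_ms = t0 + (seq_along(full) - 1) / sample_rate * 1000,
                 sample_rate = sample_rate),
            class = "emg_reconstruction")
}

#' Trial-averaged smoothed EMG aligned to an event
#'
#' Rectifies the channel, averages across trial-aligned segments, and
#' applies a boxcar smoother (default 5 ms) — the original-EMG trace a
#' reconstruction is compared against.
#'
#' @param emg an [emg_recording()].
#' @param channel muscle name.
#' @param onsets alignment times (s).
#' @param window_ms window (ms).
#' @param smooth_ms boxcar width (ms); 0 disables.
#' @return list with `values`, `time_ms`, `sample_rate`, `n_trials`.
#' @export
average_aligned_emg <- function(emg, channel, onsets, window_ms = c(-500, 2000),
                                smooth_ms = 5) {
  onsets <- onsets[!is.na(onsets)]
  x <- abs(emg_channel(emg, channel))
  sg <- .segments(x, emg$sample_rate, onsets, emg$t0, window_ms)
  avg <- colMeans(sg$segments)
  if (smooth_ms > 0) {
    per <- max(1L, round(smooth_ms / 1000 * emg$sample_rate))
    avg <- .place_waveform(avg, rep(1 / per, per), centered = TRUE)
  }
  list(values = avg, time_ms = sg$lags_ms, sample_rate = emg$sample_rate,
       n_trials = nrow(sg$segments))
}

#' Compare a reconstruction with the original EMG over the burst
#'
#' Pearson correlation over the samples between the burst onset and offset,
#' and the reconstructed area as a percentage of the original burst area
#' (both baseline-subtracted, baseline taken before the burst onset).
#'
#' @param recon an `emg_reconstruction`.
#' @param original list with `values` and `time_ms` on the same alignment
#'   (see [average_aligned_emg()]).
#' @param burst_window_ms numeric `c(onset, offset)` in ms relative to the
#'   alignment event (from burst detection on the original).
#' @param min_span_ms minimum burst span.
#' @return list with `R`, `area_ratio_pct`, `n_points`.
#' @export
compare_to_original <- function(recon, original, burst_window_ms,
                                min_span_ms = 50) {
  if (diff(burst_window_ms) < min_span_ms)
    stop("degenerate burst (shorter than minimum span)")
  sel_r <- recon$time_ms >= burst_window_ms[1] &
    recon$time_ms <= burst_window_ms[2]
  sel_o <- original$time_ms >= burst_window_ms[1] &
    original$time_ms <= burst_window_ms[2]
  n <- min(sum(sel_r), sum(sel_o))
  r <- recon$values[which(sel_r)[seq_len(n)]]
  o <- original$values[which(sel_o)[seq_len(n)]]
  base_r <- mean(recon$values[recon$time_ms < burst_window_ms[1]])
  base_o <- mean(original$values[original$time_ms < burst_window_ms[1]])
  if (!is.finite(base_r)) base_r <- 0
  if (!is.finite(base_o)) base_o <- 0
  R <- stats::cor(r, o)
  area_r <- sum(r - base_r)
  area_o <- sum(o - base_o)
  list(R = R, area_ratio_pct = 100 * area_r / area_o, n_points = n)
}

#' Neurons needed to generate the full EMG
#'
#' Extrapolates from the mean single-neuron area ratio (percent of the
#' original burst area) to the number of identical neurons that would
#' account for 100% of it.
#'
#' @param mean_area_ratio_pct mean area ratio (percent), > 0.
#' @return integer `round(100 / ratio)`.
#' @export
neurons_needed <- function(mean_area_ratio_pct) {
  if (mean_area_ratio_pct <= 0) stop("area ratio must be > 0")
  as.integer(round(100 / mean_area_ratio_pct))
}
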