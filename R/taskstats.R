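# Task-level statistics: EMG envelope extraction, burst onset/offset
# detection and metrics, normalized-rank histograms with exact binomial
# top-bin bias tests, epoch firing rates with the direction-bias test, the
# success-vs-error gain comparison, and movement-aligned firing-onset
# latency.

#' Band-pass, rectify, and low-pass an EMG channel
#'
#' Zero-phase 4th-order Butterworth band-pass (50--200 Hz), full-wave
#' rectification, then a zero-phase low-pass (5 Hz) that embosses the burst
#' envelope.  Zero-phase filtering keeps onset estimates free of group
#' delay.
#'
#' @param x raw EMG samples.
#' @param sample_rate Hz; must be at least 500 so the band edges fit.
#' @param band band-pass edges (Hz).
#' @param lowpass envelope low-pass cutoff (Hz).
#' @return numeric envelope (nonnegative up to filter ringing).
#' @export
preprocess_emg <- function(x, sample_rate, band = c(50, 200), lowpass = 5) {
  if (sample_rate < 500)
    stop("sample_rate too low for the 50-200 Hz band (need >= 500 Hz)")
  bp <- signal::butter(4, band / (sample_rate / 2), type = "pass")
  x1 <- abs(signal::filtfilt(bp, x))
  # second-order envelope smoother: higher orders pre-ring tens of ms
  # around burst edges and bias onset estimates
  lp <- signal::butter(2, lowpass / (sample_rate / 2), type = "low")
  as.numeric(signal::filtfilt(lp, x1))
}

# mean and SD of an envelope within [t0, t1)
.env_stats <- function(env, sample_rate, t0, t1, emg_t0 = 0) {
  i0 <- max(1L, floor((t0 - emg_t0) * sample_rate) + 1L)
  i1 <- min(length(env), floor((t1 - emg_t0) * sample_rate))
  seg <- env[i0:i1]
  list(mean = mean(seg), sd = stats::sd(seg))
}

#' Detect the task EMG burst of one trial
#'
#' Onset is the start of the first run of at least `onset_run_s` during
#' which the envelope exceeds the rest-epoch mean by 2 SD, beginning no
#' later than shortly after movement onset.  The offset follows the chosen
#' variant: `"hold"` takes the end of the last run of at least
#' `offset_run_s` above mean + 1 SD, searched up to
#' `movement_onset + search_s`; `"sharp_drop"` takes the local envelope
#' peak followed by the steepest drop to the next local peak.
#'
#' @param env preprocessed envelope ([preprocess_emg()]).
#' @param sample_rate Hz.
#' @param rest_stats list with `mean` and `sd` of the envelope in the rest
#'   epoch (see [.env_stats] via [burst_table()]).
#' @param movement_onset movement onset time (s).
#' @param variant `"hold"` or `"sharp_drop"`.
#' @param search_start search start (s; default trial-relative 0).
#' @param search_s offset search bound after movement onset (s).
#' @param onset_run_s,offset_run_s minimum supra-threshold run lengths (s).
#' @param emg_t0 time of the first envelope sample (s).
#' @return list of class `emg_burst` with `onset_time`, `offset_time`,
#'   `duration`, `mean_amplitude`, `peak_amplitude`, or `NULL` when no
#'   qualifying onset exists.
#' @export
detect_burst <- function(env, sample_rate, rest_stats, movement_onset,
                         variant = c("hold", "sharp_drop"),
                         search_start = 0, search_s = 1.8,
                         onset_run_s = 0.05, offset_run_s = 0.2,
                         emg_t0 = 0) {
  variant <- match.arg(variant)
  fs <- sample_rate
  thr_on <- rest_stats$mean + 2 * rest_stats$sd
  thr_off <- rest_stats$mean + 1 * rest_stats$sd
  i_lo <- max(1L, floor((search_start - emg_t0) * fs) + 1L)
  i_mo <- floor((movement_onset - emg_t0) * fs) + 1L
  i_hi <- min(length(env), i_mo + round(search_s * fs))
  seg <- env[i_lo:i_hi]
  above <- seg > thr_on
  i_on <- .first_run(above, max(1L, round(onset_run_s * fs)))
  # the burst must begin before (or just at) movement onset
  if (is.na(i_on) || (i_lo + i_on - 1L) > i_mo + round(0.1 * fs))
    return(NULL)
  on_idx <- i_lo + i_on - 1L
  if (variant == "hold") {
    seg2 <- env[on_idx:i_hi] > thr_off
    r <- rle(seg2)
    need <- round(offset_run_s * fs)
    runs <- which(r$values & r$lengths >= need)
    if (!length(runs)) return(NULL)
    ends <- cumsum(r$lengths)
    off_idx <- on_idx + ends[runs[length(runs)]] - 1L
  } else {
    w <- env[on_idx:i_hi]
    d <- diff(w)
    pk <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L   # local maxima
    if (length(pk) < 2) {
      off_idx <- on_idx + (if (length(pk)) pk[1] else which.max(w)) - 1L
    } else {
      drops <- w[pk[-length(pk)]] - w[pk[-1]]
      off_idx <- on_idx + pk[which.max(drops)] - 1L
    }
  }
  onset_t <- emg_t0 + (on_idx - 1L) / fs
  offset_t <- emg_t0 + (off_idx - 1L) / fs
  span <- env[on_idx:off_idx]
  structure(list(onset_time = onset_t, offset_time = offset_t,
                 duration = offset_t - onset_t,
                 mean_amplitude = mean(span), peak_amplitude = max(span)),
            class = "emg_burst")
}

#' Per-trial burst table for one muscle
#'
#' Preprocesses the channel once, pools the rest-epoch statistics over the
#' session's trials, and detects the burst of each movement trial.
#'
#' @param session an `ag_session` (or any list with `emg` and `trials`).
#' @param channel muscle name.
#' @param variant offset variant, see [detect_burst()].
#' @return data.frame with `trial_id`, `direction`, `outcome`, `onset_s`,
#'   `offset_s`, `duration_s`, `mean_amp`, `peak_amp` (NA rows for trials
#'   without a detected burst).
#' @export
burst_table <- function(session, channel, variant = "hold") {
  emg <- session$emg
  env <- preprocess_emg(emg_channel(emg, channel), emg$sample_rate)
  tr <- session$trials
  rs <- lapply(seq_len(nrow(tr)), function(i)
    .env_stats(env, emg$sample_rate, tr$rest_start[i], tr$cue_on[i], emg$t0))
  rest <- list(mean = mean(vapply(rs, `[[`, 0, "mean")),
               sd = mean(vapply(rs, `[[`, 0, "sd")))
  out <- data.frame(trial_id = tr$trial_id, direction = tr$direction,
                    outcome = tr$outcome, onset_s = NA_real_,
                    offset_s = NA_real_, duration_s = NA_real_,
                    mean_amp = NA_real_, peak_amp = NA_real_)
  for (i in seq_len(nrow(tr))) {
    if (is.na(tr$movement_onset[i])) next
    b <- detect_burst(env, emg$sample_rate, rest, tr$movement_onset[i],
                      variant, search_start = tr$go[i], emg_t0 = emg$t0)
    if (is.null(b)) next
    out[i, c("onset_s", "offset_s", "duration_s", "mean_amp", "peak_amp")] <-
      c(b$onset_time, b$offset_time, b$duration, b$mean_amplitude,
        b$peak_amplitude)
  }
  out
}

#' Normalized within-session ranks
#'
#' Ascending rank divided by the number of trials in each session, so ranks
#' lie on `{1/n, ..., 1}` and pooled sessions of different sizes are
#' comparable.  Ties are broken by stable trial order.
#'
#' @param values numeric vector (one per trial).
#' @param session factor-like session/day identifier (single session when
#'   omitted).
#' @return numeric ranks in `(0, 1]`.
#' @export
normalized_rank <- function(values, session = NULL) {
  if (is.null(session)) session <- rep(1L, length(values))
  out <- numeric(length(values))
  for (s in unique(session)) {
    i <- which(session == s)
    if (!length(i)) next
    out[i] <- rank(values[i], ties.method = "first") / length(i)
  }
  out
}

#' Rank histogram with an exact binomial top-bin bias test
#'
#' Histograms normalized ranks into ten bins of width 0.1 and tests whether
#' the top bin (`rank > 0.9`) is over-represented relative to the uniform
#' baseline probability 0.1, with the exact one-tailed binomial tail
#' probability `P(X >= k | n, 0.1)`.
#'
#' @param ranks normalized ranks in `(0, 1]` (e.g. the ranks of one gain
#'   label's trials).
#' @return Object of class `rank_histogram`: `bin_edges`, `counts`, `n`,
#'   `baseline_probability`, `top_bin_count`, `top_bin_p`.
#' @export
rank_bias_test <- function(ranks) {
  if (!length(ranks)) stop("empty rank subset")
  edges <- seq(0, 1, by = 0.1)
  counts <- as.numeric(table(cut(ranks, edges, right = TRUE,
                                 include.lowest = FALSE)))
  n <- length(ranks)
  k <- counts[10]
  p <- stats::pbinom(k - 1, n, 0.1, lower.tail = FALSE)
  structure(list(bin_edges = edges, counts = counts, n = n,
                 baseline_probability = 0.1, top_bin_count = k,
                 top_bin_p = p),
            class = "rank_histogram")
}

#' @export
print.rank_histogram <- function(x, ...) {
  cat(sprintf("<rank_histogram> n=%d, top bin %d (P(X>=k|p=0.1) = %.4g)\n",
              x$n, x$top_bin_count, x$top_bin_p))
  invisible(x)
}

#' Mean firing rate in each task epoch
#'
#' @param spikes a [spike_train()].
#' @param trials trial table.
#' @param epochs epochs summarized.
#' @return data.frame with `direction`, `epoch`, `rate_hz`, `total_time_s`,
#'   `n_trials`.
#' @export
epoch_firing_rates <- function(spikes, trials,
                               epochs = c("rest", "cue", "delay",
                                          "active_movement", "active_hold",
                                          "passive_movement")) {
  st <- as.numeric(spikes)
  out <- expand.grid(direction = unique(trials$direction), epoch = epochs,
                     stringsAsFactors = FALSE)
  out$rate_hz <- NA_real_; out$total_time_s <- 0; out$n_trials <- 0L
  for (r in seq_len(nrow(out))) {
    tr <- trials[trials$direction == out$direction[r], , drop = FALSE]
    tot_t <- 0; tot_n <- 0; ntr <- 0L
    for (i in seq_len(nrow(tr))) {
      ep <- trial_epochs(tr[i, ])
      ep <- ep[ep$epoch == out$epoch[r], , drop = FALSE]
      if (!nrow(ep)) next
      tot_t <- tot_t + (ep$end - ep$start)
      tot_n <- tot_n + sum(st >= ep$start & st < ep$end)
      ntr <- ntr + 1L
    }
    out$total_time_s[r] <- tot_t; out$n_trials[r] <- ntr
    if (tot_t > 0) out$rate_hz[r] <- tot_n / tot_t
  }
  out
}

# per-trial movement+hold firing rate of one direction
.movement_rates <- function(spikes, trials, direction) {
  st <- as.numeric(spikes)
  tr <- trials[trials$direction == direction &
                 !is.na(trials$movement_onset) &
                 !is.na(trials$release_go), , drop = FALSE]
  if (!nrow(tr)) stop(sprintf("no complete trials in direction '%s'",
                              direction))
  vapply(seq_len(nrow(tr)), function(i) {
    a <- tr$movement_onset[i]; b <- tr$release_go[i]
    sum(st >= a & st < b) / (b - a)
  }, numeric(1))
}

#' Direction bias of one neuron
#'
#' Compares per-trial firing rates over the movement + hold epochs between
#' extension and flexion trials (two-sided Welch t test at `alpha`).
#'
#' @param spikes a [spike_train()].
#' @param trials trial table with success trials in both directions.
#' @param alpha per-neuron significance level.
#' @return list with `bias` (`"extension"`, `"flexion"`, `"unbiased"`),
#'   `p_value`, `rate_extension`, `rate_flexion`.
#' @export
direction_bias <- function(spikes, trials, alpha = 0.05) {
  re <- .movement_rates(spikes, trials, "extension")
  rf <- .movement_rates(spikes, trials, "flexion")
  if (stats::sd(c(re, rf)) < 1e-12) {
    p <- 1
  } else {
    p <- stats::t.test(re, rf)$p.value
  }
  bias <- if (p >= alpha) "unbiased"
  else if (mean(re) > mean(rf)) "extension" else "flexion"
  list(bias = bias, p_value = p, rate_extension = mean(re),
       rate_flexion = mean(rf))
}

#' Population direction-bias binomial test
#'
#' One-tailed exact binomial test that more neurons are biased toward
#' extension than expected by chance (p = 1/2), with unbiased neurons
#' excluded from `n`.
#'
#' @param biases character vector of per-neuron labels
#'   (`"extension"`, `"flexion"`, `"unbiased"`).
#' @return list with `n_extension`, `n_flexion`, `n_biased`, `p_value`
#'   (exact tail `P(X >= n_extension | n_biased, 0.5)`).
#' @export
direction_bias_test <- function(biases) {
  ne <- sum(biases == "extension")
  nf <- sum(biases == "flexion")
  n <- ne + nf
  p <- if (n == 0) NA_real_ else
    stats::pbinom(ne - 1, n, 0.5, lower.tail = FALSE)
  list(n_extension = ne, n_flexion = nf, n_biased = n, p_value = p)
}

#' Paired comparison of afferent gain on successful vs short-hold trials
#'
#' Two-tailed paired t test of per-neuron (success, short-hold) response
#' probabilities.
#'
#' @param success,short_hold numeric vectors, one entry per neuron.
#' @return list with `mean_success`, `mean_short_hold`, `mean_difference`,
#'   `statistic`, `p_value`, `n`, `n_smaller_on_error`.
#' @export
compare_gain_success_error <- function(success, short_hold) {
  if (length(success) != length(short_hold))
    stop("paired vectors must have equal length")
  n <- length(success)
  if (n < 2) stop("need at least 2 neuron pairs")
  d <- success - short_hold
  if (stats::sd(d) < 1e-12) {
    p <- if (abs(mean(d)) < 1e-12) 1 else 0
    stat <- if (abs(mean(d)) < 1e-12) 0 else Inf * sign(mean(d))
  } else {
    tt <- stats::t.test(success, short_hold, paired = TRUE)
    p <- tt$p.value; stat <- unname(tt$statistic)
  }
  list(mean_success = mean(success), mean_short_hold = mean(short_hold),
       mean_difference = mean(d), statistic = stat, p_value = p, n = n,
       n_smaller_on_error = sum(d > 0))
}

#' Firing-onset latency relative to EMG onset
#'
#' Aligns the spike train to each trial's EMG burst onset, builds a
#' peri-event histogram with 10-ms bins, and takes the left edge of the
#' first bin exceeding the baseline mean by 2 SD for two consecutive bins.
#'
#' @param spikes a [spike_train()].
#' @param burst_onsets per-trial EMG onset times (s); at least 10.
#' @param bin_ms bin width (ms).
#' @param window_ms histogram window around EMG onset (ms).
#' @param baseline_ms baseline window (ms, relative to EMG onset).
#' @return list with `latency_ms` (`NA` when no rate increase), `rates_hz`,
#'   `bin_edges_ms`.
#' @export
firing_onset_latency <- function(spikes, burst_onsets, bin_ms = 10,
                                 window_ms = c(-500, 500),
                                 baseline_ms = c(-500, -200)) {
  burst_onsets <- burst_onsets[!is.na(burst_onsets)]
  if (length(burst_onsets) < 10) stop("need at least 10 trials")
  st <- as.numeric(spikes)
  edges <- seq(window_ms[1], window_ms[2], by = bin_ms)
  rel <- unlist(lapply(burst_onsets, function(o) {
    d <- (st - o) * 1000
    d[d >= window_ms[1] & d < window_ms[2]]
  }))
  counts <- as.numeric(table(cut(rel, edges, right = FALSE)))
  rates <- counts / length(burst_onsets) / (bin_ms / 1000)
  ctr <- edges[-length(edges)]
  bl <- ctr >= baseline_ms[1] & ctr < baseline_ms[2]
  bm <- mean(rates[bl]); bs <- stats::sd(rates[bl])
  cand <- which(ctr >= baseline_ms[2])
  above <- rates[cand] > bm + 2 * bs
  i_on <- .first_run(above, 2L)
  lat <- if (is.na(i_on)) NA_real_ else ctr[cand[i_on]]
  list(latency_ms = lat, rates_hz = rates, bin_edges_ms = edges)
}
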