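# Predicting interneuron spiking from preceding EMG: strictly causal lagged
# design (1..50 ms), sparse Bayesian linear regression with automatic
# relevance determination (ARD), per-muscle weight summaries, and trial-wise
# cross-validated decoding scores.

#' Build a strictly causal lagged design
#'
#' Bins the spike train into 1-ms counts over the supplied analysis
#' intervals (typically the extension movement epochs) and pairs each bin
#' with the preprocessed EMG of every muscle at lags 1..50 ms before it, so
#' no lag-0 or future EMG leaks into the predictors.
#'
#' @param env matrix of preprocessed EMG envelopes, time x muscle, sampled
#'   at `sample_rate` (see [preprocess_emg()]).
#' @param spikes a [spike_train()].
#' @param intervals data.frame with `start`, `end` (s) and an id column
#'   named by `id_col`; each interval must exceed the longest lag.
#' @param sample_rate envelope sampling rate (Hz).
#' @param bin_ms response bin width (ms).
#' @param lags_ms inclusive lag range (ms before the response bin).
#' @param t0 time of the first envelope sample (s).
#' @param id_col interval id column (used for trial-wise CV folds).
#' @return Object of class `lagged_design`: `X` (rows x (muscle, lag)
#'   columns, named `muscle.lagNN`), `y` (spike counts), `trial`
#'   (interval id per row), `muscles`, `lags_ms`, `bin_ms`.
#' @export
build_design <- function(env, spikes, intervals, sample_rate, bin_ms = 1,
                         lags_ms = c(1, 50), t0 = 0, id_col = "trial_id") {
  lag_seq <- seq(lags_ms[1], lags_ms[2])
  if (any(intervals$end - intervals$start <= max(lag_seq) / 1000))
    stop("analysis intervals shorter than the maximum lag")
  step <- sample_rate * bin_ms / 1000
  if (abs(step - round(step)) > 1e-9)
    stop("sample_rate must be a multiple of the bin rate")
  step <- as.integer(round(step))
  st <- as.numeric(spikes)
  muscles <- colnames(env)
  rows_X <- list(); rows_y <- list(); rows_id <- list()
  for (i in seq_len(nrow(intervals))) {
    a <- intervals$start[i]; b <- intervals$end[i]
    # bin left edges, leaving room for the deepest lag
    t_bins <- seq(a + max(lag_seq) / 1000, b - bin_ms / 1000, by = bin_ms / 1000)
    bin_s <- bin_ms / 1000
    sel <- st >= t_bins[1] & st < t_bins[length(t_bins)] + bin_s
    y <- tabulate(floor((st[sel] - t_bins[1]) / bin_s) + 1L,
                  nbins = length(t_bins))
    bin_idx <- round((t_bins - t0) * sample_rate) + 1L
    lag_idx <- round(lag_seq / 1000 * sample_rate)
    Xi <- matrix(0, length(t_bins), length(muscles) * length(lag_seq))
    for (m in seq_along(muscles)) {
      cols <- (m - 1L) * length(lag_seq) + seq_along(lag_seq)
      Xi[, cols] <- env[outer(bin_idx, lag_idx, `-`), m]
    }
    rows_X[[i]] <- Xi; rows_y[[i]] <- y
    rows_id[[i]] <- rep(as.character(intervals[[id_col]][i]), length(y))
  }
  X <- do.call(rbind, rows_X)
  colnames(X) <- as.vector(t(outer(muscles, lag_seq,
                                   function(m, l) sprintf("%s.lag%02d", m, l))))
  structure(list(X = X, y = unlist(rows_y), trial = unlist(rows_id),
                 muscles = muscles, lags_ms = lag_seq, bin_ms = bin_ms),
            class = "lagged_design")
}

#' @export
print.lagged_design <- function(x, ...) {
  cat(sprintf("<lagged_design> %d bins x %d (muscle, lag) columns, %d trials\n",
              nrow(x$X), ncol(x$X), length(unique(x$trial))))
  invisible(x)
}

#' Sparse Bayesian linear regression with automatic relevance determination
#'
#' Evidence-maximization (type-II maximum likelihood) updates of one prior
#' precision per column; columns whose precision diverges past the prune
#' threshold are removed and carry weight exactly 0.  Deterministic given
#' the data and initialization.  Columns are centered and standardized
#' internally so the precisions are scale-free; returned weights are on the
#' original scale.  Fixing `fixed_alpha` and `fixed_sigma2` disables the
#' updates and returns the closed-form penalized least-squares solution on
#' the standardized columns.
#'
#' @param design a `lagged_design`, or a list with `X` and `y`.
#' @param max_iter maximum update iterations.
#' @param tol convergence tolerance on the precision updates
#'   (max absolute change of `log(alpha)` over retained columns).
#' @param alpha_init initial per-column precision.
#' @param prune_rel prune a column when its precision exceeds
#'   `prune_rel / var(y)`.
#' @param fixed_alpha optional fixed uniform precision (disables ARD
#'   updates and pruning).
#' @param fixed_sigma2 optional fixed noise variance.
#' @return Object of class `sparse_model`: `weights` (full length, pruned
#'   columns exactly 0), `intercept`, `alpha`, `sigma2`, `iterations`,
#'   `converged`, `active` (logical), `muscles`, `lags_ms`.
#' @export
fit_ard <- function(design, max_iter = 300, tol = 1e-3, alpha_init = 1,
                    prune_rel = 1e6, fixed_alpha = NULL,
                    fixed_sigma2 = NULL) {
  X <- design$X; y <- design$y
  n <- nrow(X); p <- ncol(X)
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  # standardize columns so per-column precisions are scale-free
  # (constant columns stay at zero weight)
  xs <- apply(Xc, 2, stats::sd)
  xs[xs <= 0] <- 1
  Xc <- sweep(Xc, 2, xs, "/")
  yc <- y - ym
  vy <- stats::var(y)
  if (vy <= 0) vy <- 1
  XtX <- crossprod(Xc)
  Xty <- crossprod(Xc, yc)[, 1]
  fixed <- !is.null(fixed_alpha)
  alpha <- rep(if (fixed) fixed_alpha else alpha_init, p)
  sigma2 <- if (!is.null(fixed_sigma2)) fixed_sigma2 else vy
  active <- rep(TRUE, p)
  mu_full <- numeric(p)
  a_max <- prune_rel / vy
  converged <- FALSE
  it <- 0
  repeat {
    it <- it + 1
    ia <- which(active)
    if (!length(ia)) { converged <- TRUE; break }
    A <- XtX[ia, ia, drop = FALSE] / sigma2
    diag(A) <- diag(A) + alpha[ia]
    Sigma <- solve(A)
    mu <- (Sigma %*% Xty[ia])[, 1] / sigma2
    if (fixed) {
      mu_new <- numeric(p); mu_new[ia] <- mu
      mu_full <- mu_new; converged <- TRUE
      break
    }
    gamma <- 1 - alpha[ia] * diag(Sigma)
    alpha_new <- pmax(gamma, 1e-12) / pmax(mu^2, 1e-300)
    resid <- yc - Xc[, ia, drop = FALSE] %*% mu
    if (is.null(fixed_sigma2))
      sigma2 <- max(sum(resid^2) / max(n - sum(gamma), 1), 1e-12 * vy)
    delta <- max(abs(log(alpha_new) - log(alpha[ia])))
    alpha[ia] <- alpha_new
    drop_now <- alpha > a_max
    pruned_now <- any(drop_now & active)
    active[drop_now] <- FALSE
    mu_full <- numeric(p)
    mu_full[ia] <- mu
    mu_full[!active] <- 0
    if (delta < tol && !pruned_now) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  mu_full[!active] <- 0
  w <- mu_full / xs
  structure(list(weights = stats::setNames(w, colnames(X)),
                 intercept = ym - sum(xm * w),
                 alpha = alpha, sigma2 = sigma2, iterations = it,
                 converged = converged, active = active,
                 muscles = design$muscles, lags_ms = design$lags_ms),
            class = "sparse_model")
}

#' @export
print.sparse_model <- function(x, ...) {
  cat(sprintf("<sparse_model> %d/%d columns active, %d iterations%s\n",
              sum(x$active), length(x$active), x$iterations,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Predict binned spike counts from a fitted model
#' @param object a `sparse_model`.
#' @param X design matrix with the model's columns.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.sparse_model <- function(object, X, ...) {
  as.numeric(X %*% object$weights + object$intercept)
}

#' Per-muscle normalized weight mass
#'
#' Sums absolute weights over each muscle's lag columns and normalizes so
#' the muscle weights sum to 1 (all zero when the model is empty).
#'
#' @param model a `sparse_model`.
#' @param channel_meta optional data.frame with `muscle` and `target` to
#'   annotate target muscles.
#' @return data.frame with `muscle`, `weight`, and `target` when metadata
#'   is given.
#' @export
summarize_weights <- function(model, channel_meta = NULL) {
  nm <- length(model$muscles)
  nl <- length(model$lags_ms)
  w <- abs(model$weights)
  per <- vapply(seq_len(nm), function(m)
    sum(w[(m - 1L) * nl + seq_len(nl)]), numeric(1))
  tot <- sum(per)
  out <- data.frame(muscle = model$muscles,
                    weight = if (tot > 0) per / tot else rep(0, nm))
  if (!is.null(channel_meta))
    out$target <- channel_meta$target[match(out$muscle, channel_meta$muscle)]
  out
}

# Gaussian smoothing of a series (sd in samples)
.gauss_smooth <- function(x, sd_samples) {
  if (sd_samples <= 0) return(x)
  half <- ceiling(4 * sd_samples)
  k <- stats::dnorm(-half:half, sd = sd_samples)
  k <- k / sum(k)
  n <- length(x)
  .conv_open(x, k)[half + seq_len(n)]
}

#' Trial-wise cross-validated decoding score
#'
#' Splits the design by trial (never by bin), fits the ARD model on each
#' training set, predicts the held-out bins, and scores the Pearson
#' correlation between the Gaussian-smoothed (10 ms SD) predicted and
#' observed rates.
#'
#' @param design a `lagged_design`.
#' @param k_folds number of folds; at most the number of trials.
#' @param smooth_ms Gaussian smoothing SD (ms) applied before scoring.
#' @param ... passed to [fit_ard()].
#' @return list with `fold_correlation` (length `k_folds`), `mean_correlation`.
#' @export
crossval_decode <- function(design, k_folds = 5, smooth_ms = 10, ...) {
  trials <- unique(design$trial)
  if (length(trials) < k_folds)
    stop("fewer trials than folds")
  fold_of <- stats::setNames(rep(seq_len(k_folds), length.out = length(trials)),
                             trials)
  rho <- numeric(k_folds)
  for (f in seq_len(k_folds)) {
    test <- fold_of[design$trial] == f
    d_tr <- list(X = design$X[!test, , drop = FALSE], y = design$y[!test],
                 muscles = design$muscles, lags_ms = design$lags_ms)
    m <- fit_ard(d_tr, ...)
    pred <- predict(m, design$X[test, , drop = FALSE])
    sd_bins <- smooth_ms / design$bin_ms
    ps <- .gauss_smooth(pred, sd_bins)
    ys <- .gauss_smooth(design$y[test], sd_bins)
    rho[f] <- if (stats::sd(ps) > 0 && stats::sd(ys) > 0)
      stats::cor(ps, ys) else 0
  }
  list(fold_correlation = rho, mean_correlation = mean(rho))
}

#' Extension-movement analysis intervals of a session
#'
#' Convenience accessor for the movement + hold spans of successful
#' extension trials, the standard decoding intervals.
#'
#' @param session an `ag_session`.
#' @param direction movement direction.
#' @return data.frame with `trial_id`, `start`, `end`.
#' @export
movement_intervals <- function(session, direction = "extension") {
  tr <- session$trials
  tr <- tr[tr$direction == direction & !is.na(tr$movement_onset), ,
           drop = FALSE]
  end <- ifelse(!is.na(tr$release_go), tr$release_go, tr$hold_end)
  data.frame(trial_id = tr$trial_id, start = tr$movement_onset, end = end)
}
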