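# Closed-loop nonlinear segmental reflex simulator: a brief descending
# set-point pulse and Golgi-tendon-organ (Ib) force feedback drive the
# interneuron; the motoneuron is inhibited by muscle-spindle (Ia)
# displacement feedback; first-order activation, second-order contractile
# dynamics with force-length decline, and a damped elastic plant close the
# loop.  Includes optimal-gain fitting to a target waveform, 90-110%
# parameter sweeps, and sensitivity comparison.

#' Parameters of the segmental reflex simulator
#'
#' Free parameters are the Ib (force) feedback gain, the Ia (displacement)
#' feedback gain, and the set-point pulse amplitude; the remaining
#' constants are fixed defaults of the model.
#'
#' @param G_Ib force-feedback gain onto the interneuron (dimensionless,
#'   >= 0).
#' @param G_Ia displacement-feedback gain onto the motoneuron
#'   (dimensionless, >= 0).
#' @param SP set-point pulse amplitude (drive units, >= 0).
#' @param delay_Ib_ms,delay_Ia_ms feedback loop delays (ms).
#' @param sp_pulse_ms set-point pulse duration (ms).
#' @param tau_act_ms EMG activation time constant (ms).
#' @param omega_force activation-to-force natural frequency (rad/s),
#'   critically damped.
#' @param fl_coef force-length decline coefficient (per unit shortening).
#' @param inertia,damping,stiffness plant constants (normalized units; the
#'   elastic load is `stiffness`).
#' @param saturation motoneuron output saturation bound (drive units).
#' @param ia_sign sign of the displacement feedback onto the motoneuron
#'   (-1 = reciprocal inhibition).
#' @param dt_ms integration step (ms).
#' @param t_end_s simulated span (s).
#' @return list of class `reflex_params`.
#' @export
reflex_params <- function(G_Ib = 1.4, G_Ia = 0.8, SP = 0.3,
                          delay_Ib_ms = 20, delay_Ia_ms = 20,
                          sp_pulse_ms = 50, tau_act_ms = 30,
                          omega_force = 15, fl_coef = 0.8,
                          inertia = 0.2, damping = 1.1, stiffness = 1,
                          saturation = 10, ia_sign = -1,
                          dt_ms = 0.5, t_end_s = 3) {
  p <- as.list(environment())
  if (p$G_Ib < 0 || p$G_Ia < 0 || p$SP < 0)
    stop("gains and SP must be nonnegative")
  if (p$dt_ms <= 0) stop("dt must be > 0")
  if (p$saturation <= 0) stop("saturation must be > 0")
  class(p) <- "reflex_params"
  p
}

#' Simulate the closed-loop segmental reflex
#'
#' Fixed-step integration of: interneuron drive
#' `a(t) = max(0, SP * pulse(t) + G_Ib * F(t - delay_Ib))`; motoneuron
#' drive `m(t) = sat(a(t) + ia_sign * G_Ia * x(t - delay_Ia))` with a
#' saturating output `sat(u) = S * tanh(max(u, 0) / S)`; first-order EMG
#' `e` on `m`; critically damped second-order force `F` on
#' `e * max(0, 1 - fl_coef * x)`; plant
#' `inertia * x'' + damping * x' + stiffness * x = F`.  Deterministic.
#'
#' @param params a [reflex_params()].
#' @return Object of class `reflex_sim`: `time_s`, `emg`, `activation`
#'   (interneuron drive), `motoneuron`, `force`, `displacement`, `params`.
#' @export
simulate_reflex <- function(params) {
  p <- params
  dt <- p$dt_ms / 1000
  n <- round(p$t_end_s / dt)
  st <- .reflex_loop(n, dt,
                     round(p$delay_Ib_ms / 1000 / dt),
                     round(p$delay_Ia_ms / 1000 / dt),
                     round(p$sp_pulse_ms / 1000 / dt),
                     p$SP, p$G_Ib, p$G_Ia, p$tau_act_ms / 1000,
                     p$omega_force, p$fl_coef, p$inertia, p$damping,
                     p$stiffness, p$saturation, p$ia_sign)
  structure(list(time_s = (seq_len(n) - 1) * dt, emg = st$emg,
                 activation = st$activation, motoneuron = st$motoneuron,
                 force = st$force, displacement = st$displacement,
                 params = p),
            class = "reflex_sim")
}

#' @export
print.reflex_sim <- function(x, ...) {
  met <- emg_metrics(x)
  cat(sprintf("<reflex_sim> %.1f s, peak EMG %.3g, duration %.3g s%s\n",
              max(x$time_s), met$peak_amplitude, met$duration_s,
              if (met$no_offset) " [no offset]" else ""))
  invisible(x)
}

#' @export
plot.reflex_sim <- function(x, ...) {
  graphics::matplot(x$time_s, cbind(x$emg, x$force, x$displacement),
                    type = "l", lty = 1, xlab = "time (s)", ylab = "",
                    ...)
  graphics::legend("topright", c("EMG", "force", "displacement"),
                   col = 1:3, lty = 1, bty = "n")
  invisible(x)
}

#' Amplitude and duration of a simulated EMG burst
#'
#' Peak amplitude is the EMG maximum; duration is the total time the EMG
#' exceeds `threshold` of the peak.  When the EMG is still above the
#' threshold at the end of the simulated span the offset is undefined and
#' flagged.
#'
#' @param sim a `reflex_sim` (or list with `emg` and `time_s`).
#' @param threshold fraction of the peak defining the burst.
#' @return list with `peak_amplitude`, `duration_s`, `no_offset`.
#' @export
emg_metrics <- function(sim, threshold = 0.05) {
  e <- sim$emg
  pk <- max(e)
  if (pk <= 0) return(list(peak_amplitude = 0, duration_s = 0,
                           no_offset = FALSE))
  dt <- sim$time_s[2] - sim$time_s[1]
  above <- e > threshold * pk
  list(peak_amplitude = pk, duration_s = sum(above) * dt,
       no_offset = above[length(above)])
}

# fitting objective: (1 - R) + lambda * normalized mean amplitude error
.fit_objective <- function(gains, target, fixed, lambda) {
  p <- do.call(reflex_params,
               c(list(G_Ib = gains[1], G_Ia = gains[2], SP = gains[3]), fixed))
  sim <- tryCatch(simulate_reflex(p), error = function(e) NULL)
  if (is.null(sim)) return(1e6)
  s <- sim$emg[seq_along(target)]
  R <- if (stats::sd(s) < 1e-12 || stats::sd(target) < 1e-12) 0 else
    stats::cor(s, target)
  nd <- mean(abs(s - target)) / max(max(target), 1e-12)
  (1 - R) + lambda * nd
}

#' Fit the reflex gains to a target EMG waveform
#'
#' Minimizes `(1 - R) + lambda * |normalized amplitude error|` over
#' `(G_Ib, G_Ia, SP)` by a deterministic coarse grid search followed by
#' derivative-free (Nelder-Mead) refinement from the best starts.
#'
#' @param target target EMG waveform sampled on the simulator grid.
#' @param bounds 2 x 3 matrix (rows lower/upper, columns G_Ib, G_Ia, SP).
#' @param fixed named list of fixed [reflex_params()] overrides.
#' @param lambda amplitude-error weight.
#' @param n_grid coarse grid points per dimension.
#' @param n_starts refinement starts.
#' @return Object of class `gain_fit`: `optimal` (named gains),
#'   `objective`, `R`, `normalized_difference_pct` (100 x mean abs error /
#'   target peak), `at_bounds` flag, `sim` (simulation at the optimum).
#' @export
fit_gains <- function(target, bounds = rbind(c(0.2, 0.05, 0.02),
                                             c(3, 2, 1)),
                      fixed = list(), lambda = 1, n_grid = 5, n_starts = 3) {
  if (any(bounds <= 0)) stop("bounds must be positive")
  grids <- lapply(1:3, function(j)
    exp(seq(log(bounds[1, j]), log(bounds[2, j]), length.out = n_grid)))
  cand <- as.matrix(expand.grid(grids))
  vals <- apply(cand, 1, .fit_objective, target = target, fixed = fixed,
                lambda = lambda)
  ord <- order(vals)[seq_len(n_starts)]
  best <- NULL; best_val <- Inf
  for (s in ord) {
    # optimize in log space so bounds become box-free and positivity holds
    res <- stats::optim(log(cand[s, ]), function(lg) {
      g <- exp(lg)
      if (any(g < bounds[1, ] * 0.5) || any(g > bounds[2, ] * 2)) return(1e6)
      .fit_objective(g, target, fixed, lambda)
    }, method = "Nelder-Mead",
    control = list(maxit = 400, reltol = 1e-10))
    if (res$value < best_val) { best <- exp(res$par); best_val <- res$value }
  }
  names(best) <- c("G_Ib", "G_Ia", "SP")
  p <- do.call(reflex_params,
               c(list(G_Ib = best[1], G_Ia = best[2], SP = best[3]), fixed))
  sim <- simulate_reflex(p)
  s <- sim$emg[seq_along(target)]
  R <- if (stats::sd(s) < 1e-12 || stats::sd(target) < 1e-12) NA_real_ else
    stats::cor(s, target)
  nd <- 100 * mean(abs(s - target)) / max(max(target), 1e-12)
  at_bounds <- any(best <= bounds[1, ] * 1.001) ||
    any(best >= bounds[2, ] * 0.999)
  structure(list(optimal = best, objective = best_val, R = R,
                 normalized_difference_pct = nd, at_bounds = at_bounds,
                 sim = sim),
            class = "gain_fit")
}

#' @export
print.gain_fit <- function(x, ...) {
  cat(sprintf(
    "<gain_fit> G_Ib=%.3f G_Ia=%.3f SP=%.3f, R=%.3f, norm.diff=%.2f%%%s\n",
    x$optimal[1], x$optimal[2], x$optimal[3], x$R,
    x$normalized_difference_pct, if (x$at_bounds) " [at bounds]" else ""))
  invisible(x)
}

#' Sweep one gain parameter around its optimum
#'
#' Re-simulates with the named parameter set to 90--110% of its optimal
#' value and reports the EMG peak amplitude and duration at each point,
#' normalized to their values at 100%.
#'
#' @param params the [reflex_params()] at the optimum.
#' @param name one of `"G_Ib"`, `"G_Ia"`, `"SP"`.
#' @param range relative sweep range.
#' @param n grid points.
#' @return data.frame with `fraction`, `value`, `peak_amplitude`,
#'   `duration_s`, `no_offset`, `rel_amplitude`, `rel_duration`.
#' @export
sweep_parameter <- function(params, name = c("G_Ib", "G_Ia", "SP"),
                            range = c(0.9, 1.1), n = 5) {
  name <- match.arg(name)
  fr <- seq(range[1], range[2], length.out = n)
  base <- params[[name]]
  out <- data.frame(fraction = fr, value = fr * base,
                    peak_amplitude = NA_real_, duration_s = NA_real_,
                    no_offset = NA)
  for (i in seq_len(n)) {
    p <- params; p[[name]] <- fr[i] * base
    met <- emg_metrics(simulate_reflex(p))
    out$peak_amplitude[i] <- met$peak_amplitude
    out$duration_s[i] <- met$duration_s
    out$no_offset[i] <- met$no_offset
  }
  ref <- which.min(abs(fr - 1))
  out$rel_amplitude <- out$peak_amplitude / out$peak_amplitude[ref]
  out$rel_duration <- out$duration_s / out$duration_s[ref]
  out
}

#' Compare parameter sensitivities from 90-110% sweeps
#'
#' Effect size of each swept parameter on a metric is
#' `|metric(110%) - metric(90%)| / metric(100%)`; sweeps whose duration is
#' undefined (no EMG offset) at any grid point are excluded and flagged.
#'
#' @param sweeps named list of sweep tables from [sweep_parameter()], e.g.
#'   `list(G_Ib = ..., G_Ia = ..., SP = ...)`.
#' @return data.frame with `parameter`, `amplitude_effect`,
#'   `duration_effect`, `excluded` (duration undefined somewhere), ordered
#'   by amplitude effect.
#' @export
sensitivity_compare <- function(sweeps) {
  eff <- function(sw, col) {
    lo <- sw[[col]][which.min(sw$fraction)]
    hi <- sw[[col]][which.max(sw$fraction)]
    md <- sw[[col]][which.min(abs(sw$fraction - 1))]
    abs(hi - lo) / md
  }
  out <- data.frame(parameter = names(sweeps),
                    amplitude_effect = NA_real_, duration_effect = NA_real_,
                    excluded = FALSE)
  for (i in seq_along(sweeps)) {
    sw <- sweeps[[i]]
    out$amplitude_effect[i] <- eff(sw, "peak_amplitude")
    if (any(sw$no_offset)) {
      out$excluded[i] <- TRUE
    } else {
      out$duration_effect[i] <- eff(sw, "duration_s")
    }
  }
  out[order(-out$amplitude_effect), ]
}
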