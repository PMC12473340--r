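#' Macromolecular fraction from the pool-size ratio
#'
#' `f = M0B / (M0A + M0B) = F / (1 + F)`.
#'
#' @param F pool-size ratio(s), >= 0.
#' @return macromolecular fraction(s) in `[0, 1)`.
#' @seealso [pool_ratio_from_f()] for the inverse.
#' @export
f_from_pool_ratio <- function(F) {
  gamma_check(F, "F")
  if (any(F < 0)) stop("pool-size ratio F must be >= 0", call. = FALSE)
  F / (1 + F)
}

#' Pool-size ratio from the macromolecular fraction
#'
#' Inverse of [f_from_pool_ratio()]: `F = f / (1 - f)`.
#'
#' @param f macromolecular fraction(s) in `[0, 1)`.
#' @return pool-size ratio(s).
#' @export
pool_ratio_from_f <- function(f) {
  gamma_check(f, "f")
  if (any(f < 0 | f >= 1)) stop("f must lie in [0, 1)", call. = FALSE)
  f / (1 - f)
}

#' Fixed constants of the single-offset two-parameter qMT solve
#'
#' Model parameters held constant in the accelerated two-parameter qMT
#' approach, at the values established for skeletal muscle:
#' `T2B = 6 us`, `RA*T2A = 0.025`, `R*M0A = 48 /s`.
#'
#' @param t2b_s bound-pool T2 in seconds.
#' @param ra_t2a dimensionless product of free-pool rate and T2.
#' @param rm0a composite exchange rate in 1/s.
#' @return an object of class `single_offset_constants`.
#' @export
single_offset_constants <- function(t2b_s = 6e-6, ra_t2a = 0.025, rm0a = 48) {
  for (nm in c("t2b_s", "ra_t2a", "rm0a")) gamma_check(get(nm), nm)
  if (any(c(t2b_s, ra_t2a, rm0a) <= 0))
    stop("all single-offset constants must be positive", call. = FALSE)
  structure(list(t2b_s = t2b_s, ra_t2a = ra_t2a, rm0a = rm0a),
            class = "single_offset_constants")
}

#' Control settings for the multi-offset qMT fit
#'
#' Bounds, initial values and multistart policy of [qmt_fit()].  Parameters
#' are optimised in log space so positivity is structural; the three starts
#' (nominal, +50\%, -50\%) are deterministic and the best-residual solution
#' is kept.
#'
#' @param f0,rm0a0,t2b0 initial pool-size ratio, exchange rate (1/s) and
#'   bound-pool T2 (s); the initial `T2A` is taken as `0.025 / RA`.
#' @param lower,upper named bounds on `(F, rm0a, t2a, t2b)` in natural units.
#' @param perturb multistart perturbation factors applied to the start.
#' @param maxiter maximum Levenberg-Marquardt iterations per start.
#' @return a list of class `qmt_control`.
#' @export
qmt_control <- function(f0 = 0.07, rm0a0 = 48, t2b0 = 6e-6,
                        lower = c(F = 1e-4, rm0a = 1, t2a = 5e-3, t2b = 1e-6),
                        upper = c(F = 0.5, rm0a = 200, t2a = 0.2, t2b = 3e-5),
                        perturb = c(1, 1.5, 0.5), maxiter = 100L) {
  structure(list(f0 = f0, rm0a0 = rm0a0, t2b0 = t2b0, lower = lower,
                 upper = upper, perturb = perturb, maxiter = maxiter),
            class = "qmt_control")
}

pulses_to_frame <- function(pulses) {
  if (is.data.frame(pulses)) {
    need <- c("mt_flip_deg", "mt_offset_hz")
    miss <- setdiff(need, names(pulses))
    if (length(miss))
      stop("pulse table is missing columns: ", paste(miss, collapse = ", "),
           call. = FALSE)
    out <- data.frame(
      flip_deg = pulses$mt_flip_deg,
      offset_hz = pulses$mt_offset_hz,
      duration_s = if ("mt_duration_s" %in% names(pulses)) pulses$mt_duration_s else 0.01024,
      bandwidth_hz = if ("mt_bandwidth_hz" %in% names(pulses)) pulses$mt_bandwidth_hz else 200,
      tr_s = if ("tr_s" %in% names(pulses)) pulses$tr_s else 0.05)
    return(out)
  }
  if (inherits(pulses, "rf_pulse")) pulses <- list(pulses)
  stopifnot(is.list(pulses))
  do.call(rbind, lapply(pulses, function(p) {
    if (!inherits(p, "rf_pulse")) stop("'pulses' must contain rf_pulse objects")
    data.frame(flip_deg = p$flip_deg, offset_hz = p$offset_hz,
               duration_s = p$duration_s, bandwidth_hz = p$bandwidth_hz,
               tr_s = p$tr_s)
  }))
}

# continuous-wave-equivalent amplitudes for a pulse table
cw_equivalents <- function(ptab, mode, b1_rel) {
  vapply(seq_len(nrow(ptab)), function(i) {
    p <- rf_pulse(ptab$flip_deg[i] * b1_rel, ptab$offset_hz[i],
                  ptab$duration_s[i], ptab$bandwidth_hz[i], ptab$tr_s[i])
    if (mode == "ramani") omega1_cwpe(p) else omega1_rms(p)
  }, numeric(1))
}

#' Fit the two-pool model to a multi-offset Z-spectrum
#'
#' Least-squares estimation of `(F, R*M0A, T2A, T2B)` from normalized
#' MT-weighted signals acquired at several (flip angle, offset) combinations.
#' The bound-pool rate is fixed (`RB = 1 /s`) and the free-pool rate `RA` is
#' constrained to the value measured by T1 mapping.  MT flip angles are
#' scaled by the relative transmit field and offsets shifted by the voxel
#' off-resonance before model evaluation.
#'
#' @param sn normalized signals in (0, 1.5] (MT volume / no-MT volume).
#' @param pulses a list of [rf_pulse()] objects, or a data frame with columns
#'   `mt_flip_deg`, `mt_offset_hz` (and optionally `mt_duration_s`,
#'   `mt_bandwidth_hz`, `tr_s`), one row per signal.
#' @param ra free-pool longitudinal rate in 1/s (from T1 mapping).
#' @param mode RF approximation: `"ramani"` or `"yarnykh"`.
#' @param b1_rel relative transmit field in `[0.5, 1.5]`.
#' @param b0_hz voxel off-resonance in Hz.
#' @param rb bound-pool longitudinal rate, fixed during the fit.
#' @param control a [qmt_control()] list.
#' @return an object of class `qmt_fit` with components `params`
#'   ([two_pool_params()]), `f`, `residual_rms`, `n_points`, `converged`,
#'   `fitted`, `sn`, `mode`, `method`.
#' @examples
#' prot <- multioffset_pulses()
#' truth <- two_pool_params(0.07, 48, 0.7, 1, 0.035, 6e-6)
#' sn <- vapply(prot, function(p) ramani_signal(truth, p), numeric(1))
#' fit <- qmt_fit(sn, prot, ra = 0.7)
#' coef(fit)
#' @export
qmt_fit <- function(sn, pulses, ra, mode = c("ramani", "yarnykh"),
                    b1_rel = 1, b0_hz = 0, rb = 1, control = qmt_control()) {
  mode <- match.arg(mode)
  gamma_check(sn, "sn"); gamma_check(ra, "ra")
  gamma_check(b1_rel, "b1_rel"); gamma_check(b0_hz, "b0_hz")
  if (ra <= 0) stop("ra must be > 0", call. = FALSE)
  if (b1_rel < 0.5 || b1_rel > 1.5)
    stop("b1_rel outside the credible range [0.5, 1.5]", call. = FALSE)
  ptab <- pulses_to_frame(pulses)
  if (nrow(ptab) != length(sn))
    stop("length of 'sn' must match the number of pulses", call. = FALSE)
  keep <- ptab$flip_deg > 0
  ptab <- ptab[keep, , drop = FALSE]; sn <- sn[keep]
  n <- length(sn)
  if (n < 6 || nrow(unique(ptab[c("flip_deg", "offset_hz")])) < 6)
    stop("under-determined fit: need at least 6 distinct (flip, offset) points",
         call. = FALSE)
  if (any(sn <= 0 | sn > 1.5))
    stop("normalized signals must lie in (0, 1.5]", call. = FALSE)
  if (max(1 - sn) < 1e-3)
    stop("degenerate data: signals show no MT attenuation", call. = FALSE)

  w1 <- cw_equivalents(ptab, mode, b1_rel)
  off <- ptab$offset_hz - b0_hz
  if (any(off < 100))
    stop("effective offset below the 100 Hz on-resonance floor", call. = FALSE)

  lo <- log(control$lower); hi <- log(control$upper)
  resid_fn <- function(lp) {
    p <- exp(lp)
    two_pool_sn(w1, off, p[1], p[2], ra, rb, p[3], p[4]) - sn
  }
  start0 <- c(F = control$f0, rm0a = control$rm0a0,
              t2a = min(max(0.025 / ra, control$lower["t2a"]), control$upper["t2a"]),
              t2b = control$t2b0)
  best <- NULL
  for (fac in control$perturb) {
    st <- pmin(pmax(start0 * fac, control$lower * 1.001), control$upper * 0.999)
    fit <- try(minpack.lm::nls.lm(
      par = log(st), lower = lo, upper = hi, fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = control$maxiter)),
      silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    return(structure(list(params = NULL, f = NA_real_, residual_rms = NA_real_,
                          n_points = n, converged = FALSE, mode = mode,
                          method = "multioffset", ra = ra),
                     class = "qmt_fit"))
  est <- exp(best$par)
  params <- two_pool_params(est[["F"]], est[["rm0a"]], ra, rb,
                            est[["t2a"]], est[["t2b"]])
  fitted <- sn + best$fvec
  structure(list(params = params, f = params$f,
                 residual_rms = sqrt(best$deviance / n),
                 n_points = n, converged = best$info %in% 1:4,
                 mode = mode, method = "multioffset", ra = ra,
                 b1_rel = b1_rel, b0_hz = b0_hz,
                 sn = sn, fitted = fitted, pulse_table = ptab,
                 control = control),
            class = "qmt_fit")
}

#' Closed-form single-offset qMT solve
#'
#' Two-parameter qMT: with `T2B`, `RA*T2A` and `R*M0A` fixed at their muscle
#' values ([single_offset_constants()]), the pool-size ratio follows in
#' closed form from one normalized low-offset measurement,
#' \deqn{\frac{F}{R_A} = \frac{(R_{RFB} + R_B + RM_{0A})
#'   \left(1 - S_n\left(1 + \left(\frac{\omega_{1CWPE}}{2\pi\Delta f}\right)^2
#'   \frac{1}{R_A T_{2A}}\right)\right)}
#'   {RM_{0A}\,(S_n (R_{RFB} + R_B) - R_B)}.}
#' The Ramani (CW power-equivalent) RF approximation is used.
#'
#' @param sn_low normalized signal at the low offset (MT volume divided by
#'   the large-offset reference volume), in (0, 1).
#' @param pulse_low the low-offset [rf_pulse()].
#' @param ra free-pool longitudinal rate in 1/s (from T1 mapping).
#' @param constants a [single_offset_constants()] object.
#' @param b1_rel,b0_hz transmit-field scale and off-resonance applied to the
#'   pulse before evaluation.
#' @param rb bound-pool longitudinal rate in 1/s.
#' @return a `qmt_fit` object (`method = "single_offset"`).  A negative
#'   solved `F` is truncated to the returned `params` being flagged via
#'   `nonphysical = TRUE` and a warning.
#' @examples
#' truth <- two_pool_params(0.10, 48, 0.7, 1, 0.025/0.7, 6e-6)
#' p <- rf_pulse(650, 1000)
#' sn <- ramani_signal(truth, p)
#' solve_single_offset(sn, p, ra = 0.7)$params$F
#' @export
solve_single_offset <- function(sn_low, pulse_low, ra,
                                constants = single_offset_constants(),
                                b1_rel = 1, b0_hz = 0, rb = 1) {
  gamma_check(sn_low, "sn_low"); gamma_check(ra, "ra")
  if (!inherits(pulse_low, "rf_pulse")) stop("'pulse_low' must be an rf_pulse")
  if (!inherits(constants, "single_offset_constants"))
    stop("'constants' must come from single_offset_constants()", call. = FALSE)
  if (sn_low <= 0 || sn_low >= 1)
    stop("sn_low must lie strictly in (0, 1)", call. = FALSE)
  if (ra <= 0) stop("ra must be > 0", call. = FALSE)
  scaled <- pulse_low; scaled$flip_deg <- pulse_low$flip_deg * b1_rel
  w1 <- omega1_cwpe(scaled)
  off <- pulse_low$offset_hz - b0_hz
  if (off < 100)
    stop("effective offset below the 100 Hz on-resonance floor", call. = FALSE)
  r_rfb <- rrfb(w1, off, constants$t2b_s)
  direct <- (w1 / (2 * pi * off))^2 / constants$ra_t2a
  den <- constants$rm0a * (sn_low * (r_rfb + rb) - rb)
  if (abs(den) < 1e-12)
    stop("singular single-offset solve: denominator vanishes", call. = FALSE)
  f_over_ra <- (r_rfb + rb + constants$rm0a) * (1 - sn_low * (1 + direct)) / den
  F <- ra * f_over_ra
  nonphysical <- FALSE
  if (F < 0) {
    warning("single-offset solve produced a negative pool-size ratio; ",
            "flagged non-physical")
    nonphysical <- TRUE
  }
  t2a <- constants$ra_t2a / ra
  params <- if (nonphysical) NULL else
    two_pool_params(F, constants$rm0a, ra, rb, t2a, constants$t2b_s)
  structure(list(params = params, F = F,
                 f = if (nonphysical) NA_real_ else params$f,
                 residual_rms = 0, n_points = 1L,
                 converged = TRUE, nonphysical = nonphysical,
                 mode = "ramani", method = "single_offset", ra = ra,
                 b1_rel = b1_rel, b0_hz = b0_hz, sn = sn_low),
            class = "qmt_fit")
}

#' The standard multi-offset MT protocol pulse set
#'
#' Fourteen Gaussian MT pulses: flip angles 350 and 500 degrees crossed with
#' offsets 1, 2, 5, 10, 20, 50 and 100 kHz (200 Hz bandwidth, 10.24 ms
#' duration, 50 ms TR).
#'
#' @param flips_deg,offsets_hz vectors crossed to build the protocol.
#' @return a list of [rf_pulse()] objects.
#' @export
multioffset_pulses <- function(flips_deg = c(350, 500),
                               offsets_hz = c(1, 2, 5, 10, 20, 50, 100) * 1e3) {
  out <- list()
  for (fl in flips_deg) for (of in offsets_hz)
    out[[length(out) + 1L]] <- rf_pulse(fl, of)
  out
}

#' @export
print.qmt_fit <- function(x, ...) {
  cat(sprintf("qMT %s fit (%s RF approximation)\n", x$method, x$mode))
  if (!x$converged) {
    cat("  fit did not converge; parameters unusable\n")
    return(invisible(x))
  }
  if (isTRUE(x$nonphysical)) {
    cat(sprintf("  non-physical solution: F = %.4g\n", x$F))
    return(invisible(x))
  }
  cat(sprintf("  f = %.4f  (F = %.4f)\n", x$f, x$params$F))
  if (x$method == "multioffset")
    cat(sprintf("  R*M0A = %.3g /s, T2A = %.3g ms, T2B = %.3g us, RMS residual = %.2e (n = %d)\n",
                x$params$rm0a, x$params$t2a * 1e3, x$params$t2b * 1e6,
                x$residual_rms, x$n_points))
  invisible(x)
}

#' @export
coef.qmt_fit <- function(object, ...) {
  if (!object$converged || isTRUE(object$nonphysical))
    return(c(F = NA_real_, f = NA_real_))
  p <- object$params
  c(F = p$F, f = p$f, rm0a = p$rm0a, ra = p$ra, rb = p$rb,
    t2a = p$t2a, t2b = p$t2b)
}

#' @export
residuals.qmt_fit <- function(object, ...) {
  if (object$method != "multioffset") return(numeric(0))
  object$sn - object$fitted
}

#' @export
fitted.qmt_fit <- function(object, ...) object$fitted

#' Predict normalized signals from a fitted qMT model
#'
#' @param object a `qmt_fit`.
#' @param pulses new pulses (list of [rf_pulse()] or pulse table); defaults
#'   to the pulses used in the fit.
#' @param ... unused.
#' @return predicted normalized signals.
#' @export
predict.qmt_fit <- function(object, pulses = NULL, ...) {
  if (!object$converged || is.null(object$params))
    stop("cannot predict from a non-converged fit", call. = FALSE)
  ptab <- if (is.null(pulses)) object$pulse_table else pulses_to_frame(pulses)
  if (is.null(ptab)) stop("no pulses available for prediction", call. = FALSE)
  if (!"flip_deg" %in% names(ptab)) ptab <- pulses_to_frame(ptab)
  b1 <- if (is.null(object$b1_rel)) 1 else object$b1_rel
  b0 <- if (is.null(object$b0_hz)) 0 else object$b0_hz
  w1 <- cw_equivalents(ptab, object$mode, b1)
  p <- object$params
  two_pool_sn(w1, ptab$offset_hz - b0, p$F, p$rm0a, p$ra, p$rb, p$t2a, p$t2b)
}

#' @export
summary.qmt_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.qmt_fit")
}

#' @export
print.summary.qmt_fit <- function(x, ...) {
  print(x$fit)
  if (x$fit$method == "multioffset" && x$fit$converged) {
    r <- residuals(x$fit)
    cat(sprintf("  residual quartiles: %s\n",
                paste(signif(quantile(r, c(0.25, 0.5, 0.75)), 3), collapse = " / ")))
  }
  invisible(x)
}

#' Simulate noisy replicates of the signals of a fitted qMT model
#'
#' Draws Rician magnitude noise around the model prediction, which is the
#' noise family of MRI magnitude images.
#'
#' @param object a converged multi-offset `qmt_fit`.
#' @param nsim number of replicate signal sets.
#' @param seed optional integer seed.
#' @param snr signal-to-noise ratio of the (unit) reference signal.
#' @param ... unused.
#' @return a matrix with `nsim` columns of replicate normalized signals.
#' @export
simulate.qmt_fit <- function(object, nsim = 1, seed = NULL, snr = 100, ...) {
  mu <- predict(object)
  run <- function() {
    vapply(seq_len(nsim), function(i) rician(mu, 1 / snr), numeric(length(mu)))
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
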