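#' Spoiled-gradient-echo steady-state signal
#'
#' `S = M0 * sin(a) * (1 - E1) / (1 - E1 * cos(a))` with
#' `E1 = exp(-TR/T1)`; the forward model used by the simulator and the VFA
#' fit tests.
#'
#' @param m0 equilibrium signal amplitude.
#' @param t1_s longitudinal relaxation time in seconds.
#' @param flip_deg flip angle(s) in degrees.
#' @param tr_s repetition time in seconds.
#' @return signal(s) in the units of `m0`.
#' @export
spgr_signal <- function(m0, t1_s, flip_deg, tr_s) {
  for (nm in c("m0", "t1_s", "flip_deg", "tr_s")) gamma_check(get(nm), nm)
  if (any(t1_s <= 0) || any(tr_s <= 0))
    stop("t1_s and tr_s must be > 0", call. = FALSE)
  a <- deg2rad(flip_deg)
  e1 <- exp(-tr_s / t1_s)
  m0 * sin(a) * (1 - e1) / (1 - e1 * cos(a))
}

#' Spoiled-gradient-echo steady state with a per-TR MT saturation
#'
#' FLASH steady state when every repetition additionally destroys the
#' fraction `delta` of the longitudinal magnetization (one off-resonance MT
#' pulse per TR):
#' `S = M0 * sin(a) * (1 - E1) / (1 - E1 * (1 - delta) * cos(a))`.
#' Its small-angle expansion is the familiar MT-weighted signal equation
#' `S = A*a*R1*TR / (a^2/2 + delta + R1*TR)`; at `delta = 0` it reduces to
#' [spgr_signal()].
#'
#' @inheritParams spgr_signal
#' @param delta fractional saturation per TR (dimensionless, >= 0).
#' @return signal(s) in the units of `m0`.
#' @export
spgr_mt_signal <- function(m0, t1_s, flip_deg, tr_s, delta = 0) {
  gamma_check(delta, "delta")
  if (any(delta < 0)) stop("delta must be >= 0", call. = FALSE)
  a <- deg2rad(flip_deg)
  e1 <- exp(-tr_s / t1_s)
  m0 * sin(a) * (1 - e1) / (1 - e1 * (1 - delta) * cos(a))
}

#' Per-TR MT saturation implied by the two-pool steady state
#'
#' Converts the two-pool normalized saturation signal into the equivalent
#' per-TR fractional saturation used by the MT-FLASH readout model: in a
#' pure saturation/recovery balance `Sn = R1*TR / (R1*TR + delta)`, hence
#' `delta = R1*TR*(1/Sn - 1)`.  This is the bridge between the exchange
#' model and the MT saturation index: the simulator computes `delta` from
#' tissue parameters and the MT pulse, and [compute_mtsat()] estimates it
#' back from the FLASH triplet.
#'
#' @param params a [two_pool_params()].
#' @param pulse the MT [rf_pulse()].
#' @param tr_s repetition time of the FLASH readout in seconds.
#' @param b1_rel,b0_hz transmit-field scale and off-resonance.
#' @return fractional saturation per TR (dimensionless).
#' @export
two_pool_delta <- function(params, pulse, tr_s = 0.05, b1_rel = 1, b0_hz = 0) {
  sn <- ramani_signal(params, pulse, b1_rel = b1_rel, b0_hz = b0_hz)
  (params$ra * tr_s) * (1 / sn - 1)
}

#' Variable-flip-angle T1 fit
#'
#' Linearises the spoiled-gradient-echo equation: regressing `S/sin(a)` on
#' `S/tan(a)` gives slope `E1 = exp(-TR/T1)` and intercept `M0 * (1 - E1)`.
#' Flip angles are scaled by the relative transmit field before fitting, the
#' standard B1 correction of VFA T1 mapping.
#'
#' @param signals signal intensities, one per flip angle.
#' @param flips_deg nominal flip angles in degrees (default 5, 15, 25).
#' @param tr_s repetition time in seconds (default 25 ms).
#' @param b1_rel relative transmit field.
#' @return a list with `t1` (seconds), `m0`, and `e1` (the fitted slope).
#' @examples
#' s <- spgr_signal(1000, 1.4, c(5, 15, 25), 0.025)
#' vfa_fit_t1(s)$t1
#' @export
vfa_fit_t1 <- function(signals, flips_deg = c(5, 15, 25), tr_s = 0.025,
                       b1_rel = 1) {
  gamma_check(signals, "signals"); gamma_check(flips_deg, "flips_deg")
  gamma_check(tr_s, "tr_s"); gamma_check(b1_rel, "b1_rel")
  if (length(signals) != length(flips_deg))
    stop("signals and flips_deg must have equal length", call. = FALSE)
  if (any(signals <= 0)) stop("signals must be positive", call. = FALSE)
  if (length(unique(flips_deg)) < 2)
    stop("degenerate flip-angle set: need at least 2 distinct flips",
         call. = FALSE)
  a <- deg2rad(flips_deg) * b1_rel
  y <- signals / sin(a)
  x <- signals / tan(a)
  fit <- lm(y ~ x)
  e1 <- unname(coef(fit)[2]); icpt <- unname(coef(fit)[1])
  if (!is.finite(e1) || e1 <= 0 || e1 >= 1)
    stop(sprintf("non-physical T1 fit: slope E1 = %.4g outside (0, 1)", e1),
         call. = FALSE)
  list(t1 = -tr_s / log(e1), m0 = icpt / (1 - e1), e1 = e1)
}

#' B0 off-resonance from a dual-echo phase pair
#'
#' `delta_f = wrap(phi2 - phi1) / (2*pi*(TE2 - TE1))`, with the phase
#' difference wrapped to `(-pi, pi]` per voxel (temporal wrap only, no
#' spatial unwrapping).  The unaliased range is `+/- 1/(2*dTE)` Hz.
#'
#' @param phase1,phase2 phase volumes (radians) at the two echoes;
#'   vectorised, any common shape.
#' @param te1_s,te2_s echo times in seconds (`te2_s > te1_s`).
#' @return off-resonance in Hz, same shape as the input.
#' @examples
#' b0_from_dual_echo(0, pi, 4.92e-3, 7.38e-3)  # 203.25 Hz
#' @export
b0_from_dual_echo <- function(phase1, phase2, te1_s = 4.92e-3,
                              te2_s = 7.38e-3) {
  gamma_check(phase1, "phase1"); gamma_check(phase2, "phase2")
  gamma_check(te1_s, "te1_s"); gamma_check(te2_s, "te2_s")
  if (te2_s <= te1_s) stop("need te2_s > te1_s", call. = FALSE)
  d <- phase2 - phase1
  d <- atan2(sin(d), cos(d))          # wrap to (-pi, pi]
  d / (2 * pi * (te2_s - te1_s))
}

#' Rician magnitude noise
#'
#' Adds the magnitude-image noise of MRI: the modulus of the true signal
#' plus complex Gaussian noise of standard deviation `sigma` per channel.
#' Zero-signal voxels acquire the Rayleigh floor `sigma*sqrt(pi/2)` in
#' expectation.
#'
#' @param x true signal (any shape).
#' @param sigma Gaussian noise standard deviation per channel.
#' @return noisy magnitudes, same shape as `x`.
#' @export
rician <- function(x, sigma) {
  gamma_check(sigma, "sigma")
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (sigma == 0) return(x)
  n <- length(x)
  out <- sqrt((x + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
}
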