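#' Two-pool tissue parameters
#'
#' Ground-truth or fitted parameters of the binary spin-bath (two-pool) MT
#' model: the free water pool A and the macromolecular bound pool B.
#'
#' @param F pool-size ratio `M0B/M0A` (>= 0).
#' @param rm0a composite forward exchange rate `R * M0A` in 1/s.
#' @param ra free-pool longitudinal rate `R_A = 1/T1A` in 1/s.
#' @param rb bound-pool longitudinal rate in 1/s (conventionally fixed at 1).
#' @param t2a free-pool transverse relaxation time in seconds.
#' @param t2b bound-pool transverse relaxation time in seconds (`t2b < t2a`).
#' @return an object of class `two_pool_params`; the derived macromolecular
#'   fraction `f = F/(1+F)` is stored alongside.
#' @examples
#' two_pool_params(F = 0.07, rm0a = 48, ra = 0.7, t2a = 0.035, t2b = 6e-6)
#' @export
two_pool_params <- function(F, rm0a, ra, rb = 1, t2a, t2b) {
  for (nm in c("F", "rm0a", "ra", "rb", "t2a", "t2b"))
    gamma_check(get(nm), nm)
  if (F < 0) stop("pool-size ratio F must be >= 0", call. = FALSE)
  if (any(c(rm0a, ra, rb, t2a, t2b) <= 0))
    stop("rates and relaxation times must be strictly positive", call. = FALSE)
  if (t2b >= t2a)
    stop("bound-pool t2b must be shorter than free-pool t2a", call. = FALSE)
  structure(list(F = F, rm0a = rm0a, ra = ra, rb = rb, t2a = t2a, t2b = t2b,
                 f = F / (1 + F)),
            class = "two_pool_params")
}

#' @export
print.two_pool_params <- function(x, ...) {
  cat(sprintf(
    "two-pool parameters: F = %.4g (f = %.4g), R*M0A = %.4g /s, RA = %.4g /s,\n  RB = %.4g /s, T2A = %.4g ms, T2B = %.4g us\n",
    x$F, x$f, x$rm0a, x$ra, x$rb, x$t2a * 1e3, x$t2b * 1e6))
  invisible(x)
}

# vectorised steady-state normalized signal; w1_eq, offset_hz may be vectors
two_pool_sn <- function(w1_eq, offset_hz, F, rm0a, ra, rb, t2a, t2b,
                        n_nodes = 512L, offset_floor = 100) {
  g <- super_lorentzian_g(offset_hz, t2b, n_nodes, offset_floor)
  r_rfb <- pi * w1_eq^2 * g
  X <- rm0a * F / ra
  direct <- (w1_eq / (2 * pi * offset_hz))^2 / (ra * t2a)
  num <- rb * X + rb + r_rfb + rm0a
  den <- X * (rb + r_rfb) + (1 + direct) * (r_rfb + rb + rm0a)
  num / den
}

#' Steady-state normalized signal of the pulsed two-pool MT experiment
#'
#' Forward model for the MT-weighted signal normalised to the no-saturation
#' acquisition.  The shaped pulse is replaced by its continuous-wave
#' equivalent: averaged over TR (`mode = "ramani"`) or over the pulse
#' duration (`mode = "yarnykh"`).  The signal is
#' \deqn{S_n = \frac{R_B X + R_B + R_{RFB} + RM_{0A}}
#'  {X (R_B + R_{RFB}) + \left(1 + \left(\frac{\omega_1}{2\pi\Delta f}\right)^2
#'   \frac{1}{R_A T_{2A}}\right) (R_{RFB} + R_B + RM_{0A})},}
#' with `X = RM0A * F / RA`.
#'
#' @param params a [two_pool_params()] object.
#' @param pulse an [rf_pulse()]; the relevant entries are flip angle, offset,
#'   duration, bandwidth and TR.
#' @param mode RF approximation, `"ramani"` (CW power equivalent) or
#'   `"yarnykh"` (RMS over the pulse).
#' @param b1_rel relative transmit field (1 = nominal); scales the MT flip
#'   angle before the equivalent amplitude is computed.
#' @param b0_hz voxel off-resonance in Hz; the effective saturation offset is
#'   `offset_hz - b0_hz`.
#' @param n_nodes,offset_floor passed to [super_lorentzian_g()].
#' @return normalized signal in (0, 1] for physical parameters.
#' @examples
#' p <- two_pool_params(0.07, 48, 0.7, 1, 0.035, 6e-6)
#' ramani_signal(p, rf_pulse(500, 5000))
#' @export
ramani_signal <- function(params, pulse, mode = c("ramani", "yarnykh"),
                          b1_rel = 1, b0_hz = 0,
                          n_nodes = 512L, offset_floor = 100) {
  if (!inherits(params, "two_pool_params"))
    stop("'params' must be a two_pool_params object", call. = FALSE)
  if (!inherits(pulse, "rf_pulse")) stop("'pulse' must be an rf_pulse")
  mode <- match.arg(mode)
  gamma_check(b1_rel, "b1_rel"); gamma_check(b0_hz, "b0_hz")
  if (b1_rel <= 0) stop("b1_rel must be > 0", call. = FALSE)
  scaled <- pulse
  scaled$flip_deg <- pulse$flip_deg * b1_rel
  w1 <- if (mode == "ramani") omega1_cwpe(scaled) else omega1_rms(scaled)
  off <- pulse$offset_hz - b0_hz
  if (off < offset_floor)
    stop(sprintf("effective offset %g Hz is below the %g Hz floor",
                 off, offset_floor), call. = FALSE)
  two_pool_sn(w1, off, params$F, params$rm0a, params$ra, params$rb,
              params$t2a, params$t2b, n_nodes, offset_floor)
}
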