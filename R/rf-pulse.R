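#' Off-resonance MT pulse description
#'
#' Describes one shaped RF pulse of an MT-weighted acquisition: a Gaussian
#' envelope of given spectral bandwidth (FWHM) and duration, played at a
#' nominal frequency offset once per repetition time.  All continuous-wave
#' equivalents ([omega1_cwpe()], [omega1_rms()]) are derived from this record.
#'
#' The Gaussian time-domain width follows from the spectral FWHM through the
#' Fourier pair: `sigma_f = bandwidth / (2*sqrt(2*log(2)))`,
#' `sigma_t = 1 / (2*pi*sigma_f)`.  The envelope is truncated to
#' `[0, duration]` and centred on `duration/2`; the flip angle is the integral
#' of the truncated envelope.
#'
#' @param flip_deg pulse flip angle in degrees (> 0).
#' @param offset_hz nominal frequency offset in Hz (>= 0; 0 only for
#'   reference/no-MT records).
#' @param duration_s pulse duration `t_mt` in seconds.
#' @param bandwidth_hz spectral FWHM in Hz.
#' @param tr_s repetition time of the pulse train in seconds (> duration).
#' @param shape envelope shape; only `"gaussian"` is supported.
#' @return an object of class `rf_pulse`.
#' @examples
#' p <- rf_pulse(500, 1000)           # the multi-offset protocol pulse
#' omega1_cwpe(p)
#' @export
rf_pulse <- function(flip_deg, offset_hz, duration_s = 0.01024,
                     bandwidth_hz = 200, tr_s = 0.05, shape = "gaussian") {
  shape <- match.arg(shape, "gaussian")
  gamma_check(flip_deg, "flip_deg"); gamma_check(offset_hz, "offset_hz")
  gamma_check(duration_s, "duration_s"); gamma_check(bandwidth_hz, "bandwidth_hz")
  gamma_check(tr_s, "tr_s")
  if (flip_deg <= 0) stop("flip_deg must be > 0", call. = FALSE)
  if (offset_hz < 0) stop("offset_hz must be >= 0", call. = FALSE)
  if (duration_s <= 0 || duration_s >= tr_s)
    stop("need 0 < duration_s < tr_s", call. = FALSE)
  if (bandwidth_hz <= 0) stop("bandwidth_hz must be > 0", call. = FALSE)
  structure(list(shape = shape, flip_deg = flip_deg, offset_hz = offset_hz,
                 duration_s = duration_s, bandwidth_hz = bandwidth_hz,
                 tr_s = tr_s),
            class = "rf_pulse")
}

#' @export
print.rf_pulse <- function(x, ...) {
  cat(sprintf("Gaussian MT pulse: %g deg, offset %g Hz, %.4g ms, FWHM %g Hz, TR %g ms\n",
              x$flip_deg, x$offset_hz, x$duration_s * 1e3, x$bandwidth_hz,
              x$tr_s * 1e3))
  invisible(x)
}

# time-domain sigma of the Gaussian envelope from the spectral FWHM
gauss_sigma_t <- function(bandwidth_hz) {
  sigma_f <- bandwidth_hz / (2 * sqrt(2 * log(2)))
  1 / (2 * pi * sigma_f)
}

erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1

# integrals of the unit-peak truncated envelope and of its square
envelope_integrals <- function(pulse) {
  s <- gauss_sigma_t(pulse$bandwidth_hz)
  Tm <- pulse$duration_s
  # int_0^T exp(-(t-T/2)^2/(2 s^2)) dt  and  the same for the square
  i1 <- s * sqrt(2 * pi) * erf(Tm / (2 * sqrt(2) * s))
  i2 <- s * sqrt(pi) * erf(Tm / (2 * s))
  list(i1 = i1, i2 = i2)
}

#' Gaussian pulse envelope
#'
#' Returns the amplitude-modulation function `omega1(t)` (rad/s) of a pulse,
#' truncated to `[0, duration]` and centred on the pulse midpoint.
#'
#' @param pulse an [rf_pulse()].
#' @param peak_rate peak `omega1` in rad/s.
#' @return a vectorised function of time in seconds; zero outside the pulse.
#' @export
pulse_envelope <- function(pulse, peak_rate) {
  if (!inherits(pulse, "rf_pulse")) stop("'pulse' must be an rf_pulse")
  if (!identical(pulse$shape, "gaussian"))
    stop("unsupported pulse shape: ", pulse$shape, call. = FALSE)
  s <- gauss_sigma_t(pulse$bandwidth_hz)
  Tm <- pulse$duration_s
  function(t) ifelse(t >= 0 & t <= Tm,
                     peak_rate * exp(-(t - Tm / 2)^2 / (2 * s^2)), 0)
}

#' Peak omega1 that realises the requested flip angle
#'
#' The flip angle is the time integral of `omega1(t)` over the truncated
#' envelope; the peak rate is therefore `theta_rad / integral(envelope)`.
#'
#' @inheritParams pulse_envelope
#' @return peak `omega1` in rad/s.
#' @export
flip_to_peak_omega1 <- function(pulse) {
  if (!inherits(pulse, "rf_pulse")) stop("'pulse' must be an rf_pulse")
  i1 <- envelope_integrals(pulse)$i1
  if (!is.finite(i1) || i1 <= 0) stop("degenerate envelope integral", call. = FALSE)
  deg2rad(pulse$flip_deg) / i1
}

#' Continuous-wave power-equivalent amplitude (Ramani convention)
#'
#' `omega1_cwpe^2 = (1/TR) * integral_0^t_mt omega1(t)^2 dt`: the mean square
#' RF amplitude averaged over the whole repetition time.
#'
#' @inheritParams pulse_envelope
#' @return equivalent amplitude in rad/s.
#' @export
omega1_cwpe <- function(pulse) {
  peak <- flip_to_peak_omega1(pulse)
  sqrt(peak^2 * envelope_integrals(pulse)$i2 / pulse$tr_s)
}

#' Root-mean-square amplitude over the pulse (Yarnykh convention)
#'
#' As [omega1_cwpe()] but normalised by the pulse duration `t_mt` instead of
#' TR, so it is never smaller than the power equivalent.
#'
#' @inheritParams pulse_envelope
#' @return equivalent amplitude in rad/s.
#' @export
omega1_rms <- function(pulse) {
  peak <- flip_to_peak_omega1(pulse)
  sqrt(peak^2 * envelope_integrals(pulse)$i2 / pulse$duration_s)
}
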