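#' Estimate the apparent amplitude A and relaxation rate R1 from PDw/T1w
#'
#' Rational small-flip-angle estimators from two spoiled-gradient-echo
#' acquisitions at a low (proton-density-weighted) and a high
#' (T1-weighted) flip angle,
#' \deqn{R_1 = \frac{1}{2}\,\frac{S_{T1w}\alpha_{T1w}/TR - S_{PDw}\alpha_{PDw}/TR}
#'   {S_{PDw}/\alpha_{PDw} - S_{T1w}/\alpha_{T1w}}, \qquad
#'   A = S_{PDw} S_{T1w}\,\frac{TR\,\alpha_{T1w}/\alpha_{PDw} -
#'   TR\,\alpha_{PDw}/\alpha_{T1w}}{S_{T1w} TR\,\alpha_{T1w} -
#'   S_{PDw} TR\,\alpha_{PDw}}.}
#' Flip angles are scaled by the relative transmit field before use.  Valid
#' in the small-angle regime (up to roughly 25 degrees).
#'
#' @param s_pdw,s_t1w signal intensities of the PDw and T1w volumes.
#' @param alpha_pdw_deg,alpha_t1w_deg nominal flip angles in degrees
#'   (`alpha_pdw_deg < alpha_t1w_deg`).
#' @param tr_s repetition time in seconds (common to both volumes).
#' @param b1_rel relative transmit field.
#' @return a list with components `A` (signal units) and `r1` (1/s).
#' @export
estimate_A_R1 <- function(s_pdw, s_t1w, alpha_pdw_deg = 4, alpha_t1w_deg = 20,
                          tr_s = 0.05, b1_rel = 1) {
  for (nm in c("s_pdw", "s_t1w", "tr_s", "b1_rel")) gamma_check(get(nm), nm)
  if (any(c(s_pdw, s_t1w, tr_s) <= 0) || b1_rel <= 0)
    stop("signals, TR and b1_rel must be positive", call. = FALSE)
  if (alpha_pdw_deg >= alpha_t1w_deg)
    stop("degenerate flip-angle pair: need alpha_pdw < alpha_t1w", call. = FALSE)
  ap <- deg2rad(alpha_pdw_deg) * b1_rel
  at <- deg2rad(alpha_t1w_deg) * b1_rel
  if (s_pdw / ap <= s_t1w / at)
    stop("non-physical signal ordering: S_pdw/alpha_pdw must exceed S_t1w/alpha_t1w",
         call. = FALSE)
  r1 <- 0.5 * (s_t1w * at / tr_s - s_pdw * ap / tr_s) /
    (s_pdw / ap - s_t1w / at)
  A <- s_pdw * s_t1w * (tr_s * at / ap - tr_s * ap / at) /
    (s_t1w * tr_s * at - s_pdw * tr_s * ap)
  list(A = A, r1 = r1)
}

#' MT saturation imposed by one MT pulse
#'
#' Inverts the small-angle MT-weighted spoiled-gradient-echo signal equation
#' `S_mt = A * alpha * R1 * TR / (alpha^2/2 + delta + R1*TR)` for the
#' per-TR saturation `delta`:
#' `delta = (A*alpha/S_mt - 1) * R1 * TR - alpha^2/2`.
#'
#' @param s_mtw MT-weighted signal.
#' @param A,r1 apparent amplitude and longitudinal rate from
#'   [estimate_A_R1()].
#' @param alpha_mtw_deg read flip angle of the MT-weighted volume in degrees.
#' @param tr_s repetition time in seconds.
#' @param b1_rel relative transmit field (scales the read flip angle).
#' @param percent if `TRUE` (default) return percent units (p.u., delta*100).
#' @return the saturation `delta`; values `<= 0` are returned with attribute
#'   `nonphysical = TRUE` (no saturation resolvable).
#' @export
mtsat_delta <- function(s_mtw, A, r1, alpha_mtw_deg = 10, tr_s = 0.05,
                        b1_rel = 1, percent = TRUE) {
  for (nm in c("s_mtw", "A", "r1", "tr_s", "b1_rel")) gamma_check(get(nm), nm)
  if (any(c(s_mtw, A, r1, tr_s, b1_rel) <= 0))
    stop("all inputs must be positive", call. = FALSE)
  a <- deg2rad(alpha_mtw_deg) * b1_rel
  delta <- (A * a / s_mtw - 1) * r1 * tr_s - a^2 / 2
  out <- if (percent) delta * 100 else delta
  if (any(delta <= 0)) attr(out, "nonphysical") <- TRUE
  out
}

#' Semi-empirical B1 correction of MT saturation
#'
#' `delta_corr = delta * (1 - 0.4) / (1 - 0.4 * B1+)`, with 0.4 the
#' empirical correction factor; the identity at nominal transmit field.
#'
#' @param delta uncorrected saturation (any units).
#' @param b1_rel relative transmit field `B1+` in (0, 1.5].
#' @param factor correction factor (default 0.4).
#' @return corrected saturation in the same units as `delta`.
#' @export
mtsat_b1_correct <- function(delta, b1_rel, factor = 0.4) {
  gamma_check(delta, "delta"); gamma_check(b1_rel, "b1_rel")
  if (any(b1_rel <= 0)) stop("b1_rel must be > 0", call. = FALSE)
  den <- 1 - factor * b1_rel
  if (any(den <= 0))
    stop(sprintf("b1_rel >= %g puts the correction denominator at or below zero",
                 1 / factor), call. = FALSE)
  delta * (1 - factor) / den
}

#' MT saturation index from a PDw/MTw/T1w FLASH triplet
#'
#' Convenience wrapper: estimates `A` and `R1` from the PDw/T1w pair,
#' inverts the MT-weighted signal for the per-pulse saturation, and applies
#' the semi-empirical B1 correction.
#'
#' @param s_pdw,s_mtw,s_t1w signals of the three volumes.
#' @param flips_deg nominal read flip angles (PDw, MTw, T1w) in degrees.
#' @param tr_s repetition time in seconds.
#' @param b1_rel relative transmit field.
#' @param correct_b1 apply [mtsat_b1_correct()] (default `TRUE`).
#' @return MT saturation in percent units (p.u.).
#' @export
compute_mtsat <- function(s_pdw, s_mtw, s_t1w, flips_deg = c(4, 10, 20),
                          tr_s = 0.05, b1_rel = 1, correct_b1 = TRUE) {
  ar1 <- estimate_A_R1(s_pdw, s_t1w, flips_deg[1], flips_deg[3], tr_s, b1_rel)
  d <- mtsat_delta(s_mtw, ar1$A, ar1$r1, flips_deg[2], tr_s, b1_rel)
  if (correct_b1) d <- mtsat_b1_correct(as.numeric(d), b1_rel)
  as.numeric(d)
}

#' Magnetization transfer ratio
#'
#' `MTR = 1 - S_mt / S_ref`, as a fraction.
#'
#' @param s_mt signal with the MT pulse.
#' @param s_ref reference signal without (or with far-off-resonance) MT pulse.
#' @return MTR fraction(s).
#' @export
compute_mtr <- function(s_mt, s_ref) {
  gamma_check(s_mt, "s_mt"); gamma_check(s_ref, "s_ref")
  if (any(s_ref == 0)) stop("reference signal is zero", call. = FALSE)
  1 - s_mt / s_ref
}

#' Reference-tissue k-factor for MTR B1 correction
#'
#' Assumes a linear relation between measured MTR and transmit-field error
#' in one reference tissue: `MTR_measured = MTR_corr + k_specific * B1_error`
#' with `B1_error = B1_rel - 1`.  An ordinary least-squares line over the
#' reference-tissue voxels gives the tissue-specific slope `k_specific`, the
#' nominal-field MTR as intercept, and the tissue-independent
#' `k = k_specific / intercept` used by [apply_mtr_correction()].  Fitted per
#' subject.
#'
#' @param mtr_values measured MTR fractions (reference-tissue voxels).
#' @param b1_error transmit-field errors `B1_rel - 1`, same length.
#' @param min_n minimum number of voxels (default 10).
#' @return an object of class `mtr_k_fit`: `k_specific`,
#'   `mtr_at_nominal_b1`, `k`, `n_voxels`, `r_squared`.
#' @export
fit_k <- function(mtr_values, b1_error, min_n = 10L) {
  gamma_check(mtr_values, "mtr_values"); gamma_check(b1_error, "b1_error")
  if (length(mtr_values) != length(b1_error))
    stop("mtr_values and b1_error must have equal length", call. = FALSE)
  if (length(mtr_values) < min_n)
    stop(sprintf("cannot fit k: %d voxels, need at least %d",
                 length(mtr_values), min_n), call. = FALSE)
  if (var(b1_error) <= 0)
    stop("cannot fit k: B1_error has zero spread", call. = FALSE)
  fit <- lm(mtr_values ~ b1_error)
  icpt <- unname(coef(fit)[1]); slope <- unname(coef(fit)[2])
  if (icpt <= 0)
    stop("invalid reference tissue: fitted MTR at nominal B1 is not positive",
         call. = FALSE)
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits warn harmlessly
  structure(list(k_specific = slope, mtr_at_nominal_b1 = icpt,
                 k = slope / icpt, n_voxels = length(mtr_values),
                 r_squared = r2),
            class = "mtr_k_fit")
}

#' @export
print.mtr_k_fit <- function(x, ...) {
  cat(sprintf("MTR B1-correction fit: k = %.4g (k_specific = %.4g, MTR@B1=1: %.4g, n = %d, R2 = %.3f)\n",
              x$k, x$k_specific, x$mtr_at_nominal_b1, x$n_voxels, x$r_squared))
  invisible(x)
}

#' Apply the k-factor MTR correction
#'
#' `MTR_corr = MTR_measured / (k * B1_error + 1)`.
#'
#' @param mtr measured MTR fraction(s).
#' @param b1_error transmit-field error(s) `B1_rel - 1`.
#' @param k tissue-independent factor, from [fit_k()] (`$k`) or given.
#' @return corrected MTR fraction(s).
#' @export
apply_mtr_correction <- function(mtr, b1_error, k) {
  gamma_check(mtr, "mtr"); gamma_check(b1_error, "b1_error")
  if (inherits(k, "mtr_k_fit")) k <- k$k
  gamma_check(k, "k")
  den <- k * b1_error + 1
  if (any(den <= 0))
    stop("correction denominator k*B1_error + 1 is not positive", call. = FALSE)
  mtr / den
}
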