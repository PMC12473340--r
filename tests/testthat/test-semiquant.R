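flash_small_angle <- function(A, r1, alpha_deg, tr, delta = 0) {
  a <- alpha_deg * pi / 180
  A * a * r1 * tr / (a^2 / 2 + delta + r1 * tr)
}

test_that("A and R1 are recovered exactly from small-angle FLASH signals", {
  A <- 1000; r1 <- 0.7; tr <- 0.05
  s_p <- flash_small_angle(A, r1, 4, tr)
  s_t <- flash_small_angle(A, r1, 20, tr)
  est <- estimate_A_R1(s_p, s_t, 4, 20, tr)
  expect_equal(est$A, A, tolerance = 1e-8)
  expect_equal(est$r1, r1, tolerance = 1e-8)

  # consistency: data generated at a scaled field, analysed with the same scale
  b1 <- 1.1
  s_p2 <- flash_small_angle(A, r1, 4 * b1, tr)
  s_t2 <- flash_small_angle(A, r1, 20 * b1, tr)
  est2 <- estimate_A_R1(s_p2, s_t2, 4, 20, tr, b1_rel = b1)
  expect_equal(est2$r1, r1, tolerance = 1e-8)

  expect_error(estimate_A_R1(s_p, s_t, 10, 10, tr), "degenerate")
  expect_error(estimate_A_R1(1, 10, 4, 20, tr), "non-physical")
})

test_that("MT saturation inverts the MT-weighted signal equation", {
  A <- 1000; r1 <- 0.7; tr <- 0.05      # R1*TR = 0.035
  # no MT term -> delta recovered as zero
  s0 <- flash_small_angle(A, r1, 10, tr)
  expect_lt(abs(mtsat_delta(s0, A, r1, 10, tr, percent = FALSE)), 1e-10)
  # algebraic round trip at delta = 0.03 (3 p.u.)
  s <- flash_small_angle(A, r1, 10, tr, delta = 0.03)
  expect_equal(mtsat_delta(s, A, r1, 10, tr, percent = FALSE), 0.03,
               tolerance = 1e-10)
  expect_equal(as.numeric(mtsat_delta(s, A, r1, 10, tr)), 3, tolerance = 1e-8)
  # no saturation resolvable -> flagged
  d <- mtsat_delta(s0 * 1.01, A, r1, 10, tr)
  expect_true(isTRUE(attr(d, "nonphysical")))
})

test_that("semi-empirical B1 correction behaves as specified", {
  expect_equal(mtsat_b1_correct(1.7, 1), 1.7)
  expect_equal(mtsat_b1_correct(1, 0.9), 0.6 / 0.64, tolerance = 1e-12)
  # the printed factor (1-0.4)/(1-0.4*B1) grows with B1 (0.9375 at 0.9,
  # 1 at nominal), i.e. it scales low-B1 measurements up towards nominal
  d <- mtsat_b1_correct(1, c(0.8, 0.9, 1.0, 1.1, 1.2))
  expect_true(all(diff(d) > 0))
  expect_lt(d[1], 1); expect_gt(d[5], 1)
  expect_error(mtsat_b1_correct(1, 2.6), "denominator")
})

test_that("MT_sat is nearly invariant to the read flip-angle triplet", {
  for (t1 in c(1.2, 1.4, 1.8)) {
    truth <- muscle_truth(0.07, t1)
    delta <- two_pool_delta(truth, rf_pulse(500, 1200, 0.009984, 375), 0.05)
    triplet <- function(flips) {
      s <- spgr_signal(1000, t1, flips, 0.05)
      s_m <- spgr_mt_signal(1000, t1, flips[2], 0.05, delta)
      compute_mtsat(s[1], s_m, s[3], flips_deg = flips, tr_s = 0.05)
    }
    d1 <- triplet(c(4, 10, 20))
    d2 <- triplet(c(5, 12, 22))
    expect_lt(abs(d1 - d2) / d1, 0.02)
  }
})

test_that("MTR arithmetic and error handling", {
  expect_equal(compute_mtr(5, 5), 0)
  expect_equal(compute_mtr(0, 5), 1)
  expect_equal(compute_mtr(0.55, 1), 0.45)
  expect_error(compute_mtr(1, 0), "zero")
})

test_that("k-factor fit recovers an exactly linear construction", {
  b1e <- seq(-0.15, 0.15, length.out = 40)
  mtr <- 0.45 * (1 + 0.8 * b1e)
  kf <- fit_k(mtr, b1e)
  expect_equal(kf$k, 0.8, tolerance = 1e-6)
  expect_equal(kf$mtr_at_nominal_b1, 0.45, tolerance = 1e-6)
  expect_equal(kf$r_squared, 1, tolerance = 1e-9)
  # corrected values are flat in B1 error
  corr <- apply_mtr_correction(mtr, b1e, kf)
  expect_lt(abs(unname(coef(lm(corr ~ b1e))[2])), 1e-9)
  # constant MTR -> zero slope, correction leaves values unchanged
  kf0 <- fit_k(rep(0.45, 40), b1e)
  expect_equal(kf0$k, 0, tolerance = 1e-9)
  expect_equal(apply_mtr_correction(rep(0.45, 40), b1e, kf0), rep(0.45, 40))
  # preconditions
  expect_error(fit_k(c(0.4, 0.5), c(-0.1, 0.1)), "at least 10")
  expect_error(fit_k(rep(0.45, 12), rep(0, 12)), "zero spread")
  expect_error(fit_k(seq(-0.2, -0.05, length.out = 12),
                     seq(-0.1, 0.1, length.out = 12)), "reference")
})

test_that("MTR correction arithmetic", {
  expect_equal(apply_mtr_correction(0.48, 0, 0.8), 0.48)
  expect_equal(apply_mtr_correction(0.48, 0.1, 0.8), 0.48 / 1.08,
               tolerance = 1e-12)
  expect_error(apply_mtr_correction(0.48, -2, 0.8), "not positive")
})

test_that("all indices increase monotonically with f and track it linearly", {
  fs <- seq(0.02, 0.12, length.out = 8)
  vals <- t(vapply(fs, physics_indices, numeric(3)))
  for (j in 1:3) expect_true(all(diff(vals[, j]) > 0))
  expect_gt(summary(lm(vals[, "f_so"] ~ fs))$r.squared, 0.99)
  expect_gt(summary(lm(vals[, "mtsat"] ~ fs))$r.squared, 0.99)
  # the ratio index is bounded above, so it compresses at strong MT
  # weighting; over the muscle range only a weaker straight-line bound holds
  expect_gt(summary(lm(vals[, "mtr"] ~ fs))$r.squared, 0.95)
  # over the dilute (gel) range all three are linear
  fg <- seq(0.002, 0.017, length.out = 6)
  vg <- t(vapply(fg, physics_indices, numeric(3)))
  for (j in 1:3) expect_gt(summary(lm(vg[, j] ~ fg))$r.squared, 0.99)
})

test_that("MTR depends on B1 while the k-correction restores flatness", {
  # one tissue seen through a transmit-field gradient
  b1 <- seq(0.85, 1.15, length.out = 25)
  mtr <- vapply(b1, function(b) physics_indices(0.07, b1 = b)[["mtr"]],
                numeric(1))
  slope_raw <- unname(coef(lm(mtr ~ I(b1 - 1)))[2])
  expect_gt(abs(slope_raw), 0.1)      # uncorrected MTR tracks B1
  kf <- fit_k(mtr, b1 - 1)
  corr <- apply_mtr_correction(mtr, b1 - 1, kf)
  slope_corr <- unname(coef(lm(corr ~ I(b1 - 1)))[2])
  expect_lt(abs(slope_corr), abs(slope_raw) / 20)
})
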