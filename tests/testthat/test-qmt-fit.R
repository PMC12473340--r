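test_that("pool-size ratio and macromolecular fraction convert both ways", {
  expect_equal(f_from_pool_ratio(0), 0)
  expect_equal(f_from_pool_ratio(1), 0.5)
  expect_equal(f_from_pool_ratio(0.0753), 0.070, tolerance = 1e-3)
  expect_equal(pool_ratio_from_f(f_from_pool_ratio(0.2)), 0.2, tolerance = 1e-12)
  expect_error(f_from_pool_ratio(-0.1), ">= 0")
  expect_error(pool_ratio_from_f(1.2), "\\[0, 1\\)")
})

test_that("noiseless multi-offset protocol recovers all four parameters", {
  prot <- multioffset_pulses()
  truth <- two_pool_params(0.07, 48, 0.7, 1, 0.035, 6e-6)
  sn <- vapply(prot, function(p) ramani_signal(truth, p), numeric(1))
  for (mode in c("ramani", "yarnykh")) {
    sn_m <- vapply(prot, function(p) ramani_signal(truth, p, mode = mode),
                   numeric(1))
    fit <- qmt_fit(sn_m, prot, ra = 0.7, mode = mode)
    expect_true(fit$converged)
    est <- coef(fit)
    expect_equal(est[["F"]], 0.07, tolerance = 0.01)
    expect_equal(est[["rm0a"]], 48, tolerance = 0.01)
    expect_equal(est[["t2a"]], 0.035, tolerance = 0.01)
    expect_equal(est[["t2b"]], 6e-6, tolerance = 0.01)
  }
  # model-object surface
  fit <- qmt_fit(sn, prot, ra = 0.7)
  expect_s3_class(fit, "qmt_fit")
  expect_length(residuals(fit), 14)
  expect_lt(max(abs(residuals(fit))), 1e-8)
  expect_equal(predict(fit), fit$fitted, tolerance = 1e-12)
  expect_output(print(fit), "f = 0.0654")
  expect_output(print(summary(fit)), "residual quartiles")
  reps <- simulate(fit, nsim = 3, seed = 5, snr = 100)
  expect_equal(dim(reps), c(14L, 3L))
})

test_that("under-determined and degenerate inputs are refused", {
  prot <- multioffset_pulses()
  truth <- muscle_truth()
  sn <- vapply(prot, function(p) ramani_signal(truth, p), numeric(1))
  expect_error(qmt_fit(sn[1:4], prot[1:4], ra = 0.7), "under-determined")
  expect_error(qmt_fit(rep(1, 14), prot, ra = 0.7), "degenerate")
  expect_error(qmt_fit(sn * 3, prot, ra = 0.7), "\\(0, 1.5\\]")
  expect_error(qmt_fit(sn, prot, ra = 0.7, b1_rel = 0.2), "b1_rel")
})

test_that("uncorrected B1 error biases f upward and correction removes it", {
  prot <- multioffset_pulses()
  truth <- two_pool_params(0.07, 48, 0.7, 1, 0.035, 6e-6)
  sn_b1 <- vapply(prot, function(p) ramani_signal(truth, p, b1_rel = 1.1),
                  numeric(1))
  biased <- qmt_fit(sn_b1, prot, ra = 0.7, b1_rel = 1)
  corrected <- qmt_fit(sn_b1, prot, ra = 0.7, b1_rel = 1.1)
  expect_gt(coef(biased)[["F"]], 0.07 * 1.05)
  expect_equal(corrected$f, truth$f, tolerance = 0.01)
})

test_that("multi-offset estimates disperse more than single-offset under noise", {
  prot <- multioffset_pulses()
  truth <- muscle_truth(0.07, 1.4)
  sn0 <- vapply(prot, function(p) ramani_signal(truth, p), numeric(1))
  p_low <- rf_pulse(650, 1e3); p_ref <- rf_pulse(650, 1e5)
  s_low <- ramani_signal(truth, p_low); s_ref <- ramani_signal(truth, p_ref)
  snr <- 100
  f_mo <- with_seed(11, replicate(120, {
    sn <- pmin(rician(sn0, 1 / snr) / rician(1, 1 / snr), 1.5)
    qmt_fit(sn, prot, ra = 1 / 1.4)$f
  }))
  f_so <- with_seed(12, replicate(500, {
    sn <- min(max(rician(s_low, 1 / snr) / rician(s_ref, 1 / snr), 1e-4), 0.999)
    suppressWarnings(solve_single_offset(sn, p_low, 1 / 1.4))$f
  }))
  expect_lt(abs(median(f_so, na.rm = TRUE) - truth$f) / truth$f, 0.05)
  expect_gt(IQR(f_mo, na.rm = TRUE), IQR(f_so, na.rm = TRUE))
})

test_that("single-offset solve inverts the forward model exactly", {
  p_low <- rf_pulse(650, 1e3)
  consts <- single_offset_constants()
  for (f in c(0.02, 0.0753, 0.0909)) {
    ra <- 1 / 1.4
    truth <- two_pool_params(f / (1 - f), consts$rm0a, ra, 1,
                             consts$ra_t2a / ra, consts$t2b_s)
    sn <- ramani_signal(truth, p_low)
    sol <- solve_single_offset(sn, p_low, ra)
    expect_lt(abs(sol$F - truth$F) / truth$F, 1e-6)
  }
  # with B1 and B0 perturbations applied consistently on both sides
  truth <- two_pool_params(0.1, 48, 0.7, 1, 0.025 / 0.7, 6e-6)
  sn <- ramani_signal(truth, p_low, b1_rel = 0.9, b0_hz = 25)
  sol <- solve_single_offset(sn, p_low, 0.7, b1_rel = 0.9, b0_hz = 25)
  expect_lt(abs(sol$F - 0.1) / 0.1, 1e-6)
})

test_that("single-offset edge cases: zero numerator, singular denominator, negative F", {
  p_low <- rf_pulse(650, 1e3)
  w1 <- omega1_cwpe(p_low)
  consts <- single_offset_constants()
  direct <- (w1 / (2 * pi * 1e3))^2 / consts$ra_t2a
  sn_zero <- 1 / (1 + direct)              # numerator term 1 - Sn*(1+D) = 0
  sol <- solve_single_offset(sn_zero, p_low, 0.7)
  expect_equal(sol$F, 0, tolerance = 1e-12)

  r_rfb <- rrfb(w1, 1e3, consts$t2b_s)
  sn_sing <- 1 / (r_rfb + 1)               # Sn*(R_RFB + RB) = RB
  expect_error(solve_single_offset(sn_sing, p_low, 0.7), "singular")

  expect_warning(sol2 <- solve_single_offset(sn_zero * 1.05, p_low, 0.7),
                 "negative")
  expect_true(sol2$nonphysical)
  expect_error(solve_single_offset(1.2, p_low, 0.7), "\\(0, 1\\)")
})
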