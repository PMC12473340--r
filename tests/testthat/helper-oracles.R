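# independent numerical oracles and shared fixtures

# trapezoid-rule quadrature of a function on [a, b]
trapz_quad <- function(f, a, b, n = 1e5) {
  t <- seq(a, b, length.out = n)
  y <- f(t)
  sum((y[-1] + y[-n]) / 2) * (t[2] - t[1])
}

muscle_truth <- function(f = 0.07, t1 = 1.4, rm0a = 48, t2b = 6e-6) {
  two_pool_params(f / (1 - f), rm0a, 1 / t1, 1, 0.025 * t1, t2b)
}

# tiny cohort configuration used by pipeline smoke tests
tiny_config <- function(seed = 1, ...) {
  cohort_config(n_young = 3, n_senior = 3, grid = c(32, 32, 2), seed = seed,
                ...)
}

# noiseless semi-quantitative indices straight from the forward physics
physics_indices <- function(f, t1 = 1.4, b1 = 1) {
  tp <- muscle_truth(f, t1)
  sn1k <- ramani_signal(tp, rf_pulse(650, 1e3), b1_rel = b1)
  sn100k <- ramani_signal(tp, rf_pulse(650, 1e5), b1_rel = b1)
  delta <- two_pool_delta(tp, rf_pulse(500, 1200, 0.009984, 375), 0.05,
                          b1_rel = b1)
  s_p <- spgr_signal(1000, t1, 4 * b1, 0.05)
  s_t <- spgr_signal(1000, t1, 20 * b1, 0.05)
  s_m <- spgr_mt_signal(1000, t1, 10 * b1, 0.05, delta)
  c(f_so = solve_single_offset(sn1k / sn100k, rf_pulse(650, 1e3), 1 / t1,
                               b1_rel = b1)$f,
    mtr = compute_mtr(sn1k, sn100k),
    mtsat = compute_mtsat(s_p, s_m, s_t, b1_rel = b1))
}
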