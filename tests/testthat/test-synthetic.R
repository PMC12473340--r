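test_that("phantoms and acquisitions are fully deterministic under a seed", {
  cfg <- tiny_config(seed = 5)
  p1 <- make_leg_phantom(cfg, 2, "senior")
  p2 <- make_leg_phantom(cfg, 2, "senior")
  expect_identical(p1$truth, p2$truth)
  expect_identical(p1$b1, p2$b1)
  expect_identical(p1$b0, p2$b0)
  s1 <- simulate_protocol(p1, "singleoffset", seed = 9)
  s2 <- simulate_protocol(p2, "singleoffset", seed = 9)
  expect_equal(s1$data, s2$data, tolerance = 1e-12)
  # different subjects differ
  p3 <- make_leg_phantom(cfg, 3, "senior")
  expect_false(identical(p1$truth, p3$truth))
})

test_that("phantom geometry and configured tissue scale are honoured", {
  cfg <- cohort_config(seed = 2)
  ph <- make_leg_phantom(cfg, 1, "young")
  expect_setequal(unique(as.integer(ph$labels)), 0:5)
  counts <- table(ph$labels[ph$labels > 0])
  expect_true(all(counts >= 50))        # every muscle has a usable ROI
  expect_true(all(ph$b1 >= cfg$b1_range[1] & ph$b1 <= cfg$b1_range[2]))
  expect_true(all(abs(ph$b0) <= cfg$b0_range_hz))
  # young defaults sit at the single-offset muscle scale
  expect_true(all(cfg$f_young >= 0.070 & cfg$f_young <= 0.075))
})

test_that("generated group medians reproduce the configured age contrast", {
  cfg <- tiny_config(seed = 31)
  fy <- vapply(1:200, function(i)
    median(make_leg_phantom(cfg, i, "young")$truth$f), numeric(1))
  fs <- vapply(1:200, function(i)
    median(make_leg_phantom(cfg, i, "senior")$truth$f), numeric(1))
  expect_lt(abs((median(fy) - median(fs)) - cfg$f_age_contrast), 1.5e-3)
  t1y <- vapply(1:200, function(i)
    median(make_leg_phantom(cfg, i, "young")$truth$t1), numeric(1))
  t1s <- vapply(1:200, function(i)
    median(make_leg_phantom(cfg, i, "senior")$truth$t1), numeric(1))
  expect_lt(abs((median(t1s) - median(t1y)) -
                  (cfg$t1_senior - cfg$t1_young)), 0.02)
})

test_that("protocol stacks carry the stated volumes, roles and MT pulses", {
  cfg <- tiny_config(seed = 8)
  ph <- make_leg_phantom(cfg, 1, "young")
  mo <- simulate_protocol(ph, "multioffset", snr = Inf)
  expect_equal(dim(mo$data)[4], 15)
  expect_equal(sum(mo$meta$role == "mt"), 14)
  expect_setequal(unique(mo$meta$mt_offset_hz[mo$meta$role == "mt"]),
                  c(1, 2, 5, 10, 20, 50, 100) * 1e3)
  ms <- simulate_protocol(ph, "mtsat", snr = Inf)
  expect_equal(dim(ms$data)[4], 3)
  expect_equal(ms$meta$read_flip_deg, c(4, 10, 20))
  expect_equal(ms$meta$role, c("pdw", "mt", "t1w"))
  expect_true(ms$meta$mt_flip_deg[2] > 0 &&
                all(ms$meta$mt_flip_deg[c(1, 3)] == 0))
  expect_error(simulate_protocol(ph, "ute"), "should be one of")
})

test_that("background voxels show the Rician floor and SNR matches the dial", {
  ph <- mtcalf:::make_agarose_phantom(0.009, 1.8, c(24, 24, 2), seed = 4)
  snr <- 50
  st <- simulate_protocol(ph, "singleoffset", snr = snr, seed = 2)
  bg <- st$data[, , , 2][ph$labels == 0]
  expect_equal(mean(bg), st$sigma * sqrt(pi / 2), tolerance = 0.05)
  # per-voxel noise level across repeated acquisitions matches the dial
  vox <- which(ph$labels == 1)[1]
  sims <- vapply(1:150, function(i)
    simulate_protocol(ph, "singleoffset", snr = snr, seed = 100 + i)$data[, , , 2][vox],
    numeric(1))
  expect_equal(sd(sims), st$sigma, tolerance = 0.15)
  expect_equal(mean(sims) / sd(sims),
               mean(simulate_protocol(ph, "singleoffset", snr = Inf)$data[, , , 2][vox]) /
                 st$sigma, tolerance = 0.05)
})

test_that("agarose preset stores the printed truths and maps f to F", {
  pre <- agarose_preset()
  expect_equal(pre$f_truth[5] / pre$f_truth[1], 8.5)
  F <- pre$f_truth / (1 - pre$f_truth)
  expect_equal(f_from_pool_ratio(F), pre$f_truth, tolerance = 1e-12)
  expect_error(agarose_preset(f_truth = c(0.002, 0.002, 0.009, 0.013, 0.017)),
               "strictly")
})

test_that("noiseless acquisition round trip recovers the phantom truth", {
  cfg <- tiny_config(seed = 13)
  ph <- make_leg_phantom(cfg, 1, "young")
  stacks <- simulate_acquisitions(ph, c("singleoffset", "mtsat", "vfa",
                                        "b0", "b1"), snr = Inf)
  idx <- compute_indices(stacks, ph$labels, ph$muscles)
  t1 <- idx$value[idx$index == "t1"]
  f_so <- idx$value[idx$index == "f_so"]
  expect_equal(t1, ph$truth$t1, tolerance = 5e-3)
  expect_equal(f_so, ph$truth$f, tolerance = 0.02)
})

test_that("senior phantoms have lower f and longer T1 on the defaults", {
  cfg <- cohort_config(seed = 77)
  fy <- rowMeans(vapply(1:60, function(i)
    make_leg_phantom(cfg, i, "young")$truth$f, numeric(5)))
  fs <- rowMeans(vapply(1:60, function(i)
    make_leg_phantom(cfg, i, "senior")$truth$f, numeric(5)))
  expect_true(all(fy > fs))        # per muscle
})
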