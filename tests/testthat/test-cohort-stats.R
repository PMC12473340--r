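make_table <- function(young, senior, index = "f_so") {
  rbind(data.frame(subject = paste0("Y", seq_along(young)), group = "young",
                   muscle = "SOL", index = index, value = young),
        data.frame(subject = paste0("S", seq_along(senior)), group = "senior",
                   muscle = "SOL", index = index, value = senior))
}

test_that("normality gate separates Gaussian from skewed samples", {
  expect_equal(with_seed(1, normality_gate(rnorm(200))), "normal")
  nn <- with_seed(2, vapply(1:50, function(i)
    normality_gate(rexp(100)), character(1)))
  expect_gte(mean(nn == "non_normal"), 0.99)
  expect_equal(normality_gate(rep(1, 10)), "non_normal")  # degenerate, no crash
  expect_error(normality_gate(c(1, 2)), "at least 3")
})

test_that("Hodges-Lehmann estimate matches the brute-force definition", {
  cmp <- compare_age_groups(make_table(c(1, 2, 3), c(0, 1)), "f_so")
  expect_equal(cmp$hl_estimate, 1.5)  # median of {1,0,2,1,3,2}
  # random instances against an independent implementation (wilcox.test)
  with_seed(42, for (i in 1:25) {
    x <- rnorm(sample(5:40, 1)); y <- rnorm(sample(5:40, 1), mean = 0.3)
    hl <- mtcalf:::hl_estimate(x, y)
    expect_equal(hl, median(as.vector(outer(x, y, "-"))))
    wt <- suppressWarnings(wilcox.test(x, y, conf.int = TRUE))
    expect_equal(hl, unname(wt$estimate), tolerance = 1e-6)
  })
})

test_that("rank-biserial r satisfies the U identity and label symmetry", {
  with_seed(7, for (i in 1:25) {
    x <- rnorm(12); y <- rnorm(9, 0.5)
    u <- sum(outer(x, y, "<")) + 0.5 * sum(outer(x, y, "=="))
    expect_equal(mtcalf:::rank_biserial(x, y), 1 - 2 * u / (12 * 9),
                 tolerance = 1e-12)
    expect_equal(mtcalf:::rank_biserial(y, x), -mtcalf:::rank_biserial(x, y),
                 tolerance = 1e-12)
  })
  # complete separation
  expect_equal(mtcalf:::rank_biserial(2:4, 0:1), 1)
  # identical groups
  cmp <- compare_age_groups(make_table(1:6, 1:6), "f_so")
  expect_equal(cmp$hl_estimate, 0)
  expect_equal(cmp$rank_biserial_r, 0)
  expect_gt(cmp$p_two_sided, 0.9)
})

test_that("group comparison reports coherent effect sizes and direction", {
  y <- c(7.2, 7.4, 7.1, 7.6, 7.3, 7.5, 7.0, 7.35, 7.25)
  s <- c(6.6, 6.8, 6.5, 6.9, 6.7)
  cmp <- compare_age_groups(make_table(y, s), "f_so")
  expect_lt(cmp$p_two_sided, 0.01)
  expect_true(cmp$ci_low <= cmp$hl_estimate && cmp$hl_estimate <= cmp$ci_high)
  expect_equal(cmp$rank_biserial_r, 1)        # complete separation
  expect_equal(cmp$magnitude, "large")
  expect_equal(cmp$direction, "Y > O")
  # magnitude thresholds reproduce the conventional labels
  expect_equal(compare_age_groups(make_table(c(1, 2, 3, 4), c(1.5, 2.5, 3.5, 4.5)),
                                  "f_so")$magnitude, "small")
  expect_error(compare_age_groups(make_table(1:3, 0.5), "f_so"),
               "at least 2")
})

test_that("regional comparison applies the Bonferroni factor per pair count", {
  tab <- with_seed(3, data.frame(
    subject = rep(paste0("P", 1:20), each = 2), group = "young",
    muscle = rep(c("TA", "SOL"), 20), index = "mtr",
    value = c(rbind(rnorm(20, 0.5, 0.01), rnorm(20, 0.4, 0.01)))))
  res <- compare_regions(tab, "mtr")
  expect_lt(res$kw_p, 0.05)
  expect_equal(nrow(res$posthoc), 1)          # two muscles -> one pair
  expect_equal(res$posthoc$p_bonferroni, res$posthoc$p_raw)  # factor 1
  expect_error(compare_regions(tab[tab$muscle == "TA", ], "mtr"), "2 muscles")
})

test_that("one shifted muscle survives Bonferroni in the five-muscle design", {
  muscles <- c("SOL", "MG", "LG", "TA", "TP")
  tab <- with_seed(11, do.call(rbind, lapply(muscles, function(m)
    data.frame(subject = paste0("P", 1:24), group = "young", muscle = m,
               index = "mtr",
               value = rnorm(24, 0.45 + if (m == "TA") 0.045 else 0, 0.015)))))
  res <- compare_regions(tab, "mtr")
  expect_lt(res$kw_p, 0.05)
  expect_equal(nrow(res$posthoc), 10)
  hits <- res$posthoc[res$posthoc$p_bonferroni < 0.05, ]
  expect_true(all(hits$muscle_a == "TA" | hits$muscle_b == "TA"))
  expect_gte(nrow(hits), 3)
})

test_that("Kruskal-Wallis null rate is close to the nominal level", {
  rate <- with_seed(17, mean(replicate(2000, {
    v <- rnorm(120)
    kruskal.test(v, factor(rep(1:5, 24)))$p.value < 0.05
  })))
  expect_gt(rate, 0.035); expect_lt(rate, 0.065)
})

sim_t1_table <- function(age_shift, seed, sd_sub = 0.025, sd_mus = 0.01) {
  muscles <- c("SOL", "MG", "LG", "TA", "TP")
  with_seed(seed, {
    rows <- list()
    for (g in c("young", "senior")) {
      n <- if (g == "young") 15 else 9
      for (i in 1:n) {
        base <- 1.40 + if (g == "senior") age_shift else 0
        sub <- rnorm(1, 0, sd_sub)
        rows[[length(rows) + 1]] <- data.frame(
          subject = paste0(substr(g, 1, 1), i), group = g, muscle = muscles,
          index = "t1", value = base + sub + rnorm(5, 0, sd_mus))
      }
    }
    do.call(rbind, rows)
  })
}

test_that("two-way ANOVA detects the age effect and respects the null", {
  hits <- vapply(1:40, function(s) {
    res <- anova_t1(sim_t1_table(0.07, seed = 400 + s))
    res$p_age < 0.05 && res$p_region > 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  # null calibration on independent observations (no subject clustering)
  null_rate <- mean(vapply(1:1000, function(s)
    anova_t1(sim_t1_table(0, seed = 6000 + s, sd_sub = 0))$p_age < 0.05,
    logical(1)))
  expect_gt(null_rate, 0.025); expect_lt(null_rate, 0.075)
  # diagnostics come along
  res <- anova_t1(sim_t1_table(0.07, seed = 1))
  expect_true(is.finite(res$levene_p))
  # single subject per cell is refused
  bad <- sim_t1_table(0.07, seed = 2)
  bad <- bad[!(bad$group == "senior" & bad$subject != "s1"), ]
  expect_error(anova_t1(bad), "cells")
})

test_that("index-T1 regression recovers exact and null relations", {
  muscles <- c("SOL", "MG", "LG", "TA", "TP")
  t1 <- seq(1.3, 1.5, length.out = 20)
  tab <- rbind(
    data.frame(subject = paste0("P", 1:20), group = "young",
               muscle = rep(muscles, 4), index = "t1", value = t1),
    data.frame(subject = paste0("P", 1:20), group = "young",
               muscle = rep(muscles, 4), index = "f_so",
               value = 0.2 - 0.1 * t1))
  r <- correlate_with_t1(tab, "f_so")
  expect_equal(r$pearson_r, -1, tolerance = 1e-9)
  expect_equal(r$slope, -0.1, tolerance = 1e-9)
  # independent data: p roughly uniform
  ps <- with_seed(23, replicate(200, {
    tab$value[tab$index == "f_so"] <- rnorm(20)
    correlate_with_t1(tab, "f_so")$p
  }))
  expect_gt(mean(ps), 0.4); expect_lt(mean(ps), 0.62)
  expect_error(correlate_with_t1(tab[1:4, ], "f_so"), "paired|3")
})
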