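#' Shapiro-Wilk normality gate
#'
#' Decides the downstream statistical branch: parametric analysis when the
#' sample is compatible with normality at the 0.05 level, nonparametric
#' otherwise.  Degenerate (constant) samples are classified `"non_normal"`.
#'
#' @param values numeric sample, `n >= 3`.
#' @param alpha significance level of the gate.
#' @return `"normal"` or `"non_normal"`.
#' @export
normality_gate <- function(values, alpha = 0.05) {
  gamma_check(values, "values")
  if (length(values) < 3)
    stop("normality gate needs at least 3 values", call. = FALSE)
  if (diff(range(values)) == 0) return("non_normal")
  p <- shapiro.test(values)$p.value
  if (p < alpha) "non_normal" else "normal"
}

hl_estimate <- function(x, y) median(outer(x, y, "-"))

rank_biserial <- function(x, y) {
  # U counts pairs with x < y (ties half); r = 1 - 2U/(n1 n2):
  # +1 under complete separation x > y
  r <- rank(c(x, y))
  w <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2  # pairs x > y
  u <- length(x) * length(y) - w
  1 - 2 * u / (length(x) * length(y))
}

#' Nonparametric age-group comparison of one index
#'
#' Pools the per-muscle ROI values of each group and compares young versus
#' senior with a two-sided Mann-Whitney U test.  Effect sizes follow the
#' standard nonparametric pair: the Hodges-Lehmann estimator of the median
#' young-minus-senior difference (median of all pairwise differences) with a
#' rank-based 95\% confidence interval, and the rank-biserial correlation
#' `r = 1 - 2U/(n1*n2)` with qualitative magnitude labels (|r| < 0.3 small,
#' 0.3-0.5 medium, > 0.5 large).
#'
#' @param table a [cohort_table()] (columns `group`, `index`, `value`).
#' @param index_name which index to compare.
#' @param conf_level confidence level of the HL interval.
#' @return an object of class `group_comparison`: `index`, `p_two_sided`,
#'   `hl_estimate`, `ci_low`, `ci_high`, `rank_biserial_r`, `magnitude`,
#'   `direction`, `n_young`, `n_senior`.
#' @export
compare_age_groups <- function(table, index_name, conf_level = 0.95) {
  d <- table[table$index == index_name & is.finite(table$value), ]
  x <- d$value[d$group == "young"]
  y <- d$value[d$group == "senior"]
  if (length(x) < 2 || length(y) < 2)
    stop("both groups need at least 2 values for index ", index_name,
         call. = FALSE)
  wt <- suppressWarnings(wilcox.test(x, y, conf.int = TRUE,
                                     conf.level = conf_level))
  hl <- hl_estimate(x, y)
  r <- rank_biserial(x, y)
  magnitude <- if (abs(r) < 0.3) "small" else if (abs(r) <= 0.5) "medium" else "large"
  structure(list(index = index_name, p_two_sided = wt$p.value,
                 hl_estimate = hl,
                 ci_low = unname(wt$conf.int[1]),
                 ci_high = unname(wt$conf.int[2]),
                 rank_biserial_r = r, magnitude = magnitude,
                 direction = if (hl > 0) "Y > O" else if (hl < 0) "Y < O" else "Y = O",
                 n_young = length(x), n_senior = length(y)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: p = %.3g, HL(Y-O) = %.4g [%.4g, %.4g], r = %.2f (%s), %s\n",
              x$index, x$p_two_sided, x$hl_estimate, x$ci_low, x$ci_high,
              x$rank_biserial_r, x$magnitude, x$direction))
  invisible(x)
}

#' @export
as.data.frame.group_comparison <- function(x, ...) {
  data.frame(index = x$index, p_two_sided = x$p_two_sided,
             hl_estimate = x$hl_estimate, ci_low = x$ci_low,
             ci_high = x$ci_high, rank_biserial_r = x$rank_biserial_r,
             magnitude = x$magnitude, direction = x$direction,
             n_young = x$n_young, n_senior = x$n_senior)
}

#' Regional (between-muscle) comparison of one index
#'
#' Kruskal-Wallis test across the muscles (both age groups pooled); when it
#' is significant at `alpha`, all pairwise Mann-Whitney post hocs are run
#' with Bonferroni adjustment over the number of pairs.
#'
#' @param table a [cohort_table()].
#' @param index_name which index to compare.
#' @param alpha significance level gating the post hocs.
#' @return a list with `kw_p`, `n_muscles`, and `posthoc` (a data frame of
#'   pairwise raw and Bonferroni-adjusted p values, or `NULL`).
#' @export
compare_regions <- function(table, index_name, alpha = 0.05) {
  d <- table[table$index == index_name & is.finite(table$value), ]
  muscles <- unique(d$muscle)
  if (length(muscles) < 2)
    stop("regional comparison needs at least 2 muscles", call. = FALSE)
  kw <- kruskal.test(d$value, factor(d$muscle))
  posthoc <- NULL
  if (kw$p.value < alpha) {
    pairs <- combn(muscles, 2)
    np <- ncol(pairs)
    posthoc <- do.call(rbind, lapply(seq_len(np), function(j) {
      a <- d$value[d$muscle == pairs[1, j]]
      b <- d$value[d$muscle == pairs[2, j]]
      p <- suppressWarnings(wilcox.test(a, b)$p.value)
      data.frame(muscle_a = pairs[1, j], muscle_b = pairs[2, j],
                 p_raw = p, p_bonferroni = min(1, p * np))
    }))
  }
  list(index = index_name, kw_p = kw$p.value, n_muscles = length(muscles),
       posthoc = posthoc)
}

#' Two-way (age x region) ANOVA for T1
#'
#' Factorial analysis of the normally distributed T1 values: main effects of
#' age group and muscle plus their interaction, with Levene's test attached
#' as the homogeneity-of-variance diagnostic and Bonferroni-adjusted
#' pairwise t post hocs on the region factor when it is significant.
#'
#' @param table a [cohort_table()] restricted (internally) to the T1 index.
#' @param index_name index holding T1 values (default `"t1"`).
#' @param alpha significance level gating the post hocs.
#' @return a list with `anova` (the summary table), `p_age`, `p_region`,
#'   `p_interaction`, `levene_p`, and `posthoc`.
#' @export
anova_t1 <- function(table, index_name = "t1", alpha = 0.05) {
  d <- table[table$index == index_name & is.finite(table$value), ]
  if (!nrow(d)) stop("no T1 values in table", call. = FALSE)
  d$group <- factor(d$group); d$muscle <- factor(d$muscle)
  cells <- table(d$group, d$muscle)
  if (any(cells < 2))
    stop("age x region design has cells with fewer than 2 observations",
         call. = FALSE)
  fit <- aov(value ~ group * muscle, data = d)
  tab <- summary(fit)[[1]]
  pv <- tab[["Pr(>F)"]]
  lev <- car::leveneTest(value ~ group * muscle, data = d)
  posthoc <- NULL
  if (pv[2] < alpha)
    posthoc <- pairwise.t.test(d$value, d$muscle, p.adjust.method = "bonferroni")
  list(anova = tab, p_age = pv[1], p_region = pv[2], p_interaction = pv[3],
       levene_p = lev[["Pr(>F)"]][1], posthoc = posthoc)
}

#' Linear association between an MT index and T1
#'
#' Pairs each (subject, muscle) ROI value of the index with its T1 value and
#' reports the Pearson correlation with its two-sided p value plus the
#' least-squares line.
#'
#' @param table a [cohort_table()] containing both the index and T1 rows.
#' @param index_name the MT index.
#' @param t1_name index name holding T1 (default `"t1"`).
#' @return a list: `pearson_r`, `p`, `slope`, `intercept`, `n`.
#' @export
correlate_with_t1 <- function(table, index_name, t1_name = "t1") {
  a <- table[table$index == index_name, c("subject", "muscle", "value")]
  b <- table[table$index == t1_name, c("subject", "muscle", "value")]
  m <- merge(a, b, by = c("subject", "muscle"), suffixes = c("_idx", "_t1"))
  m <- m[is.finite(m$value_idx) & is.finite(m$value_t1), ]
  if (nrow(m) < 3)
    stop("need at least 3 paired (index, T1) values", call. = FALSE)
  ct <- cor.test(m$value_t1, m$value_idx, method = "pearson")
  fit <- lm(value_idx ~ value_t1, data = m)
  list(index = index_name, pearson_r = unname(ct$estimate), p = ct$p.value,
       slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       n = nrow(m))
}
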