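# Statistical comparisons used for cohort contrasts. Standard tests are
# delegated to stats:: implementations behind a uniform result container;
# the nested ANOVA is computed from its sums of squares directly.

stat_result <- function(test, statistic, df, p_value, groups = NULL) {
  stopifnot(is.na(p_value) || (p_value >= 0 && p_value <= 1))
  structure(list(test = test, statistic = unname(statistic),
                 df = unname(df), p_value = unname(p_value),
                 groups = groups),
            class = "stat_test_result")
}

#' @export
print.stat_test_result <- function(x, ...) {
  df_txt <- if (length(x$df)) paste(signif(x$df, 4), collapse = ", ") else "-"
  cat(sprintf("<%s> statistic = %.4g, df = %s, p = %.4g\n",
              x$test, x$statistic, df_txt, x$p_value))
  invisible(x)
}

#' Pearson chi-squared test on a 2x2 table
#'
#' Frequencies comparison without continuity correction (df = 1); the
#' Yates correction can be enabled for sensitivity analyses.
#'
#' @param a,b,c,d non-negative integer cell counts, rows `(a, b)` and
#'   `(c, d)`.
#' @param correct apply the Yates continuity correction (default FALSE).
#' @return a `stat_test_result`.
#' @export
chi_squared_2x2 <- function(a, b, c, d, correct = FALSE) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("chi_squared_2x2: counts must be non-negative integers")
  }
  m <- matrix(counts, 2, 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("chi_squared_2x2: zero row or column margin")
  }
  res <- suppressWarnings(stats::chisq.test(m, correct = correct))
  stat_result("chi-squared (2x2)", res$statistic, res$parameter, res$p.value,
              groups = list(observed = m, expected = res$expected))
}

#' Welch two-sample t test
#'
#' Two-sided t test with the Welch-Satterthwaite degrees of freedom.
#' When both samples have zero variance and equal means, p = 1 by
#' convention (no evidence of difference, t = 0).
#'
#' @param x,y numeric samples of size >= 2.
#' @return a `stat_test_result`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    stop("welch_t: both samples need >= 2 observations")
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      return(stat_result("Welch t", 0, NA_real_, 1,
                         groups = list(mean_x = mean(x), mean_y = mean(y))))
    }
    stop("welch_t: zero variance in both samples with unequal means")
  }
  res <- stats::t.test(x, y, var.equal = FALSE)
  stat_result("Welch t", res$statistic, res$parameter, res$p.value,
              groups = list(mean_x = mean(x), mean_y = mean(y),
                            sd_x = stats::sd(x), sd_y = stats::sd(y)))
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Two-sided; exact when the combined sample size is at most 20 and there
#' are no ties, otherwise the normal approximation with tie correction
#' (no continuity correction, so identical samples give p = 1).
#'
#' @param x,y non-empty numeric samples.
#' @return a `stat_test_result` (statistic is the Mann-Whitney U of `x`).
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) {
    stop("mann_whitney: both samples must be non-empty")
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= 20 && !ties
  res <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = FALSE)
  )
  stat_result("Mann-Whitney", res$statistic, NA_real_, res$p.value,
              groups = list(n_x = length(x), n_y = length(y),
                            exact = exact))
}

#' Two-level nested ANOVA (oocytes nested in groups)
#'
#' Tests the group effect against the among-oocyte-within-group mean
#' square, the appropriate error stratum when chromosomes within an
#' oocyte are pseudo-replicates: `F = MS_group / MS_oocyte(group)` with
#' `df = (G - 1, sum(O_g) - G)`. Unbalanced designs are allowed (sums of
#' squares weighted by observation counts).
#'
#' @param values numeric observations (e.g. one per chromosome).
#' @param oocyte_ids oocyte identifier per observation.
#' @param group_ids group (e.g. age) label per observation.
#' @return a `stat_test_result`.
#' @export
nested_anova <- function(values, oocyte_ids, group_ids) {
  stopifnot(length(values) == length(oocyte_ids),
            length(values) == length(group_ids))
  keep <- is.finite(values)
  values <- values[keep]
  oocyte_ids <- as.character(oocyte_ids)[keep]
  group_ids <- as.character(group_ids)[keep]
  groups <- unique(group_ids)
  if (length(groups) < 2) stop("nested_anova: need >= 2 groups")
  per_group_oocytes <- tapply(oocyte_ids, group_ids,
                              function(o) length(unique(o)))
  if (any(per_group_oocytes < 2)) {
    stop("nested_anova: need >= 2 oocytes per group")
  }
  grand <- mean(values)
  ss_group <- 0
  ss_oocyte <- 0
  for (g in groups) {
    vg <- values[group_ids == g]
    og <- oocyte_ids[group_ids == g]
    gm <- mean(vg)
    ss_group <- ss_group + length(vg) * (gm - grand)^2
    for (o in unique(og)) {
      vo <- vg[og == o]
      ss_oocyte <- ss_oocyte + length(vo) * (mean(vo) - gm)^2
    }
  }
  df_group <- length(groups) - 1
  df_oocyte <- sum(per_group_oocytes) - length(groups)
  ms_group <- ss_group / df_group
  ms_oocyte <- ss_oocyte / df_oocyte
  if (ms_oocyte == 0) {
    if (ms_group == 0) {
      return(stat_result("nested ANOVA", 0, c(df_group, df_oocyte), 1))
    }
    stop("nested_anova: singular design (zero among-oocyte variance with ",
         "non-zero group effect)")
  }
  f_stat <- ms_group / ms_oocyte
  p <- stats::pf(f_stat, df_group, df_oocyte, lower.tail = FALSE)
  stat_result("nested ANOVA", f_stat, c(df_group, df_oocyte), p,
              groups = list(ss_group = ss_group, ss_oocyte = ss_oocyte,
                            ms_group = ms_group, ms_oocyte = ms_oocyte))
}
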