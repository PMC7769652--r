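#' Pooled-variance two-sample t-test from summary statistics
#'
#' The independent-sample t-test used throughout the package, in the form
#' that reproduces cohort-table P values from printed mean +/- SD and n:
#' \deqn{t = (\bar x_a - \bar x_b) / \sqrt{s_p^2 (1/n_a + 1/n_b)}, \quad
#'       s_p^2 = \frac{(n_a-1)s_a^2 + (n_b-1)s_b^2}{n_a+n_b-2}}
#' with df = n_a + n_b - 2 and a two-sided P from the t distribution.
#' Pooled variance (not Welch) is used: it is what reproduces the published
#' blood-pressure P values at 3-decimal rounding.
#'
#' Degenerate variance: both SDs zero with equal means returns t = 0,
#' P = 1 by convention; zero pooled variance with unequal means returns
#' P = 0 with `degenerate = TRUE`.
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b group summaries; both n >= 2.
#' @return list with `t`, `df`, `p_value`, `degenerate`.
#' @examples
#' # systolic blood pressure, 5 cases vs 3 controls
#' t_test_from_summary(150, 11.40, 5, 119, 15.59, 3)$p_value  # ~0.017
#' @export
t_test_from_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  if (n_a < 2 || n_b < 2)
    stop("design error: both groups need n >= 2", call. = FALSE)
  if (sd_a < 0 || sd_b < 0)
    stop("value error: sd must be >= 0", call. = FALSE)
  df <- n_a + n_b - 2
  sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / df
  if (sp2 == 0) {
    if (mean_a == mean_b)
      return(list(t = 0, df = df, p_value = 1, degenerate = FALSE))
    return(list(t = sign(mean_a - mean_b) * Inf, df = df, p_value = 0,
                degenerate = TRUE))
  }
  tstat <- (mean_a - mean_b) / sqrt(sp2 * (1 / n_a + 1 / n_b))
  list(t = tstat, df = df, p_value = 2 * stats::pt(-abs(tstat), df),
       degenerate = FALSE)
}

#' Pooled-variance t-test on raw vectors
#'
#' Shared kernel used by the per-probe tests and the qPCR group comparison;
#' identical to [t_test_from_summary()] applied to the sample summaries.
#'
#' @param x,y numeric vectors, length >= 2 each.
#' @return list with `t`, `df`, `p_value`, `degenerate`.
#' @export
t_test_pooled <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("design error: both groups need n >= 2", call. = FALSE)
  t_test_from_summary(mean(x), stats::sd(x), length(x),
                      mean(y), stats::sd(y), length(y))
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Two-sided P as the sum of probabilities of all tables (with the observed
#' margins) no more probable than the observed one.
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return the P value.
#' @examples
#' fisher_2x2(matrix(c(5, 1, 0, 2), 2))  # gender split 5/5 vs 1/3
#' @export
fisher_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2L))
    stop("value error: expected a 2x2 table", call. = FALSE)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("value error: counts must be nonnegative integers", call. = FALSE)
  stats::fisher.test(tab)$p.value
}

#' Chi-square test on an r x c contingency table
#'
#' Pearson chi-square without continuity correction, used for the pooled
#' comorbidity rows of cohort tables (a single P over a 2 x k category
#' table). Cells with zero margins are dropped.
#'
#' @param tab matrix of nonnegative counts.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
chisq_table <- function(tab) {
  tab <- as.matrix(tab)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (any(dim(tab) < 2L))
    stop("value error: degenerate table after dropping empty margins",
         call. = FALSE)
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value)
}

#' Cohort summary-statistics table tests
#'
#' Applies [t_test_from_summary()] to each row of a cohort table of the form
#' printed in clinical papers: one row per continuous variable with mean, SD
#' and n per group.
#'
#' @param df data.frame with columns `variable`, `mean_a`, `sd_a`, `n_a`,
#'   `mean_b`, `sd_b`, `n_b`.
#' @return the input with `t`, `df`, `p_value` columns appended.
#' @export
cohort_table_tests <- function(df) {
  need <- c("variable", "mean_a", "sd_a", "n_a", "mean_b", "sd_b", "n_b")
  if (!all(need %in% names(df)))
    stop("schema error: cohort table needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  res <- lapply(seq_len(nrow(df)), function(i)
    t_test_from_summary(df$mean_a[i], df$sd_a[i], df$n_a[i],
                        df$mean_b[i], df$sd_b[i], df$n_b[i]))
  df$t <- vapply(res, `[[`, 0, "t")
  df$df <- vapply(res, `[[`, 0, "df")
  df$p_value <- vapply(res, `[[`, 0, "p_value")
  df
}
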