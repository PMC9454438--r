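# Agreement and reliability battery for duplicate HCI measurements:
# paired t-test, Bland-Altman limits of agreement, and the two-way
# mixed, single-measure, consistency intraclass correlation ICC(3,1).
#
# Conventions: the 95% limits of agreement use the constant 1.96
# exactly (the textbook Bland-Altman formula), while the confidence
# interval of the mean difference uses the t quantile. Differences are
# d_i = a_i - b_i. All tests are two-sided at alpha = 0.05.

.paired_series <- function(values_a, values_b) {
  a <- as.numeric(values_a); b <- as.numeric(values_b)
  if (length(a) != length(b))
    abort_hci("paired series must have equal length", "hci_sample_size_error")
  keep <- is.finite(a) & is.finite(b)
  a <- a[keep]; b <- b[keep]
  if (length(a) < 2L)
    abort_hci("paired analysis needs at least 2 complete pairs",
              "hci_sample_size_error")
  list(a = a, b = b, d = a - b, n = length(a))
}

#' Paired t-test on duplicate measurements
#'
#' Tests for a systematic difference between two aligned measurement
#' series (e.g. session 1 vs session 2 of one examiner).
#'
#' @param values_a,values_b aligned numeric vectors (same hips, same
#'   order).
#' @param conf_level confidence level of the interval of the mean
#'   difference.
#' @return list with `mean_diff`, `sd_diff`, `ci` (length 2), `t`,
#'   `df`, `p_value`, `n`. With zero-variance differences the result is
#'   flagged `degenerate`: `t` and `p_value` are `NA` and the CI
#'   collapses to the point `mean_diff`.
#' @export
paired_t_test <- function(values_a, values_b, conf_level = 0.95) {
  s <- .paired_series(values_a, values_b)
  m <- mean(s$d); sdd <- stats::sd(s$d); n <- s$n
  df <- n - 1L
  if (sdd == 0) {
    return(list(mean_diff = m, sd_diff = 0, ci = c(m, m), t = NA_real_,
                df = df, p_value = NA_real_, n = n, degenerate = TRUE))
  }
  se <- sdd / sqrt(n)
  tstat <- m / se
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df)
  list(mean_diff = m, sd_diff = sdd, ci = c(m - tcrit * se, m + tcrit * se),
       t = tstat, df = df, p_value = 2 * stats::pt(abs(tstat), df,
                                                   lower.tail = FALSE),
       n = n, degenerate = FALSE)
}

#' 95% limits of agreement from summary statistics
#'
#' @param mean_diff mean of the paired differences.
#' @param sd_diff standard deviation of the paired differences
#'   (non-negative).
#' @return numeric length 2: `mean_diff` plus/minus `1.96 * sd_diff`.
#' @export
loa_from_summary <- function(mean_diff, sd_diff) {
  if (sd_diff < 0)
    abort_hci("sd_diff must be non-negative", "hci_parameter_error")
  c(lower = mean_diff - 1.96 * sd_diff, upper = mean_diff + 1.96 * sd_diff)
}

#' Confidence interval of a mean from summary statistics
#'
#' The t-based interval `mean +/- t_{1-alpha/2, n-1} * sd / sqrt(n)`,
#' the same machinery behind both the paired-difference CI and the
#' per-grade descriptive CIs.
#'
#' @param mean,sd,n sample mean, standard deviation (n-1 denominator)
#'   and size.
#' @param level confidence level.
#' @return numeric length 2 (lower, upper).
#' @export
ci_mean_from_summary <- function(mean, sd, n, level = 0.95) {
  if (n < 2)
    abort_hci("n must be at least 2", "hci_sample_size_error")
  if (sd < 0)
    abort_hci("sd must be non-negative", "hci_parameter_error")
  half <- stats::qt(1 - (1 - level) / 2, n - 1) * sd / sqrt(n)
  c(lower = mean - half, upper = mean + half)
}

#' Bland-Altman agreement analysis
#'
#' Summarizes the pattern and extent of agreement between two aligned
#' measurement series: mean difference with its 95% CI, and the 95%
#' limits of agreement expected to contain about 95% of paired
#' differences. Per-pair (average, difference) points are returned for
#' plotting.
#'
#' @inheritParams paired_t_test
#' @return list of class `bland_altman` with `mean_diff`, `sd_diff`,
#'   `loa_lower`, `loa_upper`, `ci_mean_lower`, `ci_mean_upper`, `n`,
#'   and a data frame `points` (columns `average`, `difference`).
#' @export
bland_altman <- function(values_a, values_b, conf_level = 0.95) {
  s <- .paired_series(values_a, values_b)
  tt <- paired_t_test(values_a, values_b, conf_level)
  loa <- loa_from_summary(tt$mean_diff, tt$sd_diff)
  structure(list(mean_diff = tt$mean_diff, sd_diff = tt$sd_diff,
                 loa_lower = unname(loa[1L]), loa_upper = unname(loa[2L]),
                 ci_mean_lower = tt$ci[1L], ci_mean_upper = tt$ci[2L],
                 n = tt$n,
                 points = data.frame(average = (s$a + s$b) / 2,
                                     difference = s$d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d)\n", x$n))
  cat(sprintf("  mean difference %.4f (95%% CI %.4f to %.4f)\n",
              x$mean_diff, x$ci_mean_lower, x$ci_mean_upper))
  cat(sprintf("  95%% limits of agreement %.4f to %.4f\n",
              x$loa_lower, x$loa_upper))
  invisible(x)
}

#' Intraclass correlation ICC(3,1)
#'
#' Two-way mixed-effects, single-measure, consistency ICC in the
#' Shrout-Fleiss convention: `(MS_R - MS_E) / (MS_R + (k-1) MS_E)` from
#' the two-way ANOVA decomposition with rows = measured units (hips)
#' and columns = raters (examiners or sessions). Fixed shifts between
#' raters do not lower this form of the ICC. The 95% CI uses the
#' F-bound construction and the p-value the F test of `MS_R / MS_E`.
#'
#' @param ratings numeric matrix, units in rows, raters in columns;
#'   complete, with at least 5 units and 2 raters.
#' @param conf_level confidence level for the ICC interval.
#' @return list of class `icc_result` with `icc`, `ci_lower`,
#'   `ci_upper`, `f_value`, `df1`, `df2`, `p_value`, `interpretation`
#'   (see [interpret_icc()]), `n`, `k`.
#' @export
icc_3_1 <- function(ratings, conf_level = 0.95) {
  m <- as.matrix(ratings)
  if (any(!is.finite(m)))
    abort_hci("ratings matrix has missing or non-finite cells",
              "hci_incomplete_data")
  n <- nrow(m); k <- ncol(m)
  if (n < 5L)
    abort_hci("ICC needs at least 5 units (rows)", "hci_sample_size_error")
  if (k < 2L)
    abort_hci("ICC needs at least 2 raters (columns)", "hci_sample_size_error")
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  df1 <- n - 1L
  df2 <- (n - 1L) * (k - 1L)
  ms_r <- ss_rows / df1
  ms_e <- max(ss_err, 0) / df2
  if (ms_e == 0) {
    icc <- 1
    out <- list(icc = 1, ci_lower = 1, ci_upper = 1, f_value = Inf,
                df1 = df1, df2 = df2, p_value = 0)
  } else {
    icc <- (ms_r - ms_e) / (ms_r + (k - 1) * ms_e)
    fv <- ms_r / ms_e
    alpha <- 1 - conf_level
    fl <- fv / stats::qf(1 - alpha / 2, df1, df2)
    fu <- fv * stats::qf(1 - alpha / 2, df2, df1)
    out <- list(icc = icc,
                ci_lower = (fl - 1) / (fl + k - 1),
                ci_upper = (fu - 1) / (fu + k - 1),
                f_value = fv, df1 = df1, df2 = df2,
                p_value = stats::pf(fv, df1, df2, lower.tail = FALSE))
  }
  out$interpretation <- interpret_icc(out$icc)
  out$n <- n; out$k <- k
  structure(out, class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(3,1) = %.3f (95%% CI %.3f to %.3f) - %s reliability\n",
              x$icc, x$ci_lower, x$ci_upper, x$interpretation))
  cat(sprintf("  F(%d, %d) = %.2f, p = %.3g; n = %d units, k = %d raters\n",
              x$df1, x$df2, x$f_value, x$p_value, x$n, x$k))
  invisible(x)
}

#' Qualitative interpretation of an ICC value
#'
#' Banding: exactly 0 is "random"; below 0.5 "poor"; 0.5 to below 0.75
#' "moderate"; 0.75 to below 0.9 "good"; 0.9 to below 1 "excellent";
#' exactly 1 "perfect". Band edges are inclusive-lower /
#' exclusive-upper.
#'
#' @param icc ICC value in (-1, 1].
#' @return character label.
#' @export
interpret_icc <- function(icc) {
  if (!is.finite(icc) || icc <= -1 || icc > 1)
    abort_hci("icc must lie in (-1, 1]", "hci_parameter_error")
  if (icc == 0) return("random")
  if (icc == 1) return("perfect")
  if (icc < 0.5) return("poor")
  if (icc < 0.75) return("moderate")
  if (icc < 0.9) return("good")
  "excellent"
}

#' Adequate-reliability rule
#'
#' Reliability is adequate when the lower 95% confidence bound of the
#' ICC strictly exceeds 0.75.
#'
#' @param icc_ci_lower lower confidence bound of an ICC.
#' @return `TRUE` or `FALSE`.
#' @export
adequate_reliability <- function(icc_ci_lower) {
  if (!is.finite(icc_ci_lower))
    abort_hci("icc_ci_lower must be finite", "hci_parameter_error")
  icc_ci_lower > 0.75
}

#' Agreement report for one measurement contrast
#'
#' Bundles the paired t-test, Bland-Altman summary and ICC(3,1) for a
#' pair of aligned series, the unit of reporting in a reliability
#' study.
#'
#' @inheritParams paired_t_test
#' @param label name of the contrast (e.g. `"E1S1 vs E1S2"`).
#' @return list of class `agreement_report`.
#' @export
agreement_report <- function(values_a, values_b, label = "A vs B") {
  list2 <- .paired_series(values_a, values_b)
  structure(list(label = label,
                 t_test = paired_t_test(values_a, values_b),
                 bland_altman = bland_altman(values_a, values_b),
                 icc = icc_3_1(cbind(list2$a, list2$b))),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("==", x$label, "==\n")
  tt <- x$t_test
  cat(sprintf("paired t: mean diff %.4f +/- %.4f, t(%d) = %s, p = %s\n",
              tt$mean_diff, tt$sd_diff, tt$df,
              if (is.na(tt$t)) "NA" else sprintf("%.3f", tt$t),
              if (is.na(tt$p_value)) "NA" else sprintf("%.3f", tt$p_value)))
  print(x$bland_altman)
  print(x$icc)
  invisible(x)
}
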