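# Group comparison across hip dysplasia grades: descriptive summaries,
# Welch's heteroscedastic ANOVA, Games-Howell pairwise post hoc, and
# the assumption checks that are reported alongside (never used to
# switch methods: with unequal group variances being the rule for HCI
# by grade, the pipeline always runs Welch).

.grade_groups <- function(groups, min_n = 2L) {
  if (is.data.frame(groups)) {
    if (!all(c("hci", "fci_grade") %in% names(groups)))
      abort_hci("data frame input needs columns hci and fci_grade",
                "hci_column_error")
    groups <- split(as.numeric(groups$hci), groups$fci_grade)
  }
  if (!is.list(groups) || is.null(names(groups)))
    abort_hci("groups must be a named list of numeric vectors or a data frame",
              "hci_parameter_error")
  groups <- lapply(groups, function(v) as.numeric(v[is.finite(v)]))
  empty <- vapply(groups, length, integer(1)) == 0L
  if (any(empty)) {
    warn_hci(sprintf("dropping empty group(s): %s",
                     paste(names(groups)[empty], collapse = ", ")),
             "hci_empty_group")
    groups <- groups[!empty]
  }
  if (length(groups) < 2L)
    abort_hci("need at least 2 non-empty groups", "hci_sample_size_error")
  small <- vapply(groups, length, integer(1)) < min_n
  if (any(small))
    abort_hci(sprintf("group(s) %s have fewer than %d values",
                      paste(names(groups)[small], collapse = ", "), min_n),
              "hci_sample_size_error")
  groups
}

#' Descriptive summary by grade
#'
#' One row per group: n, mean, sample SD (n-1 denominator), t-based
#' 95% CI of the mean, minimum and maximum. Empty groups are dropped
#' with a warning.
#'
#' @param groups named list of numeric vectors (grade -> HCI values) or
#'   a data frame with columns `hci` and `fci_grade`.
#' @param level confidence level for the mean CI.
#' @return data frame with columns `grade`, `n`, `mean`, `sd`,
#'   `ci_lower`, `ci_upper`, `min`, `max`.
#' @export
describe_groups <- function(groups, level = 0.95) {
  g <- .grade_groups(groups)
  rows <- lapply(names(g), function(nm) {
    v <- g[[nm]]
    m <- mean(v); s <- stats::sd(v)
    ci <- ci_mean_from_summary(m, s, length(v), level)
    data.frame(grade = nm, n = length(v), mean = m, sd = s,
               ci_lower = unname(ci[1L]), ci_upper = unname(ci[2L]),
               min = min(v), max = max(v))
  })
  do.call(rbind, rows)
}

#' Welch's heteroscedastic one-way ANOVA
#'
#' Compares group means without assuming equal variances. With weights
#' `w_i = n_i / s_i^2`, the statistic is the weighted between-group
#' mean square divided by `1 + 2(k-2)/(k^2-1) * Lambda`, where
#' `Lambda = sum((1 - w_i/W)^2 / (n_i - 1))`; the denominator degrees
#' of freedom are `(k^2 - 1) / (3 Lambda)`.
#'
#' @inheritParams describe_groups
#' @return list with `f_value`, `df1`, `df2`, `p_value`, `k`.
#' @export
welch_anova <- function(groups) {
  g <- .grade_groups(groups, min_n = 2L)
  n <- vapply(g, length, integer(1))
  s2 <- vapply(g, stats::var, numeric(1))
  if (any(s2 == 0))
    abort_hci(sprintf("group(s) %s have zero variance",
                      paste(names(g)[s2 == 0], collapse = ", ")),
              "hci_degenerate_variance")
  xb <- vapply(g, mean, numeric(1))
  k <- length(g)
  w <- n / s2
  W <- sum(w)
  xw <- sum(w * xb) / W
  lambda <- sum((1 - w / W)^2 / (n - 1))
  num <- sum(w * (xb - xw)^2) / (k - 1)
  den <- 1 + 2 * (k - 2) / (k^2 - 1) * lambda
  fv <- num / den
  df1 <- k - 1
  df2 <- (k^2 - 1) / (3 * lambda)
  list(f_value = fv, df1 = df1, df2 = df2,
       p_value = stats::pf(fv, df1, df2, lower.tail = FALSE), k = k)
}

#' Games-Howell pairwise post hoc test
#'
#' All pairwise mean comparisons under unequal variances and sizes:
#' standard error `sqrt(s_i^2/n_i + s_j^2/n_j)`, Welch-Satterthwaite
#' degrees of freedom per pair, and p-values from the studentized range
#' distribution with `k` groups (`q = |diff| / (se / sqrt(2))`). Runs
#' unconditionally - no overall-ANOVA gate.
#'
#' @inheritParams describe_groups
#' @param alpha significance level for the `significant` flag.
#' @return data frame with one row per unordered pair: `grade_i`,
#'   `grade_j`, `mean_diff` (i minus j), `se`, `t_statistic`,
#'   `welch_df`, `p_value`, `significant`.
#' @export
games_howell <- function(groups, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1)
    abort_hci("alpha must be in (0, 1)", "hci_parameter_error")
  g <- .grade_groups(groups, min_n = 2L)
  n <- vapply(g, length, integer(1))
  s2 <- vapply(g, stats::var, numeric(1))
  if (any(s2 == 0))
    abort_hci(sprintf("group(s) %s have zero variance",
                      paste(names(g)[s2 == 0], collapse = ", ")),
              "hci_degenerate_variance")
  xb <- vapply(g, mean, numeric(1))
  k <- length(g)
  rows <- list()
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      vi <- s2[i] / n[i]; vj <- s2[j] / n[j]
      se <- sqrt(vi + vj)
      df <- (vi + vj)^2 / (vi^2 / (n[i] - 1) + vj^2 / (n[j] - 1))
      diff <- xb[i] - xb[j]
      tstat <- diff / se
      q <- abs(tstat) * sqrt(2)
      p <- stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        grade_i = names(g)[i], grade_j = names(g)[j],
        mean_diff = diff, se = se, t_statistic = tstat, welch_df = df,
        p_value = p, significant = p < alpha)
    }
  }
  do.call(rbind, rows)
}

#' Normality and variance-homogeneity checks
#'
#' Shapiro-Wilk per group and Levene's test with mean centering (the
#' classic form: a one-way ANOVA on `|x - group mean|`). Purely
#' descriptive companions to [welch_anova()]; results are reported,
#' never used to switch methods.
#'
#' @inheritParams describe_groups
#' @return list with `shapiro` (data frame: grade, n, w, p_value;
#'   groups with n < 3 are skipped with a warning) and `levene` (list:
#'   f_value, df1, df2, p_value).
#' @export
assumption_checks <- function(groups) {
  g <- .grade_groups(groups, min_n = 2L)
  sw <- lapply(names(g), function(nm) {
    v <- g[[nm]]
    if (length(v) < 3L) {
      warn_hci(sprintf("group %s has n < 3; normality test skipped", nm),
               "hci_small_group")
      return(NULL)
    }
    res <- stats::shapiro.test(v)
    data.frame(grade = nm, n = length(v), w = unname(res$statistic),
               p_value = res$p.value)
  })
  shapiro <- do.call(rbind, sw)

  z <- lapply(g, function(v) abs(v - mean(v)))
  nz <- vapply(z, length, integer(1))
  k <- length(z)
  N <- sum(nz)
  zbar_g <- vapply(z, mean, numeric(1))
  zbar <- sum(nz * zbar_g) / N
  ss_b <- sum(nz * (zbar_g - zbar)^2)
  ss_w <- sum(vapply(z, function(v) sum((v - mean(v))^2), numeric(1)))
  df1 <- k - 1L; df2 <- N - k
  lev <- if (ss_w == 0) {
    list(f_value = 0, df1 = df1, df2 = df2, p_value = 1)
  } else {
    fv <- (ss_b / df1) / (ss_w / df2)
    list(f_value = fv, df1 = df1, df2 = df2,
         p_value = stats::pf(fv, df1, df2, lower.tail = FALSE))
  }
  list(shapiro = shapiro, levene = lev)
}
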