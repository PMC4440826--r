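#' Mann-Whitney U test with tie-corrected normal approximation
#'
#' Rank-sum comparison of two independent samples using midranks. The
#' statistic is `U = R1 - n1*(n1+1)/2` where `R1` is the rank sum of the
#' first sample; the normal approximation uses the tie-corrected variance
#' and no continuity correction, matching the convention of the major
#' statistical packages. The signed deviate
#' `Z = (U - n1*n2/2) / sigma` is negative when the first sample ranks
#' lower. Two samples with all values identical give `Z = 0`, `p = 1`.
#'
#' @param x,y Numeric samples (non-empty). By convention `x` is the control
#'   group, so markers elevated in patients give negative `Z`.
#' @return A one-row tibble: `statistic` (U of the first sample), `z`,
#'   `p_value` (two-sided), `n1`, `n2`, `method`.
#' @export
#' @examples
#' mann_whitney(rnorm(20), rnorm(20, mean = 1))
mann_whitney <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) param_error("Both samples must be non-empty.")
  r <- rank(c(x, y))  # midranks
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  n <- n1 + n2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (sigma2 <= 0) {
    z <- 0; p <- 1
  } else {
    z <- (u - n1 * n2 / 2) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
  }
  tibble::tibble(statistic = u, z = z, p_value = p, n1 = n1, n2 = n2,
                 method = "Mann-Whitney U (tie-corrected normal)")
}

#' Pearson chi-square test on a 2x2 table
#'
#' Uncorrected (no Yates continuity correction) Pearson chi-square with one
#' degree of freedom, equal to the closed form
#' `N*(ad - bc)^2 / (r1*r2*c1*c2)`.
#'
#' @param table A 2x2 matrix of non-negative counts.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `method`.
#' @export
#' @examples
#' chi_square_2x2(matrix(c(69, 86, 51, 94), 2, byrow = TRUE))
chi_square_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)) || any(table < 0) || anyNA(table)) {
    param_error("`table` must be a 2x2 matrix of non-negative counts.")
  }
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected == 0)) {
    param_error("Zero expected count: chi-square statistic undefined.")
  }
  ht <- suppressWarnings(chisq.test(table, correct = FALSE))
  tibble::tibble(statistic = unname(ht$statistic), df = 1L,
                 p_value = ht$p.value,
                 method = "Pearson chi-square (uncorrected)")
}

#' Two-sample t-test
#'
#' Pooled-variance two-sided t-test by default, with the Welch variant by
#' flag. Degenerate inputs with zero pooled variance raise an error rather
#' than reporting an infinite statistic.
#'
#' @param x,y Numeric samples of size >= 2.
#' @param welch Use the Welch (unequal-variance) form.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `method`.
#' @export
t_test_independent <- function(x, y, welch = FALSE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    param_error("Both samples must have at least 2 observations.")
  }
  if (!welch && sd(x) == 0 && sd(y) == 0) {
    param_error("Zero pooled variance: t statistic undefined.")
  }
  ht <- tryCatch(t.test(x, y, var.equal = !welch),
                 error = function(e) param_error(conditionMessage(e)))
  tibble::tibble(statistic = unname(ht$statistic),
                 df = unname(ht$parameter), p_value = ht$p.value,
                 method = if (welch) "Welch two-sample t" else
                   "Pooled two-sample t")
}

#' Two-sample t-test from summary statistics
#'
#' Closed-form pooled-variance t for data available only as mean, standard
#' deviation and size per group (as printed in demographic tables).
#'
#' @param mean1,sd1,n1 First group summary.
#' @param mean2,sd2,n2 Second group summary.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `method`.
#' @export
#' @examples
#' t_test_summary(56.23, 8.72, 155, 57.92, 9.46, 145)
t_test_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) param_error("Both groups must have n >= 2.")
  if (sd1 < 0 || sd2 < 0) param_error("Standard deviations must be >= 0.")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  if (sp2 <= 0) param_error("Zero pooled variance: t statistic undefined.")
  t <- (mean2 - mean1) / sqrt(sp2 * (1 / n1 + 1 / n2))
  tibble::tibble(statistic = t, df = df, p_value = 2 * pt(-abs(t), df),
                 method = "Pooled two-sample t (summary statistics)")
}

#' Spearman rank-correlation matrix
#'
#' Midrank Spearman correlations between marker columns: symmetric with a
#' unit diagonal; entries involving a constant column are undefined and
#' reported as `NA`.
#'
#' @param data Data frame holding the marker columns.
#' @param markers Columns to correlate.
#' @return A symmetric numeric matrix with `markers` as dimnames.
#' @export
spearman_matrix <- function(data, markers = marker_names()) {
  if (!all(markers %in% names(data))) {
    param_error("All `markers` must be columns of `data`.")
  }
  m <- suppressWarnings(
    cor(as.matrix(data[, markers, drop = FALSE]), method = "spearman",
        use = "pairwise.complete.obs")
  )
  diag(m) <- 1
  m
}

#' Group-wise univariate marker comparison
#'
#' The standard univariate screen of a marker panel: per marker, the
#' medians and ranges of two groups side by side with the tie-corrected
#' Mann-Whitney `Z` and two-sided p-value (first group as reference, so
#' markers elevated in the second group give negative `Z`).
#'
#' @param data Cohort data frame.
#' @param groups Length-2 character vector; first entry is the reference
#'   group.
#' @param markers Marker columns to compare.
#' @return A tibble with one row per marker.
#' @export
cohort_marker_tests <- function(data, groups = c("CONTROL", "SCLC"),
                                markers = marker_names()) {
  check_cohort(data)
  if (length(groups) != 2) param_error("`groups` must name exactly 2 groups.")
  g1 <- data[data$group == groups[1], , drop = FALSE]
  g2 <- data[data$group == groups[2], , drop = FALSE]
  if (nrow(g1) == 0 || nrow(g2) == 0) {
    param_error("Both groups must be present in `data`.")
  }
  purrr::map_dfr(markers, function(m) {
    mw <- mann_whitney(g1[[m]], g2[[m]])
    tibble::tibble(
      marker = m,
      median_1 = median(g1[[m]]), min_1 = min(g1[[m]]), max_1 = max(g1[[m]]),
      median_2 = median(g2[[m]]), min_2 = min(g2[[m]]), max_2 = max(g2[[m]]),
      z = mw$z, p_value = mw$p_value
    )
  })
}
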