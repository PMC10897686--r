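# The two inferential tests used for group comparison, implemented from
# first principles so every term is auditable; base R distribution
# functions supply the reference distributions.

#' Pearson chi-square test on a 2x2 table (1 degree of freedom)
#'
#' Computes the Pearson statistic sum((O-E)^2/E) on a 2x2 contingency
#' table with expected counts from the product of the margins, and the
#' upper-tail p-value from the chi-square distribution with one degree of
#' freedom. No continuity correction by default; Yates' correction is
#' available via `yates = TRUE`.
#'
#' @param tab A 2x2 matrix (or coercible) of nonnegative counts,
#'   groups x outcomes.
#' @param yates Apply Yates' continuity correction.
#' @return An object of class `pathway_test` with `statistic`, `p_value`,
#'   `df`, `method`.
#' @export
#' @examples
#' chi_square_df1(matrix(c(20, 10, 10, 20), 2))$statistic  # 20/3
chi_square_df1 <- function(tab, yates = FALSE) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("expected a 2x2 table")
  if (any(is.na(tab)) || any(tab < 0) || any(tab != round(tab))) {
    stop("table cells must be nonnegative integers")
  }
  n <- sum(tab)
  if (n == 0) stop("degenerate table: total count is zero")
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) {
    stop("degenerate table: a row or column margin is zero")
  }
  expected <- outer(rs, cs) / n
  dev <- abs(tab - expected)
  if (yates) dev <- pmax(0, dev - 0.5)
  statistic <- sum(dev^2 / expected)
  structure(list(
    statistic = statistic,
    p_value = stats::pchisq(statistic, df = 1L, lower.tail = FALSE),
    df = 1L,
    method = if (yates) "Pearson chi-square (df = 1, Yates)" else
      "Pearson chi-square (df = 1)"
  ), class = "pathway_test")
}

#' Wilcoxon rank-sum test with continuity correction
#'
#' Rank-sum test on two samples using midranks for ties. The statistic
#' reported is the Mann-Whitney U for the first sample (rank sum of `x`
#' minus its minimum). By default the two-sided p-value comes from the
#' normal approximation with tie-corrected variance and a 0.5 continuity
#' correction, appropriate for the large cohorts this package targets;
#' `exact = TRUE` (available for samples of at most 10 per group with no
#' ties) enumerates all rank assignments instead, for verification.
#'
#' @param x,y Numeric samples, both nonempty.
#' @param correct Apply the 0.5 continuity correction (normal
#'   approximation only).
#' @param exact Use exact enumeration instead of the normal approximation.
#' @return An object of class `pathway_test` with `statistic` (U),
#'   `p_value`, `n_x`, `n_y`, `method`.
#' @export
wilcoxon_rank_sum_cc <- function(x, y, correct = TRUE, exact = FALSE) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be nonempty")
  if (anyNA(x) || anyNA(y)) stop("samples must not contain NA")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))  # midranks for ties
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2

  if (exact) {
    if (n1 > 10L || n2 > 10L) stop("exact enumeration limited to n <= 10 per group")
    if (anyDuplicated(c(x, y))) stop("exact enumeration requires untied data")
    combos <- utils::combn(N, n1)
    usums <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- 2 * min(mean(usums <= U), mean(usums >= U))
    p <- min(1, p)
    return(structure(list(statistic = U, p_value = p, n_x = n1, n_y = n2,
                          method = "Wilcoxon rank sum (exact)"),
                     class = "pathway_test"))
  }

  mu <- n1 * n2 / 2
  ties <- table(r)
  sigma2 <- (n1 * n2 / 12) * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) {
    # all observations identical: no evidence against the null
    return(structure(list(statistic = U, p_value = 1, n_x = n1, n_y = n2,
                          method = "Wilcoxon rank sum with continuity correction"),
                     class = "pathway_test"))
  }
  z <- U - mu
  if (correct) z <- sign(z) * max(0, abs(z) - 0.5)
  p <- min(1, 2 * stats::pnorm(-abs(z) / sqrt(sigma2)))
  structure(list(statistic = U, p_value = p, n_x = n1, n_y = n2,
                 method = if (correct)
                   "Wilcoxon rank sum with continuity correction" else
                   "Wilcoxon rank sum (normal approximation)"),
            class = "pathway_test")
}

#' @export
print.pathway_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  statistic = %.6g, p = %.4g\n", x$statistic, x$p_value))
  invisible(x)
}

#' Compare an outcome rate or numeric metric between two groups
#'
#' Dispatches to the chi-square test for binary outcomes (2x2 table of
#' group by outcome) and to the Wilcoxon rank-sum test for numeric
#' metrics, mirroring the analysis plan the package implements.
#'
#' @param metrics Output of [compute_patient_metrics()] merged with group
#'   labels, or any data frame with the metric column and a `group`
#'   column.
#' @param metric Column name to compare.
#' @param groups Length-2 character vector of group labels.
#' @return A `pathway_test`.
#' @export
compare_groups <- function(metrics, metric, groups = c("MDD", "TRD")) {
  stopifnot(length(groups) == 2L, metric %in% names(metrics))
  a <- metrics[[metric]][metrics$group == groups[1]]
  b <- metrics[[metric]][metrics$group == groups[2]]
  if (is.logical(metrics[[metric]])) {
    tab <- matrix(c(sum(a), sum(!a), sum(b), sum(!b)), nrow = 2,
                  byrow = TRUE,
                  dimnames = list(groups, c("yes", "no")))
    chi_square_df1(tab)
  } else {
    wilcoxon_rank_sum_cc(a[!is.na(a)], b[!is.na(b)])
  }
}
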