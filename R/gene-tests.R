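#' Two-sample t-test for one gene
#'
#' Classic two-sided two-sample t-test on log-expression values, pooled
#' variance by default (the era-typical microarray choice) with Welch's
#' unequal-variance form selectable. The statistic is antisymmetric in group
#' order; the p-value is symmetric.
#'
#' @param values_a,values_b Numeric vectors (missing values dropped); each
#'   group needs at least 2 non-missing values.
#' @param var_equal Pooled variance if `TRUE` (default), Welch otherwise.
#' @return A list with `t`, `df` and `p`.
#' @export
gene_t_test <- function(values_a, values_b, var_equal = TRUE) {
  a <- values_a[!is.na(values_a)]
  b <- values_b[!is.na(values_b)]
  if (length(a) < 2L || length(b) < 2L) {
    abort("each group needs at least 2 non-missing values")
  }
  va <- var(a); vb <- var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) {
      warn("both groups constant and equal; returning t = 0, p = 1")
      return(list(t = 0, df = length(a) + length(b) - 2L, p = 1))
    }
    abort("degenerate variance: both groups constant with different means")
  }
  res <- t_stat_vec(matrix(a, 1L), matrix(b, 1L), var_equal)
  list(t = unname(res$t), df = unname(res$df), p = unname(res$p))
}

# Vectorised row-wise two-sample t: x_a, x_b are genes x samples slices of
# the same matrix. Rows with any missing value get NA (callers log counts).
t_stat_vec <- function(x_a, x_b, var_equal = TRUE) {
  na <- ncol(x_a); nb <- ncol(x_b)
  ma <- rowMeans(x_a); mb <- rowMeans(x_b)
  va <- rowSums((x_a - ma)^2) / (na - 1L)
  vb <- rowSums((x_b - mb)^2) / (nb - 1L)
  if (var_equal) {
    sp2 <- ((na - 1L) * va + (nb - 1L) * vb) / (na + nb - 2L)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2L, length(ma))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      (va^2 / (na^2 * (na - 1L)) + vb^2 / (nb^2 * (nb - 1L)))
  }
  t <- (ma - mb) / se
  t[se == 0 & ma == mb] <- 0
  p <- 2 * pt(-abs(t), df)
  p[se == 0 & ma == mb] <- 1
  list(t = t, df = df, p = p)
}

#' Per-gene differential-expression tests for a cohort slice
#'
#' Runs the two-sided t-test of [gene_t_test()] for every gene between two
#' outcome groups. Genes with any missing value are dropped with a reported
#' count (tests and distances cannot tolerate missingness; the policy is
#' drop-and-log).
#'
#' @param expr Genes-by-samples matrix.
#' @param labels Factor/character vector over columns with exactly two
#'   levels present (conventionally `"lethal"` vs `"indolent"`); `t > 0`
#'   means higher in the first level encountered in
#'   `c("lethal", "indolent")` order if present, otherwise sorted order.
#' @param var_equal Pooled variance if `TRUE`.
#' @return Tibble with columns `gene_id`, `t`, `df`, `p`, ordered as in
#'   `expr`.
#' @export
gene_tests <- function(expr, labels, var_equal = TRUE) {
  labels <- as.character(labels)
  lv <- intersect(c("lethal", "indolent"), unique(labels))
  if (length(lv) != 2L) lv <- sort(unique(labels))
  if (length(lv) != 2L) abort("labels must have exactly two levels present")
  keep <- !apply(is.na(expr), 1L, any)
  if (!all(keep)) {
    inform(sprintf("gene_tests: dropped %d gene(s) with missing values",
                   sum(!keep)))
  }
  x <- expr[keep, , drop = FALSE]
  res <- t_stat_vec(x[, labels == lv[[1L]], drop = FALSE],
                    x[, labels == lv[[2L]], drop = FALSE], var_equal)
  tibble::tibble(gene_id = rownames(x), t = unname(res$t),
                 df = unname(res$df), p = unname(res$p))
}

#' False-discovery-rate q-values
#'
#' Storey's q-value procedure: the null proportion pi0 is estimated on a
#' lambda grid with a cubic smoothing spline and the Benjamini-Hochberg
#' step-up quantities are scaled by it. `method = "bh"` is the same
#' computation with pi0 pinned to 1. Families smaller than 100 tests fall
#' back to BH (pi0 estimation is unstable on tiny families).
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @param method `"storey"` (default) or `"bh"`.
#' @return Vector of q-values, monotone in `p_values`; the estimated pi0 is
#'   attached as `attr(, "pi0")`.
#' @export
compute_q_values <- function(p_values, method = c("storey", "bh")) {
  method <- match.arg(method)
  if (!length(p_values)) abort("empty p-value vector")
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must be in [0, 1]")
  }
  pi0 <- 1
  if (method == "storey" && length(p_values) >= 100L) {
    lambda <- seq(0.05, 0.95, by = 0.05)
    pi0_l <- vapply(lambda, function(l) mean(p_values > l) / (1 - l), numeric(1L))
    fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
    pi0 <- stats::predict(fit, x = max(lambda))$y
    pi0 <- min(max(pi0, 1e-8), 1)
  }
  q <- pmin(pi0 * stats::p.adjust(p_values, method = "BH"), 1)
  attr(q, "pi0") <- pi0
  q
}
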