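#' Cross-tabulate two phenotype variables
#'
#' Convenience wrapper producing the labelled count matrix the association
#' statistics consume, with unused factor levels (e.g. `unknown`, `excluded`)
#' optionally dropped.
#'
#' @param data A data frame.
#' @param row,col Column names (strings) to tabulate.
#' @param drop_levels Levels to exclude from both margins (default
#'   `c("unknown", "excluded")`).
#' @return An integer matrix with row/column labels.
#' @export
contingency <- function(data, row, col,
                        drop_levels = c("unknown", "excluded")) {
  r <- as.character(data[[row]])
  c_ <- as.character(data[[col]])
  keep <- !(r %in% drop_levels) & !(c_ %in% drop_levels) & !is.na(r) & !is.na(c_)
  tab <- table(r[keep], c_[keep])
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = dimnames(tab))
  m
}

validate_contingency <- function(tab) {
  if (!is.matrix(tab) || any(tab < 0) || any(tab != round(tab))) {
    abort("contingency table must be a matrix of non-negative integer counts")
  }
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    abort("contingency table needs at least 2 rows and 2 columns")
  }
  if (sum(tab) < 1) abort("contingency table grand total must be >= 1")
  tab
}

#' Cramer's V association measure
#'
#' `V = sqrt(chi^2 / (N * (min(r, c) - 1)))` with the Pearson chi-squared
#' statistic computed without continuity correction. Rows or columns with a
#' zero margin are dropped with a warning before computing.
#'
#' @param tab A contingency count matrix (at least 2x2 after dropping zero
#'   margins).
#' @return V in \[0, 1\].
#' @export
cramers_v <- function(tab) {
  tab <- validate_contingency(tab)
  keep_r <- rowSums(tab) > 0
  keep_c <- colSums(tab) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warn("dropping zero-margin rows/columns before computing Cramer's V")
    tab <- tab[keep_r, keep_c, drop = FALSE]
    validate_contingency(tab)
  }
  chi2 <- suppressWarnings(
    stats::chisq.test(tab, correct = FALSE)$statistic)
  v <- sqrt(as.numeric(chi2) / (sum(tab) * (min(dim(tab)) - 1L)))
  min(max(v, 0), 1)
}

#' Fisher's exact test
#'
#' 2x2 tables are computed exactly: the two-sided p-value is the sum of
#' hypergeometric probabilities of all tables (with the observed margins) no
#' more probable than the observed one, using the customary relative
#' tolerance of 1e-7 to absorb floating-point ties. Larger tables use a
#' seeded Monte-Carlo null with fixed margins (via [stats::r2dtable()]),
#' reporting the permutation p-value and its standard error.
#'
#' @param tab A contingency count matrix.
#' @param mc_reps Monte-Carlo draws for r-by-c tables (minimum 1000).
#' @param seed Seed for the Monte-Carlo null; ignored for 2x2 tables.
#' @return A list with `p`, `method` (`"exact"` or `"monte_carlo"`), and for
#'   Monte-Carlo tables `se`, `mc_reps` and `seed`.
#' @export
fisher_exact <- function(tab, mc_reps = 10000L, seed = 1L) {
  tab <- validate_contingency(tab)
  if (all(dim(tab) == 2L)) {
    m <- sum(tab[1L, ]); n <- sum(tab[2L, ]); k <- sum(tab[, 1L])
    support <- max(0L, k - n):min(k, m)
    probs <- dhyper(support, m, n, k)
    p_obs <- dhyper(tab[1L, 1L], m, n, k)
    p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
    return(list(p = min(p, 1), method = "exact"))
  }
  if (mc_reps < 1000L) abort("mc_reps must be at least 1000 for r x c tables")
  log_prob <- function(x) {
    sum(lgamma(rowSums(x) + 1)) + sum(lgamma(colSums(x) + 1)) -
      lgamma(sum(x) + 1) - sum(lgamma(x + 1))
  }
  obs <- log_prob(tab)
  withr::local_seed(seed)
  draws <- stats::r2dtable(mc_reps, rowSums(tab), colSums(tab))
  hits <- vapply(draws, function(x) log_prob(x) <= obs + 1e-7, logical(1L))
  p_hat <- (1 + sum(hits)) / (mc_reps + 1)
  list(p = p_hat, se = sqrt(p_hat * (1 - p_hat) / mc_reps),
       method = "monte_carlo", mc_reps = mc_reps, seed = seed)
}

#' Odds ratio with Woolf confidence interval
#'
#' `OR = (a d) / (b c)` for a 2x2 table `[[a, b], [c, d]]`, with the Woolf
#' (log) interval `exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. Zero
#' cells get the documented 0.5 continuity correction with a warning; a zero
#' margin makes the odds ratio undefined and is an error.
#'
#' @param tab A 2x2 count matrix.
#' @param confidence Coverage in (0, 1), default 0.95.
#' @return A list with `or`, `lo`, `hi` and `confidence`.
#' @export
odds_ratio_ci <- function(tab, confidence = 0.95) {
  tab <- validate_contingency(tab)
  if (!all(dim(tab) == 2L)) abort("odds_ratio_ci needs a 2x2 table")
  assert_scalar_number(confidence, "confidence", 1e-12, 1 - 1e-12)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("undefined odds ratio: a margin of the table is zero")
  }
  if (any(tab == 0)) {
    warn("zero cell: applying 0.5 continuity correction")
    tab <- tab + 0.5
  }
  a <- tab[1L, 1L]; b <- tab[1L, 2L]; c_ <- tab[2L, 1L]; d <- tab[2L, 2L]
  or <- (a * d) / (b * c_)
  z <- qnorm(1 - (1 - confidence) / 2)
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  list(or = or, lo = exp(log(or) - z * se), hi = exp(log(or) + z * se),
       confidence = confidence)
}
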