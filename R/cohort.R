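#' Bundle an expression matrix and a phenotype table into a cohort
#'
#' A cohort pairs a genes-by-samples log-expression matrix with a per-sample
#' phenotype table over exactly the same samples. The phenotype rows are
#' stored in the expression column order so downstream code can index either
#' by position.
#'
#' @param expression Numeric genes-by-samples matrix (see
#'   [validate_expression_matrix()]).
#' @param phenotype A phenotype tibble (see [phenotype_table()]).
#' @return An object of class `"cohort"`: a list with elements `expression`
#'   and `phenotype`.
#' @seealso [align_cohort()] to reconcile mismatched sample sets.
#' @export
cohort <- function(expression, phenotype) {
  validate_expression_matrix(expression)
  phenotype <- phenotype_table(phenotype)
  e_ids <- colnames(expression)
  p_ids <- phenotype$sample_id
  if (!setequal(e_ids, p_ids)) {
    abort(paste0(
      "expression and phenotype sample sets differ; use align_cohort() ",
      "(expression-only: ", paste(head(setdiff(e_ids, p_ids), 3), collapse = ", "),
      "; phenotype-only: ", paste(head(setdiff(p_ids, e_ids), 3), collapse = ", "), ")"))
  }
  phenotype <- phenotype[match(e_ids, p_ids), , drop = FALSE]
  structure(list(expression = expression, phenotype = phenotype),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  n_out <- table(x$phenotype$outcome)
  cat(sprintf("<cohort> %d genes x %d samples (%s)\n",
              nrow(x$expression), ncol(x$expression),
              paste(sprintf("%s: %d", names(n_out), n_out), collapse = ", ")))
  invisible(x)
}

#' Align expression and phenotype to their common samples
#'
#' Restricts both tables to the samples present in each, in expression
#' order, and reports what was dropped. Errors if the intersection is empty.
#'
#' @param expression Genes-by-samples matrix.
#' @param phenotype Phenotype tibble.
#' @return A `"cohort"`; the dropped ids are attached as
#'   `attr(, "dropped")`, a list with `expression_only` and `phenotype_only`.
#' @export
align_cohort <- function(expression, phenotype) {
  validate_expression_matrix(expression)
  phenotype <- phenotype_table(phenotype)
  keep <- intersect(colnames(expression), phenotype$sample_id)
  if (!length(keep)) abort("alignment error: no samples in common")
  dropped <- list(expression_only = setdiff(colnames(expression), keep),
                  phenotype_only = setdiff(phenotype$sample_id, keep))
  if (length(dropped$expression_only) || length(dropped$phenotype_only)) {
    inform(sprintf("align_cohort: dropped %d expression-only and %d phenotype-only sample(s)",
                   length(dropped$expression_only), length(dropped$phenotype_only)))
  }
  out <- cohort(expression[, keep, drop = FALSE],
                phenotype[phenotype$sample_id %in% keep, , drop = FALSE])
  attr(out, "dropped") <- dropped
  out
}
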