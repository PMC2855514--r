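#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a trained model
#'
#' Broom-style one-row-per-term summaries: per-gene class means and pooled
#' standard deviation for DLDA, per-gene template sign for NTP, coefficient
#' estimates for logistic regression, exemplar counts for kNN.
#'
#' @param x A `"trained_model"`.
#' @param ... Ignored.
#' @return A tibble.
#' @export
tidy.trained_model <- function(x, ...) {
  f <- x$fit
  switch(x$spec$family,
    dlda = tibble::tibble(gene_id = f$genes,
                          mean_indolent = unname(f$mu_indolent),
                          mean_lethal = unname(f$mu_lethal),
                          pooled_sd = sqrt(unname(f$pooled_var))),
    ntp = tibble::tibble(gene_id = f$genes,
                         template = unname(f$template_lethal),
                         center = unname(f$center), scale = unname(f$scale)),
    logistic = tibble::tibble(term = names(f$coefficients),
                              estimate = unname(f$coefficients)),
    knn = tibble::tibble(label = levels(f$labels),
                         n_exemplars = as.integer(table(f$labels))),
    abort(sprintf("no tidy method for family '%s'", x$spec$family)))
}

#' One-row model summary
#'
#' @param x A `"trained_model"`.
#' @param ... Ignored.
#' @return A one-row tibble with the family, feature counts and (for
#'   logistic fits) convergence information.
#' @export
glance.trained_model <- function(x, ...) {
  base <- tibble::tibble(family = x$spec$family,
                         feature_policy = x$spec$feature_policy,
                         n_genes = length(x$selected_gene_ids),
                         n_clinical = length(x$spec$clinical_fields))
  if (x$spec$family == "logistic") {
    base$converged <- x$fit$converged
    base$ridge_penalty <- x$fit$ridge_penalty
    base$refit_penalty <- x$fit$refit_penalty
  }
  base
}

#' Tidy an evaluation report
#'
#' @param x An `"evaluation_report"` from [run_cv()].
#' @param ... Ignored.
#' @return The per-repetition tibble (model, family, repetition, mean AUC,
#'   mean selected gene count).
#' @export
tidy.evaluation_report <- function(x, ...) x$per_repetition

#' One-row-per-model evaluation summary
#'
#' @param x An `"evaluation_report"`.
#' @param ... Ignored.
#' @return The summary tibble (grand-mean AUC, sd, gene counts).
#' @export
glance.evaluation_report <- function(x, ...) x$summary
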