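#' Write a trained model to a plain-text file
#'
#' Serialises the family, hyperparameters, selected feature list and fitted
#' parameter block as versioned JSON, so a scored run can be reproduced
#' without the training data. Plugin models hold arbitrary closures and are
#' not serialisable.
#'
#' @param model A `"trained_model"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "trained_model"))
  if (model$spec$family == "plugin") {
    abort("plugin models hold user closures and cannot be serialised")
  }
  fit <- model$fit
  if (model$spec$family == "knn") {
    fit$exemplars <- list(genes = rownames(fit$exemplars),
                          samples = colnames(fit$exemplars),
                          values = as.numeric(fit$exemplars))  # column-major
    fit$labels <- as.character(fit$labels)
  }
  if (model$spec$family == "logistic") {
    # named vectors serialise as bare arrays; keep the term names
    fit$coefficients <- as.list(fit$coefficients)
  }
  payload <- list(
    format = "hetsig_model", version = 1L,
    family = model$spec$family,
    hyperparameters = model$spec$hyperparameters,
    feature_policy = model$spec$feature_policy,
    clinical_fields = model$spec$clinical_fields,
    label = model$spec$label,
    selected_gene_ids = model$selected_gene_ids,
    fit = fit)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a trained model written by [write_model()]
#'
#' @param path Path to the JSON file.
#' @return A `"trained_model"`.
#' @export
read_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "hetsig_model") || payload$version != 1L) {
    abort("not a version-1 hetsig model file")
  }
  spec <- model_spec(payload$family,
                     hyperparameters = as.list(payload$hyperparameters),
                     feature_policy = payload$feature_policy,
                     clinical_fields = as.character(payload$clinical_fields %||% character()),
                     label = payload$label)
  fit <- payload$fit
  if (payload$family == "knn") {
    ex <- matrix(as.numeric(unlist(fit$exemplars$values)),
                 nrow = length(fit$exemplars$genes),
                 dimnames = list(fit$exemplars$genes, fit$exemplars$samples))
    fit$exemplars <- ex
    fit$labels <- factor(fit$labels, levels = c("indolent", "lethal"))
    fit$k <- as.integer(fit$k)
  }
  if (payload$family == "dlda") {
    for (nm in c("mu_lethal", "mu_indolent", "pooled_var")) {
      fit[[nm]] <- setNames(as.numeric(fit[[nm]]), fit$genes)
    }
  }
  if (payload$family == "ntp") {
    for (nm in c("center", "scale", "template_lethal")) {
      fit[[nm]] <- setNames(as.numeric(fit[[nm]]), fit$genes)
    }
  }
  if (payload$family == "logistic") {
    fit$coefficients <- unlist(fit$coefficients)
  }
  structure(list(spec = spec,
                 selected_gene_ids = as.character(payload$selected_gene_ids %||% character()),
                 fit = fit),
            class = c(paste0(payload$family, "_model"), "trained_model"))
}
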