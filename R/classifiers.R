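#' Specify a classifier
#'
#' A model specification names the classifier family, its hyperparameters,
#' and which features it sees: selected genes, encoded clinical fields, or
#' both. Every family produces a continuous lethality score oriented so that
#' larger means more lethal.
#'
#' @param family `"dlda"`, `"knn"`, `"ntp"`, `"logistic"`, or `"plugin"`.
#' @param hyperparameters Named list: `k` (odd) for knn; `ridge_penalty` for
#'   logistic (default 1e-4); for plugins, functions `train(x, y)` and
#'   `score(fit, x)` where `x` is samples-by-features and `y` a two-level
#'   factor with `"lethal"` the positive class.
#' @param feature_policy `"genes_only"`, `"clinical_only"`, or `"combined"`.
#' @param clinical_fields Subset of `c("age", "gleason_category",
#'   "erg_status")`; must be empty iff `feature_policy = "genes_only"`.
#' @param label Optional display label; defaults to a compact description.
#' @return An object of class `"model_spec"`.
#' @export
model_spec <- function(family = c("dlda", "knn", "ntp", "logistic", "plugin"),
                       hyperparameters = list(),
                       feature_policy = c("genes_only", "clinical_only", "combined"),
                       clinical_fields = character(),
                       label = NULL) {
  family <- match.arg(family)
  feature_policy <- match.arg(feature_policy)
  ok_fields <- c("age", "gleason_category", "erg_status")
  if (!all(clinical_fields %in% ok_fields)) {
    abort(sprintf("clinical_fields must be a subset of {%s}",
                  paste(ok_fields, collapse = ", ")))
  }
  if (feature_policy == "genes_only" && length(clinical_fields)) {
    abort("genes_only models cannot list clinical_fields")
  }
  if (feature_policy != "genes_only" && !length(clinical_fields)) {
    abort(sprintf("%s models need at least one clinical field", feature_policy))
  }
  if (family %in% c("dlda", "knn", "ntp") && feature_policy != "genes_only") {
    abort(sprintf("%s models operate on genes only; use logistic or a plugin to mix clinical fields", family))
  }
  if (family == "knn") {
    k <- hyperparameters$k %||% 5L
    if (k %% 2L == 0L) abort("knn requires an odd k")
    hyperparameters$k <- as.integer(k)
  }
  if (family == "logistic") {
    hyperparameters$ridge_penalty <- hyperparameters$ridge_penalty %||% 1e-4
    if (hyperparameters$ridge_penalty < 0) abort("ridge_penalty must be >= 0")
  }
  if (family == "plugin" &&
      (!is.function(hyperparameters$train) || !is.function(hyperparameters$score))) {
    abort("plugin models need hyperparameters$train and hyperparameters$score functions")
  }
  label <- label %||% paste0(family, "_", feature_policy,
                             if (length(clinical_fields))
                               paste0("_", paste(substr(clinical_fields, 1, 3), collapse = "")))
  structure(list(family = family, hyperparameters = hyperparameters,
                 feature_policy = feature_policy,
                 clinical_fields = clinical_fields, label = label),
            class = "model_spec")
}

check_labels <- function(labels, n) {
  labels <- as.character(labels)
  if (length(labels) != n) abort("labels length must match sample count")
  if (!all(labels %in% c("lethal", "indolent"))) {
    abort("labels must be 'lethal' or 'indolent'")
  }
  if (length(unique(labels)) < 2L) abort("training error: a class is absent")
  factor(labels, levels = c("indolent", "lethal"))
}

#' Encode clinical covariates as a numeric design matrix
#'
#' Age enters linearly; `gleason_category` and `erg_status` are
#' reference-coded indicators with references `G4_6` and `negative`. When an
#' `unknown` level is present it gets its own indicator rather than being
#' silently folded into the reference.
#'
#' @param phenotype A phenotype tibble slice.
#' @param clinical_fields Which fields to encode.
#' @return A samples-by-columns numeric matrix (possibly 0 columns).
#' @export
encode_clinical <- function(phenotype, clinical_fields) {
  n <- nrow(phenotype)
  cols <- list()
  if ("age" %in% clinical_fields) {
    age <- phenotype$age_at_diagnosis
    if (any(is.na(age))) abort("age_at_diagnosis has missing values")
    cols$age <- age
  }
  if ("gleason_category" %in% clinical_fields) {
    g <- as.character(phenotype$gleason_category)
    cols$gleason_G7 <- as.numeric(g == "G7")
    cols$gleason_G8_10 <- as.numeric(g == "G8_10")
    if (any(g == "unknown")) cols$gleason_unknown <- as.numeric(g == "unknown")
  }
  if ("erg_status" %in% clinical_fields) {
    e <- as.character(phenotype$erg_status)
    cols$erg_rearranged <- as.numeric(e == "rearranged")
    if (any(e == "unknown")) cols$erg_unknown <- as.numeric(e == "unknown")
  }
  if (!length(cols)) return(matrix(numeric(0), n, 0))
  do.call(cbind, cols)
}

# samples-by-features design for a spec: selected genes (transposed from the
# genes x samples matrix) plus encoded clinical columns
build_design <- function(spec, expr, phenotype, gene_ids) {
  parts <- list()
  if (spec$feature_policy != "clinical_only") {
    missing_genes <- setdiff(gene_ids, rownames(expr))
    if (length(missing_genes)) {
      abort(sprintf("scoring error: missing selected feature(s): %s",
                    paste(head(missing_genes, 5), collapse = ", ")))
    }
    if (!length(gene_ids)) abort("gene-using model has an empty gene set")
    parts$genes <- t(expr[gene_ids, , drop = FALSE])
  }
  if (spec$feature_policy != "genes_only") {
    parts$clin <- encode_clinical(phenotype, spec$clinical_fields)
  }
  do.call(cbind, parts)
}

#' Train a classifier
#'
#' Dispatches on the spec's family. All per-gene standardisation statistics
#' are computed on the training data only and frozen into the model — the
#' anti-leakage contract every family honours.
#'
#' @param spec A [model_spec()].
#' @param expr Genes-by-samples training slice restricted to the selected
#'   genes (ignored for clinical-only models; pass `NULL`).
#' @param labels Outcome labels (`"lethal"`/`"indolent"`) per training
#'   sample.
#' @param phenotype Phenotype rows for the training samples (needed when the
#'   spec uses clinical fields).
#' @return A `"trained_model"` whose [score_samples()] output is oriented
#'   larger = more lethal.
#' @export
train_model <- function(spec, expr, labels, phenotype = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  gene_ids <- if (spec$feature_policy == "clinical_only") character() else rownames(expr)
  n <- if (spec$feature_policy == "clinical_only") nrow(phenotype) else ncol(expr)
  y <- check_labels(labels, n)
  if (spec$feature_policy != "genes_only" && is.null(phenotype)) {
    abort("phenotype required for models with clinical fields")
  }
  fit <- switch(spec$family,
    dlda = fit_dlda(expr, y),
    knn = fit_knn(expr, y, spec$hyperparameters$k),
    ntp = fit_ntp(expr, y),
    logistic = {
      x <- build_design(spec, expr, phenotype, gene_ids)
      fit_logistic(x, y, spec$hyperparameters$ridge_penalty)
    },
    plugin = {
      x <- build_design(spec, expr, phenotype, gene_ids)
      list(fit = spec$hyperparameters$train(x, y))
    })
  structure(list(spec = spec, selected_gene_ids = gene_ids, fit = fit),
            class = c(paste0(spec$family, "_model"), "trained_model"))
}

fit_dlda <- function(expr, y) {
  if (min(table(y)) < 2L) abort("DLDA needs >= 2 samples per class")
  x_l <- expr[, y == "lethal", drop = FALSE]
  x_i <- expr[, y == "indolent", drop = FALSE]
  n_l <- ncol(x_l); n_i <- ncol(x_i)
  mu_l <- rowMeans(x_l); mu_i <- rowMeans(x_i)
  pooled <- (rowSums((x_l - mu_l)^2) + rowSums((x_i - mu_i)^2)) / (n_l + n_i - 2L)
  keep <- pooled > 0
  if (!all(keep)) {
    warn(sprintf("DLDA: dropped %d zero-variance gene(s)", sum(!keep)))
  }
  if (!any(keep)) abort("DLDA: all genes have zero pooled variance")
  list(genes = rownames(expr)[keep], mu_lethal = mu_l[keep],
       mu_indolent = mu_i[keep], pooled_var = pooled[keep])
}

fit_knn <- function(expr, y, k) {
  if (k > ncol(expr)) abort("k cannot exceed the number of training samples")
  list(exemplars = expr, labels = y, k = k)
}

fit_ntp <- function(expr, y) {
  if (nrow(expr) < 2L) abort("NTP needs at least 2 marker genes")
  mu <- rowMeans(expr)
  s <- apply(expr, 1L, sd)
  s[s == 0] <- 1  # constant markers carry no direction; standardised to 0
  z <- (expr - mu) / s
  d <- rowMeans(z[, y == "lethal", drop = FALSE]) -
    rowMeans(z[, y == "indolent", drop = FALSE])
  if (all(d == 0)) abort("degenerate template: all markers have zero mean difference")
  list(genes = rownames(expr), center = mu, scale = s,
       template_lethal = sign(d))
}

# Ridge-penalised logistic regression by iteratively reweighted least
# squares; the intercept is never penalised. Separation at penalty 0 shows
# up as non-convergence or exploding coefficients and triggers a flagged
# refit at the default penalty.
fit_logistic <- function(x, y, ridge_penalty, .retry = TRUE) {
  x1 <- cbind(`(intercept)` = 1, x)
  p <- ncol(x1)
  pen <- diag(c(0, rep(ridge_penalty, p - 1L)), p)
  beta <- numeric(p)
  yy <- as.numeric(y == "lethal")
  converged <- FALSE
  for (iter in seq_len(100L)) {
    eta <- drop(x1 %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (yy - mu) / w
    xtw <- t(x1 * w)
    beta_new <- tryCatch(
      drop(solve(xtw %*% x1 + pen, xtw %*% z)),
      error = function(e) rep(NA_real_, p))
    if (any(!is.finite(beta_new))) break
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < 1e-8) { converged <- TRUE; break }
  }
  diverged <- !converged || any(abs(beta) > 1e6)
  if (diverged && ridge_penalty == 0 && .retry) {
    warn("logistic fit did not converge at penalty 0 (separation?); refitting with ridge_penalty = 1e-4")
    fit <- fit_logistic(x, y, 1e-4, .retry = FALSE)
    fit$refit_penalty <- TRUE
    return(fit)
  }
  list(coefficients = setNames(beta, colnames(x1)), converged = converged,
       ridge_penalty = ridge_penalty, refit_penalty = FALSE,
       iterations = iter)
}

#' Score samples with a trained model
#'
#' One finite score per sample, oriented larger = more lethal. Errors if a
#' selected feature is absent from the input.
#'
#' @param model A `"trained_model"` from [train_model()].
#' @param expr Genes-by-samples matrix covering the model's selected genes
#'   (ignored by clinical-only models).
#' @param phenotype Phenotype rows for the scored samples, when the model
#'   uses clinical fields.
#' @return Named numeric vector of scores.
#' @export
score_samples <- function(model, expr = NULL, phenotype = NULL) {
  UseMethod("score_samples")
}

get_expr_slice <- function(model, expr, genes = model$selected_gene_ids) {
  if (is.null(expr)) abort("this model requires an expression matrix")
  missing_genes <- setdiff(genes, rownames(expr))
  if (length(missing_genes)) {
    abort(sprintf("scoring error: missing selected feature(s): %s",
                  paste(head(missing_genes, 5), collapse = ", ")))
  }
  expr[genes, , drop = FALSE]
}

#' @export
score_samples.dlda_model <- function(model, expr = NULL, phenotype = NULL) {
  f <- model$fit
  x <- get_expr_slice(model, expr, f$genes)
  colSums(((x - f$mu_indolent)^2 - (x - f$mu_lethal)^2) / f$pooled_var)
}

#' @export
score_samples.knn_model <- function(model, expr = NULL, phenotype = NULL) {
  f <- model$fit
  x <- get_expr_slice(model, expr, rownames(f$exemplars))
  train <- f$exemplars
  vapply(seq_len(ncol(x)), function(j) {
    d <- sqrt(colSums((train - x[, j])^2))
    # ties broken by smaller training-sample index (stable sort)
    nn <- order(d, seq_along(d))[seq_len(f$k)]
    mean(f$labels[nn] == "lethal")
  }, numeric(1L), USE.NAMES = FALSE) |> setNames(colnames(x))
}

#' @export
score_samples.ntp_model <- function(model, expr = NULL, phenotype = NULL) {
  f <- model$fit
  x <- get_expr_slice(model, expr, f$genes)
  z <- (x - f$center) / f$scale
  tl <- f$template_lethal
  norm_t <- sqrt(sum(tl^2))
  cos_l <- vapply(seq_len(ncol(z)), function(j) {
    v <- z[, j]
    nv <- sqrt(sum(v^2))
    if (nv == 0) return(0)
    sum(v * tl) / (nv * norm_t)
  }, numeric(1L))
  # templates are sign-opposite, so d_indolent - d_lethal = 2 * cos(lethal)
  setNames(2 * cos_l, colnames(z))
}

#' @export
score_samples.logistic_model <- function(model, expr = NULL, phenotype = NULL) {
  x <- build_design(model$spec, expr, phenotype, model$selected_gene_ids)
  beta <- model$fit$coefficients
  if (!identical(colnames(x), names(beta)[-1L])) {
    missing_cols <- setdiff(names(beta)[-1L], colnames(x))
    if (length(missing_cols)) {
      abort(sprintf("scoring error: missing selected feature(s): %s",
                    paste(head(missing_cols, 5), collapse = ", ")))
    }
    x <- x[, names(beta)[-1L], drop = FALSE]
  }
  scores <- drop(cbind(1, x) %*% beta)
  setNames(scores, rownames(x) %||% phenotype$sample_id)
}

#' @export
score_samples.plugin_model <- function(model, expr = NULL, phenotype = NULL) {
  x <- build_design(model$spec, expr, phenotype, model$selected_gene_ids)
  scores <- model$spec$hyperparameters$score(model$fit$fit, x)
  if (length(scores) != nrow(x) || any(!is.finite(scores))) {
    abort("plugin score function must return one finite score per sample")
  }
  setNames(as.numeric(scores), rownames(x))
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained %s model> %d gene(s)%s\n", x$spec$family,
              length(x$selected_gene_ids),
              if (length(x$spec$clinical_fields))
                paste0(" + clinical {", paste(x$spec$clinical_fields, collapse = ", "), "}")
              else ""))
  invisible(x)
}
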