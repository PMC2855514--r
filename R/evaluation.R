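#' Split a cohort into Learning and Validation sets
#'
#' Random split stratified by outcome: each class is allocated to the
#' Learning set at `learning_fraction` (rounded), so per-class proportions
#' match within one sample. Excluded samples are left out of both sets.
#'
#' @param phenotype A phenotype tibble.
#' @param learning_fraction Fraction of each class assigned to the Learning
#'   set (default 0.5; the split ratio is configurable because no single
#'   value is canonical).
#' @param seed Integer seed; the same seed reproduces the split exactly.
#' @return List with `learning_ids` and `validation_ids`.
#' @export
split_learning_validation <- function(phenotype, learning_fraction = 0.5,
                                      seed = 1L) {
  phenotype <- phenotype_table(phenotype)
  assert_scalar_number(learning_fraction, "learning_fraction", 1e-12, 1 - 1e-12)
  keep <- phenotype$outcome %in% c("lethal", "indolent")
  ids <- phenotype$sample_id[keep]
  out <- as.character(phenotype$outcome[keep])
  if (min(table(out)) < 2L) abort("need >= 2 samples per class to split")
  withr::local_seed(substream_seed(seed, "split"))
  learning_ids <- character()
  for (cl in c("lethal", "indolent")) {
    cl_ids <- ids[out == cl]
    n_learn <- round(learning_fraction * length(cl_ids))
    if (n_learn < 1L || n_learn >= length(cl_ids)) {
      abort(sprintf("learning_fraction leaves class '%s' empty on one side", cl))
    }
    learning_ids <- c(learning_ids, sample(cl_ids, n_learn))
  }
  list(learning_ids = sort(learning_ids),
       validation_ids = sort(setdiff(ids, learning_ids)))
}

#' Stratified repeated k-fold plans
#'
#' Builds `repetitions` independent stratified k-fold partitions of the
#' given samples (e.g. 10 folds repeated 100 times = 1000 train/test plans).
#' Within a repetition the test folds are disjoint, their union is the full
#' set, and each fold's class counts are within one sample of proportional.
#'
#' @param phenotype Phenotype tibble restricted to the Learning samples
#'   (excluded outcomes are dropped).
#' @param k Number of folds (default 10).
#' @param repetitions Number of independent partitions (default 100).
#' @param seed Integer seed.
#' @return A tibble of class `"fold_plan"` with columns `repetition`,
#'   `fold`, and list-columns `train_ids`, `test_ids`.
#' @export
make_fold_plans <- function(phenotype, k = 10L, repetitions = 100L, seed = 1L) {
  phenotype <- phenotype_table(phenotype)
  keep <- phenotype$outcome %in% c("lethal", "indolent")
  ids <- phenotype$sample_id[keep]
  out <- as.character(phenotype$outcome[keep])
  if (k < 2L) abort("k must be >= 2")
  if (length(ids) < k) abort("more folds than samples: a test fold would be empty")
  withr::local_seed(substream_seed(seed, "folds"))
  plans <- vector("list", repetitions)
  for (r in seq_len(repetitions)) {
    fold_of <- integer(length(ids))
    for (cl in unique(out)) {
      idx <- which(out == cl)
      fold_of[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
    }
    test_sets <- split(ids, fold_of)
    if (length(test_sets) < k || any(lengths(test_sets) == 0L)) {
      abort("a test fold has zero samples")
    }
    for (f in seq_len(k)) {
      train <- ids[fold_of != f]
      if (length(unique(out[fold_of != f])) < 2L) {
        abort("a training fold is missing a class; reduce k")
      }
      plans[[r]][[f]] <- tibble::tibble(
        repetition = r, fold = f,
        train_ids = list(train), test_ids = list(ids[fold_of == f]))
    }
    plans[[r]] <- dplyr::bind_rows(plans[[r]])
  }
  out_tbl <- dplyr::bind_rows(plans)
  class(out_tbl) <- c("fold_plan", class(out_tbl))
  out_tbl
}

#' Area under the ROC curve
#'
#' Mann-Whitney form: the fraction of (lethal, indolent) pairs in which the
#' lethal sample has the higher score, counting ties as half. Equals the
#' probability that a random lethal sample outranks a random indolent one.
#'
#' @param scores Numeric vector.
#' @param labels `"lethal"`/`"indolent"` per score; both classes must be
#'   present.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  labels <- as.character(labels)
  pos <- labels == "lethal"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) abort("undefined AUC: one class is absent")
  r <- rank(scores)  # midranks handle ties as half-concordant
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Feature-selection configuration
#'
#' @param p_threshold Per-gene t-test p-value cut-off for threshold mode
#'   (the canonical choices are 0.01 and 0.001).
#' @param mode `"threshold"` or `"stepwise"`. Stepwise sorts genes by p and
#'   grows the set one gene at a time, scoring each candidate size by inner
#'   stratified cross-validated AUC on the training slice only, then keeps
#'   the smallest set attaining the maximal inner AUC ("best AUC with the
#'   fewer number of gene predictors").
#' @param stepwise_inner_folds Inner CV folds for stepwise mode (default 5).
#' @param max_genes Cap on the selected set size (default 50 for stepwise;
#'   `Inf` for threshold mode).
#' @return A list of class `"selection_config"`.
#' @export
selection_config <- function(p_threshold = 0.01,
                             mode = c("threshold", "stepwise"),
                             stepwise_inner_folds = 5L, max_genes = NULL) {
  mode <- match.arg(mode)
  assert_scalar_number(p_threshold, "p_threshold", 1e-300, 1 - 1e-12)
  max_genes <- max_genes %||% (if (mode == "stepwise") 50L else Inf)
  if (max_genes < 1) abort("max_genes must be positive")
  structure(list(p_threshold = p_threshold, mode = mode,
                 stepwise_inner_folds = as.integer(stepwise_inner_folds),
                 max_genes = max_genes),
            class = "selection_config")
}

#' Select genes inside a training fold
#'
#' Receives only the training slice — by construction it can never see test
#' samples, which is the pipeline's anti-leakage contract. Threshold mode
#' returns the genes with t-test `p < p_threshold`, ordered by p. Stepwise
#' mode evaluates nested candidate sets (ordered by p) by inner stratified
#' CV AUC and returns the smallest set attaining the maximum.
#'
#' @param expr Genes-by-samples matrix of training samples only.
#' @param labels Outcome labels for those samples.
#' @param config A [selection_config()].
#' @param spec Classifier used to score stepwise candidates (default DLDA);
#'   ignored in threshold mode.
#' @param seed Seed for the stepwise inner folds.
#' @return Character vector of gene ids (possibly empty: the caller decides
#'   whether to fall back to clinical-only or skip).
#' @export
select_features_in_fold <- function(expr, labels, config, spec = NULL,
                                    seed = 1L) {
  stopifnot(inherits(config, "selection_config"))
  tests <- gene_tests(expr, labels)
  ranked <- tests[order(tests$p), ]
  if (config$mode == "threshold") {
    sel <- ranked$gene_id[ranked$p < config$p_threshold]
    return(head(sel, config$max_genes))
  }
  pool <- head(ranked$gene_id, min(config$max_genes, nrow(ranked)))
  if (!length(pool)) return(character())
  spec <- spec %||% model_spec("dlda")
  y <- as.character(labels)
  ph_stub <- tibble::tibble(sample_id = colnames(expr), outcome = y,
                            death_from_cancer = y == "lethal",
                            followup_years = 0)
  inner <- make_fold_plans(ph_stub, k = config$stepwise_inner_folds,
                           repetitions = 1L, seed = substream_seed(seed, "inner"))
  names(y) <- colnames(expr)
  inner_auc <- vapply(seq_along(pool), function(m) {
    genes <- pool[seq_len(m)]
    fold_aucs <- purrr::map_dbl(seq_len(nrow(inner)), function(i) {
      tr <- inner$train_ids[[i]]; te <- inner$test_ids[[i]]
      fit <- tryCatch(
        train_model(spec, expr[genes, tr, drop = FALSE], y[tr]),
        error = function(e) NULL)
      if (is.null(fit)) return(NA_real_)
      auc(score_samples(fit, expr[genes, te, drop = FALSE]), y[te])
    })
    mean(fold_aucs, na.rm = TRUE)
  }, numeric(1L))
  best <- max(inner_auc, na.rm = TRUE)
  m_star <- which(inner_auc >= best - 1e-12)[[1L]]  # smallest set at the max
  pool[seq_len(m_star)]
}

#' Iterated cross-validation of classifier specs
#'
#' For every fold plan and every spec: select genes on the training slice
#' (unless `leaky = TRUE`, which deliberately selects once on the full
#' sample set to demonstrate selection bias), train, score the held-out
#' fold, and record the test AUC. Per-repetition means and grand means are
#' aggregated per spec. A failing fold is recorded and skipped with a
#' warning, never fatal — thousand-partition runs must not abort on one
#' degenerate fold.
#'
#' @param dataset A [cohort()] (already aligned).
#' @param model_specs A list of [model_spec()]s.
#' @param fold_plans A [make_fold_plans()] tibble.
#' @param config A [selection_config()].
#' @param leaky If `TRUE`, feature selection sees all samples in the plans
#'   (the biased variant; for demonstration and testing only).
#' @param seed Seed for stepwise inner folds.
#' @return An `"evaluation_report"`: list with `per_fold`,
#'   `per_repetition`, `summary` tibbles and the spec list.
#' @export
run_cv <- function(dataset, model_specs, fold_plans, config = selection_config(),
                   leaky = FALSE, seed = 1L) {
  stopifnot(inherits(dataset, "cohort"))
  if (inherits(model_specs, "model_spec")) model_specs <- list(model_specs)
  expr <- dataset$expression
  ph <- dataset$phenotype
  y <- setNames(as.character(ph$outcome), ph$sample_id)

  leaky_genes <- NULL
  if (leaky) {
    all_ids <- unique(c(unlist(fold_plans$train_ids), unlist(fold_plans$test_ids)))
    leaky_genes <- select_features_in_fold(expr[, all_ids, drop = FALSE],
                                           y[all_ids], config, seed = seed)
  }

  rows <- vector("list", nrow(fold_plans) * length(model_specs))
  ri <- 0L
  for (i in seq_len(nrow(fold_plans))) {
    tr <- fold_plans$train_ids[[i]]
    te <- fold_plans$test_ids[[i]]
    genes <- NULL
    needs_genes <- any(vapply(model_specs, function(s)
      s$feature_policy != "clinical_only", logical(1L)))
    if (needs_genes) {
      genes <- if (leaky) leaky_genes else
        select_features_in_fold(expr[, tr, drop = FALSE], y[tr], config,
                                seed = substream_seed(seed, paste0("sel", i)))
    }
    for (s in seq_along(model_specs)) {
      spec <- model_specs[[s]]
      ri <- ri + 1L
      res <- tryCatch({
        uses_genes <- spec$feature_policy != "clinical_only"
        if (uses_genes && !length(genes)) {
          abort("empty selection: no genes passed the filter")
        }
        fit <- train_model(
          spec,
          if (uses_genes) expr[genes, tr, drop = FALSE] else NULL,
          y[tr],
          phenotype = ph[match(tr, ph$sample_id), , drop = FALSE])
        sc <- score_samples(
          fit,
          expr = if (uses_genes) expr[genes, te, drop = FALSE] else NULL,
          phenotype = ph[match(te, ph$sample_id), , drop = FALSE])
        list(auc = auc(sc, y[te]), n_genes = if (uses_genes) length(genes) else 0L,
             error = NA_character_)
      }, error = function(e) list(auc = NA_real_, n_genes = NA_integer_,
                                  error = conditionMessage(e)))
      rows[[ri]] <- tibble::tibble(
        model = spec$label, family = spec$family,
        repetition = fold_plans$repetition[[i]], fold = fold_plans$fold[[i]],
        auc = res$auc, n_genes = res$n_genes, error = res$error)
    }
  }
  per_fold <- dplyr::bind_rows(rows)
  n_failed <- sum(!is.na(per_fold$error))
  if (n_failed > 0L) {
    warn(sprintf("run_cv: %d fold fit(s) failed and were skipped", n_failed))
  }
  per_repetition <- per_fold |>
    dplyr::filter(is.na(.data$error)) |>
    dplyr::group_by(.data$model, .data$family, .data$repetition) |>
    dplyr::summarise(mean_auc = mean(.data$auc),
                     mean_n_genes = mean(.data$n_genes), .groups = "drop")
  summary <- per_repetition |>
    dplyr::group_by(.data$model, .data$family) |>
    dplyr::summarise(grand_mean_auc = mean(.data$mean_auc),
                     sd_auc = sd(.data$mean_auc),
                     mean_n_genes = mean(.data$mean_n_genes),
                     n_repetitions = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$grand_mean_auc))
  structure(list(per_fold = per_fold, per_repetition = per_repetition,
                 summary = summary, specs = model_specs, leaky = leaky),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report>%s\n", if (x$leaky) " (LEAKY variant)" else ""))
  print(x$summary)
  invisible(x)
}

#' Pick the best model from a cross-validation report
#'
#' Maximal grand-mean AUC; exact ties broken by fewer mean selected genes,
#' then by the documented family order dlda, logistic, knn, ntp, plugin.
#'
#' @param report An `"evaluation_report"`.
#' @return The winning [model_spec()].
#' @export
select_best_model <- function(report) {
  stopifnot(inherits(report, "evaluation_report"))
  s <- report$summary
  if (!nrow(s)) abort("empty evaluation report")
  fam_order <- c(dlda = 1L, logistic = 2L, knn = 3L, ntp = 4L, plugin = 5L)
  s <- s[order(-s$grand_mean_auc, s$mean_n_genes, fam_order[s$family]), ]
  winner <- s$model[[1L]]
  report$specs[[which(vapply(report$specs, `[[`, character(1L), "label") == winner)[[1L]]]]
}

#' Final evaluation on the Validation set
#'
#' Refits the chosen spec on the full Learning set (features reselected
#' there, never on validation samples), scores the Validation set, and
#' reports the validation AUC with two labelled confidence intervals: a
#' stratified bootstrap percentile interval over validation resamples, and —
#' when a cross-validation report is supplied for a gene-using model — the
#' percentile interval of the repetition-level CV AUC distribution.
#'
#' @param dataset A [cohort()].
#' @param learning_ids,validation_ids Sample ids from
#'   [split_learning_validation()].
#' @param spec The chosen [model_spec()].
#' @param config A [selection_config()].
#' @param bootstrap_reps Bootstrap resamples (default 2000).
#' @param seed Integer seed.
#' @param cv_report Optional `"evaluation_report"` for the CV-distribution
#'   interval.
#' @param confidence Interval coverage (default 0.95).
#' @return A list with `auc`, `n_genes`, `ci_bootstrap` (lo/hi), and
#'   `ci_cv_distribution` (lo/hi or NULL).
#' @export
validate_final <- function(dataset, learning_ids, validation_ids, spec,
                           config = selection_config(), bootstrap_reps = 2000L,
                           seed = 1L, cv_report = NULL, confidence = 0.95) {
  stopifnot(inherits(dataset, "cohort"))
  expr <- dataset$expression
  ph <- dataset$phenotype
  y <- setNames(as.character(ph$outcome), ph$sample_id)
  if (length(unique(y[validation_ids])) < 2L) {
    abort("validation set is missing a class")
  }
  uses_genes <- spec$feature_policy != "clinical_only"
  genes <- character()
  if (uses_genes) {
    genes <- select_features_in_fold(expr[, learning_ids, drop = FALSE],
                                     y[learning_ids], config, spec = spec,
                                     seed = substream_seed(seed, "final_sel"))
    if (!length(genes)) abort("empty selection on the Learning set")
  }
  fit <- train_model(spec,
                     if (uses_genes) expr[genes, learning_ids, drop = FALSE] else NULL,
                     y[learning_ids],
                     phenotype = ph[match(learning_ids, ph$sample_id), , drop = FALSE])
  sc <- score_samples(fit,
                      expr = if (uses_genes) expr[genes, validation_ids, drop = FALSE] else NULL,
                      phenotype = ph[match(validation_ids, ph$sample_id), , drop = FALSE])
  val_auc <- auc(sc, y[validation_ids])

  withr::local_seed(substream_seed(seed, "bootstrap"))
  yv <- y[validation_ids]
  idx_l <- which(yv == "lethal"); idx_i <- which(yv == "indolent")
  boot <- vapply(seq_len(bootstrap_reps), function(b) {
    take <- c(sample(idx_l, replace = TRUE), sample(idx_i, replace = TRUE))
    auc(sc[take], yv[take])
  }, numeric(1L))
  alpha <- (1 - confidence) / 2
  ci_boot <- unname(quantile(boot, c(alpha, 1 - alpha), type = 7))

  ci_cv <- NULL
  if (!is.null(cv_report) && uses_genes) {
    reps <- cv_report$per_repetition
    reps <- reps$mean_auc[reps$model == spec$label]
    if (length(reps) >= 2L) {
      ci_cv <- unname(quantile(reps, c(alpha, 1 - alpha), type = 7))
    }
  }
  list(auc = val_auc, n_genes = length(genes), model = fit,
       scores = sc,
       ci_bootstrap = list(lo = ci_boot[[1L]], hi = ci_boot[[2L]]),
       ci_cv_distribution = if (!is.null(ci_cv))
         list(lo = ci_cv[[1L]], hi = ci_cv[[2L]]) else NULL,
       confidence = confidence)
}
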