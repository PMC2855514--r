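#' Simulate a cohort and write it to disk
#'
#' Orchestration stage: generates a synthetic cohort, writes the expression
#' matrix, phenotype table and ground-truth sidecars as TSV under `out_dir`,
#' plus a JSON manifest echoing the configuration and seed so the run can be
#' reproduced bit-identically.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with the written `paths` and the generated
#'   objects (`cohort`, `truth`).
#' @export
pipeline_simulate <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  gen <- generate_cohort(config)
  paths <- list(
    expression = file.path(out_dir, "expression.tsv"),
    phenotype = file.path(out_dir, "phenotype.tsv"),
    truth_samples = file.path(out_dir, "truth_samples.tsv"),
    truth_genes = file.path(out_dir, "truth_genes.tsv"),
    manifest = file.path(out_dir, "manifest.json"))
  write_expression(gen$cohort$expression, paths$expression)
  write_phenotype(gen$cohort$phenotype, paths$phenotype)
  truth <- gen$truth
  readr::write_tsv(tibble::tibble(
    sample_id = names(truth$subtype),
    lethal_subtype = unname(truth$subtype),
    stroma_contaminated = unname(truth$stroma_flag)), paths$truth_samples)
  gene_roles <- dplyr::bind_rows(c(
    unname(purrr::imap(truth$signal_gene_ids, function(g, j)
      tibble::tibble(gene_id = g, role = sprintf("signal_subtype_%s", j)))),
    list(tibble::tibble(gene_id = truth$erg_signature_gene_ids, role = "erg_signature"),
         tibble::tibble(gene_id = truth$stroma_gene_ids, role = "stroma"))))
  readr::write_tsv(gene_roles, paths$truth_genes)
  write_manifest(paths$manifest, stage = "simulate", seed = config$seed,
                 config = unclass(config), t0 = t0,
                 outputs = unlist(paths[names(paths) != "manifest"]))
  invisible(list(paths = paths, cohort = gen$cohort, truth = truth))
}

#' Run the full classifier-evaluation protocol
#'
#' Orchestration stage mirroring the study protocol: stratified
#' Learning/Validation split, repeated stratified k-fold cross-validation
#' with in-fold feature selection, model selection by grand-mean AUC, and a
#' final fit evaluated once on the Validation set with bootstrap (and, for
#' gene models, CV-distribution) confidence intervals. Writes per-fold and
#' summary TSVs plus a manifest.
#'
#' @param dataset A [cohort()].
#' @param model_specs List of [model_spec()]s to compare.
#' @param out_dir Output directory.
#' @param selection A [selection_config()].
#' @param k,repetitions Cross-validation geometry (defaults 10 and 100).
#' @param learning_fraction Learning-set fraction (default 0.5).
#' @param bootstrap_reps Validation bootstrap resamples (default 2000).
#' @param seed Master seed; stages draw from named substreams.
#' @return Invisibly, a list with `report`, `best_spec`, `validation`,
#'   `split` and the written `paths`.
#' @export
pipeline_evaluate <- function(dataset, model_specs, out_dir,
                              selection = selection_config(), k = 10L,
                              repetitions = 100L, learning_fraction = 0.5,
                              bootstrap_reps = 2000L, seed = 1L) {
  stopifnot(inherits(dataset, "cohort"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  split <- split_learning_validation(dataset$phenotype, learning_fraction, seed)
  learn_ph <- dataset$phenotype[dataset$phenotype$sample_id %in% split$learning_ids, ]
  plans <- make_fold_plans(learn_ph, k = k, repetitions = repetitions, seed = seed)
  report <- run_cv(dataset, model_specs, plans, selection, seed = seed)
  best <- select_best_model(report)
  val <- validate_final(dataset, split$learning_ids, split$validation_ids,
                        best, selection, bootstrap_reps, seed, cv_report = report)
  paths <- list(per_fold = file.path(out_dir, "cv_per_fold.tsv"),
                summary = file.path(out_dir, "cv_summary.tsv"),
                validation = file.path(out_dir, "validation.tsv"),
                manifest = file.path(out_dir, "manifest.json"))
  readr::write_tsv(report$per_fold, paths$per_fold)
  readr::write_tsv(report$summary, paths$summary)
  readr::write_tsv(tibble::tibble(
    model = best$label, validation_auc = val$auc, n_genes = val$n_genes,
    ci_bootstrap_lo = val$ci_bootstrap$lo, ci_bootstrap_hi = val$ci_bootstrap$hi,
    ci_cv_lo = val$ci_cv_distribution$lo %||% NA_real_,
    ci_cv_hi = val$ci_cv_distribution$hi %||% NA_real_,
    confidence = val$confidence), paths$validation)
  write_manifest(paths$manifest, stage = "evaluate", seed = seed,
                 config = list(k = k, repetitions = repetitions,
                               learning_fraction = learning_fraction,
                               bootstrap_reps = bootstrap_reps,
                               selection = unclass(selection),
                               models = vapply(model_specs, `[[`, character(1L), "label")),
                 t0 = t0, outputs = unlist(paths[names(paths) != "manifest"]))
  invisible(list(report = report, best_spec = best, validation = val,
                 split = split, paths = paths))
}

#' Run the homogeneity analysis
#'
#' Orchestration stage: selects a gene signature (a supplied list, or the
#' deliberately overfit outcome signature), computes pairwise distances and
#' per-sample homogeneity scores between the outcome classes, and writes the
#' scores, group averages with structure categories, and silhouette-plot
#' records.
#'
#' @param dataset A [cohort()]; excluded samples are dropped.
#' @param out_dir Output directory.
#' @param signature_genes Optional character vector of gene ids; `NULL`
#'   selects the overfit signature at `q_threshold`.
#' @param q_threshold FDR threshold for the overfit signature (default 0.05).
#' @param metric Distance metric (see [pairwise_distances()]).
#' @param seed Recorded in the manifest (the stage itself is deterministic).
#' @return Invisibly, a list with `result`, `groups`, `signature` and
#'   `paths`.
#' @export
pipeline_homogeneity <- function(dataset, out_dir, signature_genes = NULL,
                                 q_threshold = 0.05,
                                 metric = "one_minus_pearson", seed = 1L) {
  stopifnot(inherits(dataset, "cohort"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  keep <- dataset$phenotype$outcome %in% c("lethal", "indolent")
  expr <- dataset$expression[, keep, drop = FALSE]
  groups <- as.character(dataset$phenotype$outcome)[keep]
  if (is.null(signature_genes)) {
    sig <- overfit_signature(dataset, q_threshold)$gene_id
    if (length(sig) < 2L) abort("overfit signature has fewer than 2 genes")
  } else {
    sig <- intersect(signature_genes, rownames(expr))
    if (length(sig) < 2L) abort("fewer than 2 signature genes present in the matrix")
  }
  d <- pairwise_distances(expr, sig, metric = metric)
  res <- silhouette_widths(d, groups)
  grp <- group_homogeneity(res)
  paths <- list(scores = file.path(out_dir, "homogeneity_scores.tsv"),
                groups = file.path(out_dir, "homogeneity_groups.tsv"),
                plot_data = file.path(out_dir, "silhouette_plot_data.tsv"),
                signature = file.path(out_dir, "signature_genes.txt"),
                manifest = file.path(out_dir, "manifest.json"))
  readr::write_tsv(tibble::as_tibble(res), paths$scores)
  readr::write_tsv(grp, paths$groups)
  readr::write_tsv(silhouette_plot_data(res), paths$plot_data)
  writeLines(sig, paths$signature)
  write_manifest(paths$manifest, stage = "homogeneity", seed = seed,
                 config = list(metric = metric, q_threshold = q_threshold,
                               n_signature_genes = length(sig),
                               signature_supplied = !is.null(signature_genes)),
                 t0 = t0, outputs = unlist(paths[names(paths) != "manifest"]))
  invisible(list(result = res, groups = grp, signature = sig, paths = paths))
}

#' Compute the clinical association table
#'
#' Orchestration stage: Gleason-by-outcome association (Cramer's V and
#' Fisher's exact test) and ERG-by-outcome association (odds ratio with
#' Woolf interval and Fisher's exact test). Blocks whose variable is
#' entirely unknown are skipped with a notice.
#'
#' @param dataset A [cohort()] (only the phenotype is used).
#' @param out_dir Output directory.
#' @param confidence Interval coverage for the odds ratio (default 0.95).
#' @param seed Recorded in the manifest; also seeds any Monte-Carlo Fisher
#'   test on tables larger than 2x2.
#' @return Invisibly, a list with the association tibble (`associations`),
#'   the underlying tables, and `paths`.
#' @export
pipeline_associate <- function(dataset, out_dir, confidence = 0.95, seed = 1L) {
  stopifnot(inherits(dataset, "cohort"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  ph <- dataset$phenotype[dataset$phenotype$outcome %in% c("lethal", "indolent"), ]
  rows <- list()
  tables <- list()

  if (any(ph$gleason_category != "unknown")) {
    tab <- contingency(ph, "gleason_category", "outcome")
    tables$gleason <- tab
    fe <- fisher_exact(tab, seed = substream_seed(seed, "fisher_gleason"))
    rows$gleason <- tibble::tibble(
      statistic = c("gleason_cramers_v", "gleason_fisher_p"),
      value = c(cramers_v(tab), fe$p),
      ci_lo = NA_real_, ci_hi = NA_real_,
      method = c("cramers_v", fe$method), seed = seed)
  } else {
    inform("pipeline_associate: gleason_category all unknown; block skipped")
  }

  if (any(ph$erg_status != "unknown")) {
    tab <- contingency(ph, "erg_status", "outcome")
    # orient rows rearranged/negative and columns lethal/indolent so the
    # odds ratio reads "lethality enrichment among ERG-rearranged"
    tab <- tab[intersect(c("rearranged", "negative"), rownames(tab)),
               intersect(c("lethal", "indolent"), colnames(tab)), drop = FALSE]
    tables$erg <- tab
    if (all(dim(tab) == 2L)) {
      or <- odds_ratio_ci(tab, confidence)
      fe <- fisher_exact(tab)
      rows$erg <- tibble::tibble(
        statistic = c("erg_odds_ratio", "erg_fisher_p"),
        value = c(or$or, fe$p),
        ci_lo = c(or$lo, NA_real_), ci_hi = c(or$hi, NA_real_),
        method = c("woolf", fe$method), seed = seed)
    } else {
      inform("pipeline_associate: ERG table is degenerate; block skipped")
    }
  } else {
    inform("pipeline_associate: erg_status all unknown; block skipped")
  }

  associations <- dplyr::bind_rows(rows)
  paths <- list(associations = file.path(out_dir, "associations.tsv"),
                manifest = file.path(out_dir, "manifest.json"))
  readr::write_tsv(associations, paths$associations)
  write_manifest(paths$manifest, stage = "associate", seed = seed,
                 config = list(confidence = confidence), t0 = t0,
                 outputs = paths$associations)
  invisible(list(associations = associations, tables = tables, paths = paths))
}

# One manifest schema for every stage: config echo, seed, package version,
# timing, outputs. Enough to re-run a deterministic stage bit-identically.
write_manifest <- function(path, stage, seed, config, t0, outputs) {
  jsonlite::write_json(list(
    stage = stage,
    package = "hetsig",
    version = as.character(utils::packageVersion("hetsig")),
    seed = seed,
    config = config,
    elapsed_secs = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    outputs = unname(outputs)),
    path, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}
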