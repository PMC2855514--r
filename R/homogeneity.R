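#' Pairwise sample distances over a gene subset
#'
#' Computes the sample-by-sample distance matrix used by the homogeneity
#' analysis, over an optional gene subset. `one_minus_pearson` (the
#' expression-profile standard, and the default) is 1 minus the Pearson
#' correlation of the two samples' profiles across the subset; `euclidean`
#' is the ordinary distance. Genes with any missing value are dropped with a
#' reported count.
#'
#' @param expr Genes-by-samples matrix.
#' @param gene_subset Gene ids to use (default all).
#' @param metric `"one_minus_pearson"` or `"euclidean"`.
#' @return Symmetric numeric matrix with zero diagonal and sample dimnames.
#' @export
pairwise_distances <- function(expr, gene_subset = NULL,
                               metric = c("one_minus_pearson", "euclidean")) {
  metric <- match.arg(metric)
  validate_expression_matrix(expr)
  if (!is.null(gene_subset)) {
    missing_genes <- setdiff(gene_subset, rownames(expr))
    if (length(missing_genes) == length(gene_subset)) {
      abort("none of the requested genes are present in the matrix")
    }
    expr <- expr[intersect(gene_subset, rownames(expr)), , drop = FALSE]
  }
  keep <- !apply(is.na(expr), 1L, any)
  if (!all(keep)) {
    inform(sprintf("pairwise_distances: dropped %d gene(s) with missing values",
                   sum(!keep)))
    expr <- expr[keep, , drop = FALSE]
  }
  if (metric == "one_minus_pearson") {
    if (nrow(expr) < 2L) abort("correlation distance needs >= 2 genes")
    sds <- apply(expr, 2L, sd)
    if (any(sds == 0)) {
      abort(sprintf("zero-variance sample under correlation metric: %s",
                    colnames(expr)[sds == 0][[1L]]))
    }
    d <- 1 - cor(expr)
  } else {
    d <- as.matrix(dist(t(expr)))
  }
  diag(d) <- 0
  d
}

#' Per-sample silhouette widths (homogeneity scores)
#'
#' For each sample, `a(i)` is its mean distance to the other members of its
#' own group and `b(i)` its mean distance to the nearest other group; the
#' homogeneity score is `s(i) = (b(i) - a(i)) / max(a(i), b(i))`, in
#' \[-1, 1\]. A sample alone in its group gets `s(i) = 0` by convention.
#' With two groups (the usual case here) `b(i)` is simply the mean distance
#' to the other group.
#'
#' @param dist Symmetric distance matrix with sample dimnames (e.g. from
#'   [pairwise_distances()]).
#' @param groups Group label per sample (>= 2 groups must be present).
#' @return A tibble of class `"silhouette_result"` with columns `sample_id`,
#'   `group`, `score`.
#' @export
silhouette_widths <- function(dist, groups) {
  if (!is.matrix(dist) || nrow(dist) != ncol(dist)) {
    abort("dist must be a square matrix")
  }
  if (max(abs(dist - t(dist))) > 1e-8) abort("dist must be symmetric")
  groups <- as.character(groups)
  if (length(groups) != nrow(dist)) abort("one group label per sample required")
  lv <- unique(groups)
  if (length(lv) < 2L) abort("all samples are in one group")
  n <- nrow(dist)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(groups == groups[[i]])
    own <- own[own != i]
    if (!length(own)) { scores[[i]] <- 0; next }  # singleton convention
    a_i <- mean(dist[i, own])
    b_i <- min(vapply(setdiff(lv, groups[[i]]), function(g) {
      mean(dist[i, groups == g])
    }, numeric(1L)))
    m <- max(a_i, b_i)
    scores[[i]] <- if (m == 0) 0 else (b_i - a_i) / m
  }
  out <- tibble::tibble(sample_id = rownames(dist) %||% as.character(seq_len(n)),
                        group = groups, score = scores)
  class(out) <- c("silhouette_result", class(out))
  out
}

#' Average homogeneity per group
#'
#' Plain means of the per-sample homogeneity scores, per group and overall,
#' with the structure category of each group average attached.
#'
#' @param result A `"silhouette_result"`.
#' @return Tibble with columns `group`, `n`, `avg_score`, `category`;
#'   the overall average is in `attr(, "overall")`.
#' @export
group_homogeneity <- function(result) {
  stopifnot(inherits(result, "silhouette_result"))
  out <- result |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(), avg_score = mean(.data$score),
                     .groups = "drop") |>
    dplyr::mutate(category = structure_category(.data$avg_score))
  attr(out, "overall") <- mean(result$score)
  out
}

#' Structure category of an average homogeneity score
#'
#' The classical silhouette interpretation bands: above 0.70 a strong
#' structure, 0.51-0.70 reasonable, 0.26-0.50 weak, at or below 0.25 no
#' substantial structure. These bands agree with the two labelled anchors of
#' the prostate study (0.71 strong, 0.34 weak).
#'
#' @param avg_score Numeric vector in \[-1, 1\].
#' @return Character vector: `"strong"`, `"reasonable"`, `"weak"` or
#'   `"none"`.
#' @export
structure_category <- function(avg_score) {
  if (any(!is.finite(avg_score)) || any(abs(avg_score) > 1 + 1e-12)) {
    abort("average homogeneity score must be in [-1, 1]")
  }
  dplyr::case_when(
    avg_score >= 0.705 ~ "strong",
    avg_score > 0.50 ~ "reasonable",
    avg_score > 0.25 ~ "weak",
    TRUE ~ "none")
}

#' Deliberately overfit outcome signature
#'
#' Selects the genes that best separate the outcome classes on the ENTIRE
#' cohort — intentionally overfitting, to obtain the best available
#' molecular descriptors of the two groups for the homogeneity analysis
#' (never for classifier evaluation). Per-gene two-sided t-tests with
#' q-value correction; genes with `q < q_threshold`, sorted by p.
#'
#' @param dataset A [cohort()]; excluded samples are ignored.
#' @param q_threshold FDR threshold (default 0.05).
#' @param method q-value method, `"storey"` (default) or `"bh"`.
#' @return Tibble with `gene_id`, `t`, `p`, `q`, sorted by p.
#' @export
overfit_signature <- function(dataset, q_threshold = 0.05,
                              method = c("storey", "bh")) {
  stopifnot(inherits(dataset, "cohort"))
  method <- match.arg(method)
  assert_scalar_number(q_threshold, "q_threshold", 1e-12, 1 - 1e-12)
  keep <- dataset$phenotype$outcome %in% c("lethal", "indolent")
  tests <- gene_tests(dataset$expression[, keep, drop = FALSE],
                      as.character(dataset$phenotype$outcome)[keep])
  tests$q <- as.numeric(compute_q_values(tests$p, method = method))
  out <- tests[tests$q < q_threshold, , drop = FALSE]
  out[order(out$p), ]
}

#' Silhouette-plot bar records
#'
#' Orders samples within each group by descending homogeneity score (ties by
#' sample id) — the layout of a silhouette plot.
#'
#' @param result A `"silhouette_result"`.
#' @return Tibble `(group, sample_id, score)` in plotting order, with a
#'   `bar` index column.
#' @export
silhouette_plot_data <- function(result) {
  stopifnot(inherits(result, "silhouette_result"))
  out <- result |>
    tibble::as_tibble() |>
    dplyr::arrange(.data$group, dplyr::desc(.data$score), .data$sample_id) |>
    dplyr::select("group", "sample_id", "score")
  out$bar <- seq_len(nrow(out))
  out
}

#' Flag stroma-contaminated samples
#'
#' Average-linkage hierarchical clustering of the samples on the
#' 1 - Pearson distance over a stroma gene signature, cut into two clusters;
#' the cluster with the higher mean stroma-gene expression is flagged. The
#' strength of the separation is reported as the flagged cluster's average
#' silhouette width and its structure category — on uncontaminated data the
#' two clusters are arbitrary and the separation reads weak or none.
#'
#' @param dataset A [cohort()].
#' @param stroma_gene_ids Stroma signature gene ids; at least 5 must be
#'   present in the matrix.
#' @return Tibble `(sample_id, flagged)`; attributes `n_flagged`,
#'   `separation` (average silhouette of the flagged cluster),
#'   `separation_category`, and `cluster_means`.
#' @export
flag_stroma_samples <- function(dataset, stroma_gene_ids) {
  stopifnot(inherits(dataset, "cohort"))
  expr <- dataset$expression
  present <- intersect(stroma_gene_ids, rownames(expr))
  if (length(present) < 5L) {
    abort(sprintf("only %d of the stroma signature genes are present (need >= 5)",
                  length(present)))
  }
  d <- pairwise_distances(expr, present, metric = "one_minus_pearson")
  tree <- hclust(as.dist(d), method = "average")
  cl <- cutree(tree, k = 2L)
  means <- vapply(1:2, function(k) mean(expr[present, cl == k, drop = FALSE]),
                  numeric(1L))
  flag_cluster <- which.max(means)
  flagged <- cl == flag_cluster
  sil <- silhouette_widths(d, ifelse(flagged, "stroma", "other"))
  sep <- mean(sil$score[flagged])
  out <- tibble::tibble(sample_id = colnames(expr), flagged = unname(flagged))
  attr(out, "n_flagged") <- sum(flagged)
  attr(out, "separation") <- sep
  attr(out, "separation_category") <- structure_category(max(min(sep, 1), -1))
  attr(out, "cluster_means") <- means
  inform(sprintf("flag_stroma_samples: flagged %d sample(s); separation %s (%.2f)",
                 sum(flagged), attr(out, "separation_category"), sep))
  out
}
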