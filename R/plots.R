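#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_hline geom_boxplot
#'   geom_point facet_grid labs theme_minimal coord_flip
NULL

#' Silhouette plot of homogeneity scores
#'
#' Horizontal bars, one per sample, sorted by descending homogeneity score
#' within each group; the dashed line marks each group's average.
#'
#' @param object A `"silhouette_result"` from [silhouette_widths()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.silhouette_result <- function(object, ...) {
  pd <- silhouette_plot_data(object)
  grp <- group_homogeneity(object)
  pd$group <- factor(pd$group)
  ggplot(pd, aes(x = -.data$bar, y = .data$score, fill = .data$group)) +
    geom_col(width = 1) +
    geom_hline(data = grp, aes(yintercept = .data$avg_score),
               linetype = "dashed", linewidth = 0.3) +
    facet_grid(rows = ggplot2::vars(.data$group), scales = "free_y",
               space = "free_y") +
    coord_flip() +
    labs(x = NULL, y = "homogeneity score (silhouette width)",
         fill = "group") +
    theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid.major.y = ggplot2::element_blank())
}

#' @rdname autoplot.silhouette_result
#' @param result A `"silhouette_result"`.
#' @export
plot_silhouette <- function(result) autoplot(result)

#' AUC distribution plot for an evaluation report
#'
#' One box per model spec over the repetition-level mean AUCs, with the
#' grand mean marked; the dashed line is chance (AUC 0.5).
#'
#' @param object An `"evaluation_report"` from [run_cv()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.evaluation_report <- function(object, ...) {
  ggplot(object$per_repetition,
         aes(x = stats::reorder(.data$model, .data$mean_auc),
             y = .data$mean_auc)) +
    geom_boxplot(outlier.size = 0.5) +
    geom_point(data = object$summary,
               aes(x = .data$model, y = .data$grand_mean_auc),
               colour = "red", size = 2) +
    geom_hline(yintercept = 0.5, linetype = "dashed") +
    coord_flip() +
    labs(x = NULL, y = "cross-validated AUC (per-repetition mean)") +
    theme_minimal()
}
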