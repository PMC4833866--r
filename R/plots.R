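#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' ROC curve with the optimal cutoff marked
#'
#' @param object A [optimal_cutoff()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gcr_cutoff <- function(object, ...) {
  roc <- roc_points(object$grid)
  best <- object$evaluation
  ggplot2::ggplot(roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point(data = tibble::tibble(fpr = 1 - best$spec,
                                              tpr = best$sens),
                        colour = "red", size = 2) +
    ggplot2::annotate("text", x = 1 - best$spec, y = best$sens,
                      label = sprintf("c* = %.2f", object$cutoff),
                      hjust = -0.15, vjust = 1.2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("ROC (AUC = %.3f)", object$auc))
}

#' Empirical CDFs of the two samples in a discrete KS test
#'
#' @param object A [ks_discrete_test()] result. The samples themselves are
#'   not stored in the object, so pass them again.
#' @param a,b The two samples.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ks_discrete <- function(object, a, b, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(value = a, sample = "a"),
    tibble::tibble(value = b, sample = "b")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, colour = .data$sample)) +
    ggplot2::stat_ecdf(geom = "step") +
    ggplot2::labs(x = "patch score", y = "ECDF",
                  title = sprintf("Discrete KS: D = %.3f, p = %.3g",
                                  object$statistic, object$p.value))
}

#' Permutation null distribution with the observed statistic
#'
#' @param object A `perm_enrichment` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.perm_enrichment <- function(object, ...) {
  ggplot2::ggplot(tibble::tibble(stat = object$perm_stats),
                  ggplot2::aes(x = .data$stat)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey80", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red") +
    ggplot2::labs(x = object$statistic, y = "random sets",
                  title = sprintf("observed = %g, p = %.3g",
                                  object$observed, object$p.value))
}

#' Bar chart of per-sample defect combinations
#'
#' @param object An [summarize_samples()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.alteration_summary <- function(object, ...) {
  ggplot2::ggplot(object$fractions,
                  ggplot2::aes(x = .data$combination, y = .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~definition) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "fraction of samples")
}

#' Histogram of GCR strain scores per assay
#'
#' @param strain_scores A [score_strains()] result.
#' @param wt_scores Optional named vector or tibble of control scores per
#'   assay, drawn as vertical lines.
#' @return A ggplot.
#' @export
plot_score_distribution <- function(strain_scores, wt_scores = NULL) {
  p <- ggplot2::ggplot(dplyr::filter(strain_scores, !is.na(.data$score)),
                       ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(binwidth = 0.25, boundary = 0, fill = "grey75",
                            colour = "grey40") +
    ggplot2::facet_wrap(~assay, scales = "free_y") +
    ggplot2::labs(x = "GCR strain score", y = "strains")
  if (!is.null(wt_scores)) {
    if (is.numeric(wt_scores)) {
      wt_scores <- tibble::tibble(assay = names(wt_scores),
                                  wt_score = unname(wt_scores))
    }
    p <- p + ggplot2::geom_vline(data = wt_scores,
                                 ggplot2::aes(xintercept = .data$wt_score),
                                 colour = "red", linetype = "dashed")
  }
  p
}
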