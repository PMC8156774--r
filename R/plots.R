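#' Plot training curves of a fitted link model
#'
#' Per-epoch binary cross-entropy and binary accuracy for the training and
#' validation (test-tier) links.
#'
#' @param object A `crispr_link_fit` from [train_link_model()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot crispr_link_fit
#' @export
autoplot.crispr_link_fit <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$epoch, y = .data$value,
                                  colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~ .data$metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL,
                  title = "Link-model training history") +
    ggplot2::theme_minimal()
}

#' ROC curve of a fitted link model
#'
#' @param fit A `crispr_link_fit`.
#' @param tier Which link tier to plot (default `"independent"`).
#' @return A ggplot object; the subtitle reports the tier auROC.
#' @export
plot_roc <- function(fit, tier = "independent") {
  sc <- fit$scores[fit$scores$tier == tier, ]
  ord <- order(sc$score, decreasing = TRUE)
  y <- sc$label[ord]
  d <- tibble(
    fpr = c(0, cumsum(y == 0) / sum(y == 0)),
    tpr = c(0, cumsum(y == 1) / sum(y == 1))
  )
  auc <- evaluate_auroc(sc$score, sc$label)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = 2, colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = paste0("ROC, ", tier, " tier"),
                  subtitle = sprintf("auROC = %.3f", auc)) +
    ggplot2::theme_minimal()
}

#' Heatmap of an experiment grid
#'
#' Feature scheme by balance mode, filled by mean independent-tier auROC.
#'
#' @param grid Output of [run_experiment_grid()].
#' @return A ggplot object.
#' @export
plot_grid_auroc <- function(grid) {
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$mode, y = .data$scheme,
                                     fill = .data$auroc_independent)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.3f", .data$auroc_independent)), colour = "white") +
    ggplot2::scale_fill_viridis_c(limits = c(0.5, 1), name = "auROC") +
    ggplot2::labs(x = "cluster sampling", y = "features",
                  title = "Independent-tier auROC") +
    ggplot2::theme_minimal()
}
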