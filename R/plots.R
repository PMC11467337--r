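#' Swarm-style plot of one morphometric parameter by genotype
#'
#' Jittered per-cell points with group mean +/- sd, the visual convention of
#' per-parameter group comparisons.
#'
#' @param morpho Tibble with per-cell measurements and a genotype column.
#' @param parameter Column name to plot.
#' @param genotype Genotype column name.
#' @return A ggplot object.
#' @export
plot_group_comparison <- function(morpho, parameter,
                                  genotype = "genotype") {
  stopifnot(parameter %in% names(morpho), genotype %in% names(morpho))
  df <- tibble::tibble(value = morpho[[parameter]],
                       genotype = morpho[[genotype]])
  stats <- df |>
    dplyr::group_by(.data$genotype) |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     sd = sd(.data$value, na.rm = TRUE), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$genotype, y = .data$value,
                                   colour = .data$genotype)) +
    ggplot2::geom_jitter(width = 0.25, alpha = 0.4, size = 0.8) +
    ggplot2::geom_pointrange(
      data = stats,
      ggplot2::aes(y = .data$mean, ymin = .data$mean - .data$sd,
                   ymax = .data$mean + .data$sd),
      colour = "black", linewidth = 0.6) +
    ggplot2::labs(x = NULL, y = parameter) +
    ggplot2::theme_classic() +
    ggplot2::theme(legend.position = "none")
}

#' Patient-level ROC curve plot
#' @param object A `roc_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  pts <- object$points
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step(direction = "hv", linewidth = 0.8) +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  subtitle = sprintf("AUC = %.4f", object$auc)) +
    ggplot2::theme_classic()
}

#' Training history plot (loss and accuracies per epoch)
#' @param model A trained `ht_classifier`.
#' @return A ggplot object.
#' @export
plot_training_history <- function(model) {
  stopifnot(!is.null(model$history))
  h <- tidyr::pivot_longer(model$history,
                           c("loss", "acc_optimization",
                             "acc_generalization"),
                           names_to = "metric")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value,
                                  colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = model$selected_epoch,
                        linetype = "dotted") +
    ggplot2::facet_wrap(~ .data$metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "Epoch", y = NULL) +
    ggplot2::theme_classic() +
    ggplot2::theme(legend.position = "none")
}

#' Mid-plane section plot of a tomogram
#' @param tomo A [tomogram()].
#' @param z Slice index (default: middle).
#' @return A ggplot object.
#' @export
plot_tomogram_slice <- function(tomo, z = NULL) {
  stopifnot(inherits(tomo, "tomogram"))
  d <- dim(tomo$ri)
  if (is.null(z)) z <- ceiling(d[3] / 2)
  df <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]))
  df$ri <- as.numeric(tomo$ri[, , z])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$ri)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "RI") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_void()
}
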