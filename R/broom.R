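#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a Mann-Whitney comparison
#' @param x A `mann_whitney` object.
#' @param ... Unused.
#' @return One-row tibble: statistic (U), p.value, method.
#' @method tidy mann_whitney
#' @export
tidy.mann_whitney <- function(x, ...) {
  tibble::tibble(statistic = x$u, p.value = x$p_value, method = x$method)
}

#' Tidy the ROC points of a screening result
#' @param x A `roc_result`.
#' @param ... Unused.
#' @return Tibble of threshold, fpr, tpr.
#' @method tidy roc_result
#' @export
tidy.roc_result <- function(x, ...) x$points

#' One-line summary of a screening ROC
#' @param x A `roc_result`.
#' @param ... Unused.
#' @return One-row tibble: auc, n_positive, n_negative, plus the two
#'   operating points.
#' @method glance roc_result
#' @export
glance.roc_result <- function(x, ...) {
  op <- operating_points(x)
  tibble::tibble(
    auc = x$auc, n_positive = x$n_positive, n_negative = x$n_negative,
    tpr_at_zero_fpr = op$tpr_at_zero_fpr$value,
    fpr_at_full_tpr = op$fpr_at_full_tpr$value)
}

#' Per-layer parameter table of the classifier
#' @param x An `ht_classifier`.
#' @param ... Unused.
#' @return Tibble: op name, type, input/output channels, n_parameters.
#' @method tidy ht_classifier
#' @export
tidy.ht_classifier <- function(x, ...) {
  rows <- lapply(x$plan, function(op) {
    pn <- paste0(op$name, c(".W", ".b", ".gamma", ".beta"))
    np <- sum(vapply(pn, function(p)
      if (is.null(x$params[[p]])) 0L else length(x$params[[p]]), 0L))
    if (np == 0) return(NULL)
    tibble::tibble(name = op$name, type = op$type,
                   cin = op$cin %||% NA_integer_,
                   cout = op$cout %||% NA_integer_,
                   n_parameters = np)
  })
  dplyr::bind_rows(rows)
}

#' One-line summary of a trained classifier
#' @param x An `ht_classifier`.
#' @param ... Unused.
#' @return One-row tibble with architecture scale, parameter count and,
#'   when trained, the selected epoch and its accuracies.
#' @method glance ht_classifier
#' @export
glance.ht_classifier <- function(x, ...) {
  out <- tibble::tibble(
    n_parameters = x$n_parameters,
    n_stages = x$arch$n_stages,
    base_channels = x$arch$base_channels,
    latent_dim = x$arch$latent_dim)
  if (!is.null(x$history) && nrow(x$history) > 0) {
    sel <- x$history[x$history$epoch == x$selected_epoch, ]
    out$selected_epoch <- x$selected_epoch
    out$acc_optimization <- sel$acc_optimization
    out$acc_generalization <- sel$acc_generalization
  }
  out
}
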