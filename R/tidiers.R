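#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a cross-validation result
#'
#' One row per fold and metric, in long format.
#'
#' @param x An `mtl_cv` object.
#' @param ... Unused.
#' @return Tibble `(fold, metric, value)`.
#' @export
tidy.mtl_cv <- function(x, ...) {
  x$fold_metrics |>
    tidyr::pivot_longer(-"fold", names_to = "metric", values_to = "value")
}

#' Summarise a cross-validation result
#'
#' Cross-fold mean and standard deviation of every metric, one column pair
#' per metric, one row total.
#'
#' @param x An `mtl_cv` object.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.mtl_cv <- function(x, ...) {
  x$summary |>
    tidyr::pivot_wider(names_from = "metric", values_from = c("mean", "sd"),
                       names_glue = "{metric}_{.value}")
}

#' Plot out-of-fold predictions against the ground truth
#'
#' @param object An `mtl_cv` object.
#' @param task `"synergy"` or `"sensitivity"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mtl_cv <- function(object, task = c("synergy", "sensitivity"), ...) {
  task <- match.arg(task)
  if (task == "synergy") {
    df <- object$synergy_predictions
    xlab <- "observed Loewe synergy score"
  } else {
    df <- object$sensitivity_predictions
    df <- dplyr::rename(df, loewe_score = "ri_score")
    xlab <- "observed RI sensitivity score"
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$loewe_score, y = .data$pred_score)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::labs(x = xlab, y = "out-of-fold prediction",
                  title = sprintf("%s: out-of-fold predictions", task)) +
    ggplot2::theme_minimal()
}

#' Tidy an autoencoder training history
#' @param x A `trained_autoencoder`.
#' @param ... Unused.
#' @return Tibble `(epoch, train_loss, val_loss)`.
#' @export
tidy.trained_autoencoder <- function(x, ...) x$history

#' Summarise a trained autoencoder
#' @param x A `trained_autoencoder`.
#' @param ... Unused.
#' @return One-row tibble with dimensions and best monitored loss.
#' @export
glance.trained_autoencoder <- function(x, ...) {
  tibble::tibble(input_dim = x$spec$input_dim, hidden_dim = x$spec$hidden_dim,
                 code_dim = x$spec$code_dim, best_epoch = x$best_epoch,
                 best_loss = x$best_loss)
}

#' Plot an autoencoder training curve
#' @param object A `trained_autoencoder`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.trained_autoencoder <- function(object, ...) {
  object$history |>
    tidyr::pivot_longer(-"epoch", names_to = "series") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$epoch, y = .data$value,
                                 colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "reconstruction loss", title = "autoencoder pretraining") +
    ggplot2::theme_minimal()
}

#' Tidy a predictor fit history
#' @param x An `mtl_fit`.
#' @param ... Unused.
#' @return The per-epoch loss history tibble.
#' @export
tidy.mtl_fit <- function(x, ...) x$history

#' Summarise a predictor fit
#' @param x An `mtl_fit`.
#' @param ... Unused.
#' @return One-row tibble with the early-stopping outcome.
#' @export
glance.mtl_fit <- function(x, ...) {
  tibble::tibble(epochs_run = nrow(x$history), best_epoch = x$best_epoch,
                 best_val_loss = x$best_val_loss,
                 learning_rate = x$spec$learning_rate,
                 shared_layer_size = x$spec$shared_layer_sizes[1],
                 variant = x$spec$variant)
}

#' Plot a predictor training history
#' @param object An `mtl_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mtl_fit <- function(object, ...) {
  object$history |>
    dplyr::select("epoch", "train_total", "val_total") |>
    tidyr::pivot_longer(-"epoch", names_to = "series") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$epoch, y = .data$value,
                                 colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 3) +
    ggplot2::labs(y = "total loss", title = "multi-task training") +
    ggplot2::theme_minimal()
}

#' Per-tissue boxplot of cell-line correlations
#'
#' @param cell_pcc Output of [per_group_pcc()] grouped by `cell_id`.
#' @param annotation Tibble `cell_id`, `tissue`.
#' @return A ggplot.
#' @export
plot_tissue_pcc <- function(cell_pcc, annotation) {
  cell_pcc |>
    dplyr::inner_join(annotation, by = "cell_id") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$tissue, y = .data$pcc)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1) +
    ggplot2::labs(x = NULL, y = "per-cell-line PCC",
                  title = "synergy prediction quality by tissue") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
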