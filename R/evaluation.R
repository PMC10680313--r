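#' Label a synergy score
#'
#' Positive (strong synergy) iff the Loewe score is strictly greater than the
#' threshold (default 30); scores at or below it are negative.
#'
#' @param score Numeric vector of Loewe synergy scores.
#' @param threshold Decision boundary (default 30).
#' @return Character vector of `"positive"` / `"negative"`.
#' @export
label_synergy <- function(score, threshold = 30) {
  ifelse(score > threshold, "positive", "negative")
}

#' Label a monotherapy sensitivity score
#'
#' Positive iff the RI score is strictly greater than the threshold (default
#' 50). The boundary is strict for consistency with the synergy labeler.
#'
#' @param score Numeric vector of RI scores.
#' @param threshold Decision boundary (default 50).
#' @return Character vector of `"positive"` / `"negative"`.
#' @export
label_sensitivity <- function(score, threshold = 50) {
  ifelse(score > threshold, "positive", "negative")
}

as_binary_label <- function(labels) {
  if (is.numeric(labels)) return(as.integer(labels != 0))
  as.integer(labels == "positive")
}

#' Regression metrics
#'
#' Mean squared error, its square root, and the Pearson correlation between
#' observed and predicted values. A constant observed vector has no defined
#' correlation; `pcc` is then `NA` and `pcc_defined` is `FALSE`.
#'
#' @param y Observed values (length >= 2).
#' @param y_hat Predicted values, same length.
#' @return A one-row tibble: `mse`, `rmse`, `pcc`, `pcc_defined`, `n`.
#' @export
regression_metrics <- function(y, y_hat) {
  if (length(y) != length(y_hat)) abort("y and y_hat lengths differ")
  if (length(y) < 2) abort("need at least 2 observations")
  mse <- mean((y - y_hat)^2)
  defined <- stats::sd(y) > 0 && stats::sd(y_hat) > 0
  tibble::tibble(
    mse = mse,
    rmse = sqrt(mse),
    pcc = if (defined) stats::cor(y, y_hat) else NA_real_,
    pcc_defined = defined,
    n = length(y)
  )
}

#' Classification metrics
#'
#' ROC-AUC by the rank statistic (tied probabilities receive averaged ranks,
#' i.e. ties count one half), PR-AUC by step-wise integration of the
#' precision-recall curve (no interpolation), and accuracy at a probability
#' cutoff of 0.5 on the positive class.
#'
#' @param labels Binary labels: 0/1 or `"negative"`/`"positive"`.
#' @param probs Positive-class probabilities.
#' @return A one-row tibble: `roc_auc`, `pr_auc`, `acc`, `n_pos`, `n_neg`.
#'   AUCs are `NA` when either class is absent.
#' @export
classification_metrics <- function(labels, probs) {
  y <- as_binary_label(labels)
  if (length(y) != length(probs)) abort("labels and probs lengths differ")
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  acc <- mean((probs > 0.5) == (y == 1))
  if (n_pos == 0 || n_neg == 0) {
    return(tibble::tibble(roc_auc = NA_real_, pr_auc = NA_real_, acc = acc,
                          n_pos = n_pos, n_neg = n_neg))
  }
  r <- rank(probs)  # average ranks for ties
  roc_auc <- (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  # step-wise PR integration over thresholds descending; tied probabilities
  # enter as one block
  ord <- order(-probs)
  ys <- y[ord]; ps <- probs[ord]
  block_last <- which(diff(ps) != 0)
  cut_idx <- c(block_last, length(ps))
  tp <- cumsum(ys)[cut_idx]
  fp <- cumsum(1 - ys)[cut_idx]
  recall <- tp / n_pos
  precision <- tp / (tp + fp)
  pr_auc <- sum(diff(c(0, recall)) * precision)
  tibble::tibble(roc_auc = roc_auc, pr_auc = pr_auc, acc = acc,
                 n_pos = n_pos, n_neg = n_neg)
}

#' Per-group Pearson correlation
#'
#' Computes the correlation between observed and predicted scores within each
#' group (cell line or tissue). Groups with fewer than 3 samples, or with a
#' constant observed vector, are flagged and get no value.
#'
#' @param predictions Data frame holding observed and predicted columns plus
#'   the grouping column.
#' @param group Name of the grouping column (e.g. `"cell_id"` or `"tissue"`).
#' @param truth,estimate Names of the observed and predicted columns.
#' @return Tibble `(group, pcc, n, flagged)`, one row per group.
#' @export
per_group_pcc <- function(predictions, group,
                          truth = "loewe_score", estimate = "pred_score") {
  stopifnot(group %in% names(predictions))
  predictions |>
    dplyr::summarise(
      n = dplyr::n(),
      pcc = if (dplyr::n() >= 3 && stats::sd(.data[[truth]]) > 0) {
        stats::cor(.data[[truth]], .data[[estimate]])
      } else {
        NA_real_
      },
      .by = dplyr::all_of(group)
    ) |>
    dplyr::mutate(flagged = is.na(.data$pcc)) |>
    dplyr::select(dplyr::all_of(group), "pcc", "n", "flagged")
}

#' Per-tissue summary of cell-line correlations
#'
#' Aggregates per-cell-line correlations to a boxplot-ready per-tissue table.
#'
#' @param cell_pcc Output of [per_group_pcc()] grouped by `cell_id`.
#' @param annotation Tibble `cell_id`, `tissue`.
#' @return Tibble `(tissue, median_pcc, n_cell_lines)`.
#' @export
per_tissue_summary <- function(cell_pcc, annotation) {
  cell_pcc |>
    dplyr::inner_join(annotation, by = "cell_id") |>
    dplyr::summarise(
      median_pcc = stats::median(.data$pcc, na.rm = TRUE),
      n_cell_lines = dplyr::n(),
      .by = "tissue"
    )
}
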