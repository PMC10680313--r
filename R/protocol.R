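#' Options for the small-panel reference study
#'
#' The package's reference experiment runs on the default synthetic fixture
#' (40 drugs x 20 cell lines, 2000 genes): a deliberately small panel where
#' full dual cross-validation stays in the minutes range on one CPU. At this
#' scale some defaults that suit thousands of drugs are counterproductive,
#' so the protocol fixes: encoder code widths of 64 (at or above the data
#' rank of the miniature panels, so compression is nearly lossless),
#' autoencoder dropout 0 (with 40 training rows, dropout starves the code of
#' signal), long autoencoder pretraining (an epoch is a single Adam step at
#' this size), a 128-wide shared trunk, branch dropout 0.2, learning rate
#' 1e-3, and a 40-epoch predictor budget.
#'
#' @param seed Top-level seed; all stage seeds are derived from it.
#' @return List with `c_drug`, `c_cell`, `ae_dropout`, `ae_opts`, `spec`,
#'   `opts` ready for [cross_validate()].
#' @export
small_panel_protocol <- function(seed = 1) {
  list(
    c_drug = 64L, c_cell = 64L, ae_dropout = 0,
    ae_opts = ae_training_opts(batch_size = 64, max_epochs = 2000,
                               patience = 2000, learning_rate = 1e-3,
                               val_fraction = 0, seed = derive_seed(seed, "ae")),
    spec = predictor_spec(shared_layer_sizes = 128, dropout_rate = 0.2,
                          learning_rate = 1e-3,
                          seed = derive_seed(seed, "predictor")),
    opts = training_opts(batch_size = 128, max_epochs = 40, patience = 40,
                         seed = derive_seed(seed, "train"))
  )
}

#' Run the synthetic-fixture reference study
#'
#' End-to-end experiment on the default synthetic fixture: generate the
#' dataset, average replicates, pre-train the autoencoders, build the dual
#' cross-validation plan, and run five-fold cross-validation with the full
#' multi-task model (and optionally the synergy-only ablation on the same
#' codes, plan and seeds, for the multi-task-benefit comparison). Pooled
#' out-of-fold metrics are computed over all five test folds.
#'
#' @param seed Top-level seed driving generation, encoding, splitting and
#'   training.
#' @param include_only_synergy Also run the `only-synergy` ablation
#'   (default `TRUE`).
#' @param config Fixture conditions; default [synthetic_config()] with a
#'   seed derived from `seed`.
#' @return A `synthetic_study` list: `dataset`, `cv_full`, `cv_only_synergy`
#'   (or `NULL`), and `metrics` (pooled out-of-fold synergy and sensitivity
#'   regression/classification metrics per model).
#' @export
run_synthetic_study <- function(seed = 1, include_only_synergy = TRUE,
                                config = NULL) {
  config <- config %||% synthetic_config(seed = derive_seed(seed, "fixture"))
  proto <- small_panel_protocol(seed)
  ds <- simulate_synergy_dataset(config)
  syn <- average_synergy_replicates(ds$synergy)
  enc <- encode_feature_sets(ds$drug_features, ds$cell_features,
                             proto$c_drug, proto$c_cell, TRUE,
                             proto$ae_opts, seed, proto$ae_dropout)
  plan <- build_cv_plan(syn, rownames(enc$drug_codes), 5, seed)
  cv_full <- cross_validate(syn, ds$sensitivity, enc$drug_codes, enc$cell_codes,
                            plan, proto$spec, proto$opts, seed = seed)
  cv_syn <- NULL
  if (include_only_synergy) {
    spec_syn <- proto$spec
    spec_syn$variant <- "only-synergy"
    cv_syn <- cross_validate(syn, ds$sensitivity, enc$drug_codes, enc$cell_codes,
                             plan, spec_syn, proto$opts, seed = seed)
  }
  pooled <- function(cv, model_name) {
    sp <- cv$synergy_predictions
    out <- dplyr::bind_cols(
      tibble::tibble(model = model_name, task = "synergy"),
      regression_metrics(sp$loewe_score, sp$pred_score)[, c("mse", "rmse", "pcc")],
      if (!all(is.na(sp$pred_prob))) {
        classification_metrics(sp$label, sp$pred_prob)[, c("roc_auc", "pr_auc", "acc")]
      }
    )
    if (!is.null(cv$sensitivity_predictions) && nrow(cv$sensitivity_predictions) > 1) {
      sn <- cv$sensitivity_predictions
      out <- dplyr::bind_rows(out, dplyr::bind_cols(
        tibble::tibble(model = model_name, task = "sensitivity"),
        regression_metrics(sn$ri_score, sn$pred_score)[, c("mse", "rmse", "pcc")],
        if (!all(is.na(sn$pred_prob))) {
          classification_metrics(sn$label, sn$pred_prob)[, c("roc_auc", "pr_auc", "acc")]
        }
      ))
    }
    out
  }
  metrics <- pooled(cv_full, "full")
  if (!is.null(cv_syn)) metrics <- dplyr::bind_rows(metrics, pooled(cv_syn, "only-synergy"))
  structure(
    list(dataset = ds, cv_full = cv_full, cv_only_synergy = cv_syn,
         metrics = metrics, plan = plan, seed = seed),
    class = "synthetic_study"
  )
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("<synthetic_study> pooled out-of-fold metrics:\n")
  print(x$metrics, n = Inf)
  invisible(x)
}
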