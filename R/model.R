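#' Train a deployable synergy model end to end
#'
#' Convenience pipeline: pre-trains the drug and cell-line autoencoders on the
#' feature sets (unless `use_autoencoder = FALSE`), encodes the features,
#' splits the synergy samples into train/validation by combination folds, and
#' fits the multi-task predictor. The result bundles everything needed to
#' score new drug pairs by id.
#'
#' @param synergy Synergy table (replicates averaged).
#' @param sensitivity Sensitivity table.
#' @param drug_features A `drug_feature_set`.
#' @param cell_features A `cell_feature_set`.
#' @param spec A [predictor_spec()].
#' @param c_drug,c_cell Encoder code widths (defaults 128 and 256).
#' @param use_autoencoder `FALSE` feeds raw z-scored features to the trunk
#'   (the no-autoencoder ablation).
#' @param val_fraction Fraction of combination folds held out for early
#'   stopping (one fold of `n_folds`).
#' @param n_folds Folds used for the internal split and leakage plan.
#' @param opts,ae_opts Training options for predictor and autoencoders.
#' @param ae_dropout Encoder dropout rate for the pre-trained autoencoders
#'   (default 0.2; set 0 for very small panels, where dropout starves the
#'   code of signal).
#' @param seed Top-level seed.
#' @param synergy_threshold,sensitivity_threshold Label boundaries.
#' @return A `synergy_model` bundling predictor, encoders, feature sets and
#'   thresholds.
#' @export
train_synergy_model <- function(synergy, sensitivity, drug_features, cell_features,
                                spec = predictor_spec(), c_drug = 128, c_cell = 256,
                                use_autoencoder = TRUE, n_folds = 5,
                                opts = training_opts(), ae_opts = ae_training_opts(),
                                seed = 1, val_fraction = NULL, ae_dropout = 0.2,
                                synergy_threshold = 30, sensitivity_threshold = 50) {
  enc <- encode_feature_sets(drug_features, cell_features, c_drug, c_cell,
                             use_autoencoder, ae_opts, seed, ae_dropout)
  plan <- build_cv_plan(synergy, rownames(enc$drug_codes), n_folds, seed)
  synergy <- dplyr::mutate(synergy,
                           combo_fold = combo_fold_of(plan, .data$drug_row, .data$drug_col))
  vf <- abs(seed) %% n_folds
  fit <- train_model(synergy[synergy$combo_fold != vf, ],
                     synergy[synergy$combo_fold == vf, ],
                     sensitivity, enc$drug_codes, enc$cell_codes, spec, plan,
                     held_out_drug_fold = NA, opts = opts,
                     synergy_threshold = synergy_threshold,
                     sensitivity_threshold = sensitivity_threshold)
  structure(
    list(predictor = fit$model, fit = fit[c("history", "best_epoch", "best_val_loss")],
         drug_encoder = enc$drug_encoder, cell_encoder = enc$cell_encoder,
         drug_codes = enc$drug_codes, cell_codes = enc$cell_codes,
         drug_features = drug_features, cell_features = cell_features,
         plan = plan, thresholds = c(synergy = synergy_threshold,
                                     sensitivity = sensitivity_threshold),
         use_autoencoder = use_autoencoder, seed = seed),
    class = "synergy_model"
  )
}

# Pretrain (or skip) the two autoencoders and return entity code matrices.
encode_feature_sets <- function(drug_features, cell_features, c_drug, c_cell,
                                use_autoencoder, ae_opts, seed, ae_dropout = 0.2) {
  fd <- drug_features$feature_matrix
  fc <- cell_features$feature_matrix
  if (!use_autoencoder) {
    return(list(drug_codes = fd, cell_codes = fc,
                drug_encoder = NULL, cell_encoder = NULL))
  }
  dspec <- autoencoder_spec(ncol(fd), c_drug, dropout_rate = ae_dropout,
                            seed = derive_seed(seed, "drug_ae"))
  cspec <- autoencoder_spec(ncol(fc), c_cell, dropout_rate = ae_dropout,
                            seed = derive_seed(seed, "cell_ae"))
  d_opts <- ae_opts; d_opts$seed <- derive_seed(seed, "drug_ae_train")
  c_opts <- ae_opts; c_opts$seed <- derive_seed(seed, "cell_ae_train")
  drug_encoder <- pretrain_autoencoder(fd, dspec, d_opts)
  cell_encoder <- pretrain_autoencoder(fc, cspec, c_opts)
  list(drug_codes = encode(drug_encoder, fd),
       cell_codes = encode(cell_encoder, fc),
       drug_encoder = drug_encoder, cell_encoder = cell_encoder)
}

lookup_code <- function(codes, id, what) {
  if (!id %in% rownames(codes)) abort(sprintf("unknown %s id '%s'", what, id))
  codes[id, , drop = FALSE]
}

#' Predict synergy and sensitivity for one drug pair on a cell line
#'
#' Runs the predictor with both drug orderings; the synergy score and
#' positive-class probability are the means over the two orders (hence exactly
#' symmetric in the drugs), while the sensitivity outputs are reported per
#' drug: drug A's from the (A, B) order and drug B's from the (B, A) order.
#'
#' @param model A `synergy_model`.
#' @param drug_a,drug_b Drug identifiers known to the model.
#' @param cell_id Cell-line identifier known to the model.
#' @return One-row tibble: `synergy_score`, `synergy_prob`, `synergy_label`,
#'   and per-drug `sensitivity_score_a/b`, `sensitivity_prob_a/b` (NA for
#'   variants without the corresponding head).
#' @export
predict_pair <- function(model, drug_a, drug_b, cell_id) {
  stopifnot(inherits(model, "synergy_model"))
  za <- lookup_code(model$drug_codes, drug_a, "drug")
  zb <- lookup_code(model$drug_codes, drug_b, "drug")
  zc <- lookup_code(model$cell_codes, cell_id, "cell line")
  pr <- model$predictor
  repA <- shared_forward(pr, za, zc)
  repB <- shared_forward(pr, zb, zc)
  out <- tibble::tibble(drug_a = drug_a, drug_b = drug_b, cell_id = cell_id,
                        synergy_score = NA_real_, synergy_prob = NA_real_,
                        synergy_label = NA_character_,
                        sensitivity_score_a = NA_real_, sensitivity_prob_a = NA_real_,
                        sensitivity_score_b = NA_real_, sensitivity_prob_b = NA_real_)
  if (!is.null(pr$syn)) {
    f1 <- synergy_forward(pr, repA, repB)
    f2 <- synergy_forward(pr, repB, repA)
    out$synergy_score <- as.numeric(f1$score + f2$score) / 2
    if (!is.null(f1$prob)) out$synergy_prob <- as.numeric(f1$prob[, 2] + f2$prob[, 2]) / 2
    out$synergy_label <- label_synergy(out$synergy_score, model$thresholds[["synergy"]])
  }
  if (!is.null(pr$sen)) {
    sa <- sensitivity_forward(pr, repA)
    sb <- sensitivity_forward(pr, repB)
    out$sensitivity_score_a <- as.numeric(sa$score)
    out$sensitivity_score_b <- as.numeric(sb$score)
    if (!is.null(sa$prob)) {
      out$sensitivity_prob_a <- as.numeric(sa$prob[, 2])
      out$sensitivity_prob_b <- as.numeric(sb$prob[, 2])
    }
  }
  out
}

#' @export
print.synergy_model <- function(x, ...) {
  cat(sprintf("<synergy_model> %d drugs, %d cell lines; variant '%s'%s\n",
              nrow(x$drug_codes), nrow(x$cell_codes), x$predictor$variant,
              if (x$use_autoencoder) " (autoencoded features)" else " (raw features)"))
  invisible(x)
}
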