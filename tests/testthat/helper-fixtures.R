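# Shared fixtures, built in code and cached for the test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# miniature dataset exercising every pipeline stage quickly
tiny_dataset <- function() {
  cached("tiny_dataset", simulate_synergy_dataset(synthetic_config(
    n_drugs = 12, n_cells = 6, n_genes = 200, k_genes = 100,
    pair_fraction = 0.8, replicate_fraction = 0.1, seed = 42
  )))
}

tiny_codes <- function() {
  cached("tiny_codes", {
    ds <- tiny_dataset()
    mtsynergy:::encode_feature_sets(
      ds$drug_features, ds$cell_features, 16, 16, TRUE,
      ae_training_opts(max_epochs = 60, patience = 60, val_fraction = 0, seed = 9),
      9, ae_dropout = 0
    )
  })
}

# a small trained multi-task fit shared by prediction-oriented tests
tiny_fit <- function() {
  cached("tiny_fit", {
    ds <- tiny_dataset()
    syn <- average_synergy_replicates(ds$synergy)
    enc <- tiny_codes()
    plan <- build_cv_plan(syn, rownames(enc$drug_codes), 5, 7)
    syn$combo_fold <- mtsynergy:::combo_fold_of(plan, syn$drug_row, syn$drug_col)
    fit <- train_model(
      syn[!syn$combo_fold %in% c(0, 1), ], syn[syn$combo_fold == 1, ],
      ds$sensitivity, enc$drug_codes, enc$cell_codes,
      predictor_spec(shared_layer_sizes = 64, dropout_rate = 0.2,
                     learning_rate = 3e-3, seed = 7),
      plan, held_out_drug_fold = 0,
      opts = training_opts(batch_size = 64, max_epochs = 45, patience = 45, seed = 7)
    )
    list(fit = fit, plan = plan, syn = syn, enc = enc, ds = ds)
  })
}

# eval-mode forward pass through an engine layer list with explicit loops,
# independent of the matrix code under test
oracle_forward_eval <- function(layers, x) {
  stopifnot(is.numeric(x), is.null(dim(x)))
  for (l in layers) {
    if (l$kind == "dense") {
      out <- numeric(ncol(l$W))
      for (j in seq_len(ncol(l$W))) {
        acc <- l$b[j]
        for (i in seq_along(x)) acc <- acc + x[i] * l$W[i, j]
        out[j] <- acc
      }
      x <- out
    } else if (l$kind == "bn") {
      for (j in seq_along(x)) {
        x[j] <- (x[j] - l$rmean[j]) / sqrt(l$rvar[j] + l$eps) * l$gamma[j] + l$beta[j]
      }
    } else if (l$kind == "relu") {
      for (j in seq_along(x)) if (x[j] < 0) x[j] <- 0
    } else if (l$kind == "dropout") {
      # inactive at inference
    }
  }
  x
}

oracle_softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}
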