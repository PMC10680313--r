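pairs_df <- function(n_drugs, cells = "c1") {
  ids <- sprintf("d%02d", seq_len(n_drugs))
  combos <- t(combn(ids, 2))
  tidyr::crossing(tibble::tibble(drug_row = combos[, 1], drug_col = combos[, 2]),
                  cell_id = cells) |>
    dplyr::mutate(loewe_score = 0)
}

test_that("combination folds deal unordered pairs round-robin", {
  samples <- pairs_df(5)  # 10 pairs
  plan <- assign_combo_folds(samples, n_folds = 5, seed = 1)
  expect_equal(as.vector(table(plan$combo_folds$fold)), rep(2L, 5))
  # both spellings of a pair land in the same fold
  f1 <- mtsynergy:::combo_fold_of(plan, "d01", "d03")
  f2 <- mtsynergy:::combo_fold_of(plan, "d03", "d01")
  expect_identical(f1, f2)
  expect_error(assign_combo_folds(pairs_df(3), n_folds = 5), "folds")
  expect_identical(assign_combo_folds(samples, 5, 9)$combo_folds,
                   assign_combo_folds(samples, 5, 9)$combo_folds)
})

test_that("no unordered pair spans two combination folds", {
  ds <- tiny_dataset()
  syn <- average_synergy_replicates(ds$synergy)
  plan <- assign_combo_folds(syn, 5, 3)
  syn$fold <- mtsynergy:::combo_fold_of(plan, syn$drug_row, syn$drug_col)
  audit <- tapply(syn$fold, pair_key(syn$drug_row, syn$drug_col),
                  function(f) length(unique(f)))  # brute-force audit
  expect_true(all(audit == 1))
  sizes <- table(plan$combo_folds$fold)
  expect_lte(max(sizes) - min(sizes), 1)
})

test_that("drug folds partition the drugs evenly and deterministically", {
  drugs <- sprintf("d%02d", 1:13)
  plan <- assign_drug_folds(drugs, 5, 2)
  expect_setequal(plan$drug_folds$drug_id, drugs)
  expect_equal(anyDuplicated(plan$drug_folds$drug_id), 0L)
  sizes <- table(plan$drug_folds$fold)
  expect_lte(max(sizes) - min(sizes), 1)
  expect_identical(assign_drug_folds(drugs, 5, 2)$drug_folds, plan$drug_folds)
  expect_error(assign_drug_folds(drugs[1:4], 5), "folds")
})

test_that("cross-validation plans round-trip through delimited text", {
  ds <- tiny_dataset()
  plan <- build_cv_plan(average_synergy_replicates(ds$synergy), seed = 4)
  dir <- withr::local_tempdir()
  write_cv_plan(plan, dir)
  back <- read_cv_plan(dir)
  expect_equal(back$combo_folds$fold, plan$combo_folds$fold)
  expect_equal(back$drug_folds$drug_id, plan$drug_folds$drug_id)
  expect_equal(back$n_folds, plan$n_folds)
})

test_that("binary cross-entropy matches its closed forms and a loop oracle", {
  expect_lt(bce_loss(1, 1 - 1e-9), 1e-6)
  expect_equal(bce_loss(c(1, 0), c(0.5, 0.5)), log(2))
  set.seed(6)
  y <- rbinom(7, 1, 0.5); p <- runif(7, 0.05, 0.95)
  acc <- 0
  for (i in 1:7) acc <- acc - (y[i] * log(p[i]) + (1 - y[i]) * log(1 - p[i]))
  expect_equal(bce_loss(y, p), acc / 7)
  expect_equal(bce_loss(c("positive", "negative"), c(0.5, 0.5)), log(2))
  expect_error(bce_loss(c(1, 0), 0.5), "lengths")
  expect_true(is.finite(bce_loss(c(1, 0), c(1, 0))))  # clamped at the extremes
})

test_that("the total loss is the plain sum of four sub-batch components", {
  perfect <- total_loss(
    list(syn_score = c(1, 2), syn_prob = c(1 - 1e-9, 1e-9),
         sen_score = 3, sen_prob = 1 - 1e-9),
    list(syn_score = c(1, 2), syn_label = c(1, 0), sen_score = 3, sen_label = 1)
  )
  expect_lt(perfect$total, 1e-6)
  set.seed(12)
  preds <- list(syn_score = rnorm(5, 10), syn_prob = runif(5, 0.1, 0.9),
                sen_score = rnorm(3, 50), sen_prob = runif(3, 0.1, 0.9))
  targs <- list(syn_score = rnorm(5, 10), syn_label = rbinom(5, 1, 0.3),
                sen_score = rnorm(3, 50), sen_label = rbinom(3, 1, 0.5))
  lb <- total_loss(preds, targs)
  # oracle: each term computed independently
  expect_equal(lb$mse_syn, mean((targs$syn_score - preds$syn_score)^2))
  expect_equal(lb$mse_sen, mean((targs$sen_score - preds$sen_score)^2))
  expect_equal(lb$bce_syn, bce_loss(targs$syn_label, preds$syn_prob))
  expect_equal(lb$bce_sen, bce_loss(targs$sen_label, preds$sen_prob))
  expect_equal(lb$total, lb$mse_syn + lb$mse_sen + lb$bce_syn + lb$bce_sen,
               tolerance = 1e-12)
  # empty sensitivity sub-batch contributes exactly zero
  empty <- total_loss(list(syn_score = preds$syn_score, syn_prob = preds$syn_prob,
                           sen_score = numeric(0), sen_prob = numeric(0)),
                      targs)
  expect_identical(empty$mse_sen, 0); expect_identical(empty$bce_sen, 0)
  expect_error(total_loss(list(syn_score = numeric(0)), targs), "synergy")
})

test_that("the leakage filter trims only the sensitivity sub-batch", {
  syn_part <- tibble::tibble(drug_row = c("a", "b", "c"), loewe_score = 1:3)
  sen_part <- tibble::tibble(drug_row = c("a", "b", "c"), ri_score = 1:3,
                             drug_fold = c(0L, 1L, 0L))
  out <- leakage_filter(list(synergy = syn_part, sensitivity = sen_part), 0L)
  expect_identical(out$synergy, syn_part)  # untouched
  expect_identical(out$sensitivity$drug_row, "b")
  all_held <- leakage_filter(list(synergy = syn_part,
                                  sensitivity = dplyr::mutate(sen_part, drug_fold = 0L)), 0L)
  expect_equal(nrow(all_held$sensitivity), 0)
  none_held <- leakage_filter(list(synergy = syn_part, sensitivity = sen_part), 4L)
  expect_identical(none_held$sensitivity, sen_part)
  # brute-force row scan on a random batch
  set.seed(9)
  sen <- tibble::tibble(drug_row = sample(letters[1:6], 30, TRUE),
                        drug_fold = sample(0:4, 30, TRUE))
  kept <- leakage_filter(list(synergy = syn_part, sensitivity = sen), 2L)$sensitivity
  expect_identical(kept, sen[sen$drug_fold != 2L, ])
})

test_that("both-orders duplication doubles rows and preserves targets", {
  ds <- tiny_dataset()
  syn <- average_synergy_replicates(ds$synergy)
  ex <- expand_orders(syn)
  expect_equal(nrow(ex), 2 * nrow(syn))
  first <- ex[ex$.order == 1L, ]; second <- ex[ex$.order == 2L, ]
  expect_identical(first$loewe_score, second$loewe_score)
  expect_identical(first$drug_row, second$drug_col)
  expect_identical(first$drug_col, second$drug_row)
})

test_that("training learns the planted signal and is exactly repeatable", {
  tf <- tiny_fit()
  h <- tf$fit$history
  expect_lte(tf$fit$best_val_loss, h$val_total[1] * 0.5)  # halves the initial loss
  # identical seeds and specs give identical histories
  refit <- train_model(
    tf$syn[!tf$syn$combo_fold %in% c(0, 1), ], tf$syn[tf$syn$combo_fold == 1, ],
    tf$ds$sensitivity, tf$enc$drug_codes, tf$enc$cell_codes,
    predictor_spec(shared_layer_sizes = 64, dropout_rate = 0.2,
                   learning_rate = 3e-3, seed = 7),
    tf$plan, held_out_drug_fold = 0,
    opts = training_opts(batch_size = 64, max_epochs = 45, patience = 45, seed = 7)
  )
  expect_identical(refit$history, h)
})

test_that("patience zero stops at the first non-improving epoch", {
  tf <- tiny_fit()
  fit <- train_model(
    tf$syn[!tf$syn$combo_fold %in% c(0, 1), ], tf$syn[tf$syn$combo_fold == 1, ],
    tf$ds$sensitivity, tf$enc$drug_codes, tf$enc$cell_codes,
    predictor_spec(shared_layer_sizes = 16, dropout_rate = 0.2,
                   learning_rate = 0.05, seed = 1),  # aggressive rate forces a stumble
    tf$plan, held_out_drug_fold = 0,
    opts = training_opts(batch_size = 64, max_epochs = 50, patience = 0, seed = 1)
  )
  worse <- which(fit$history$val_total > cummin(fit$history$val_total))[1]
  expect_equal(nrow(fit$history), worse)  # halted right there
})

test_that("ablation variants zero out the excluded loss components", {
  tf <- tiny_fit()
  run_variant <- function(variant) {
    train_model(
      tf$syn[!tf$syn$combo_fold %in% c(0, 1), ], tf$syn[tf$syn$combo_fold == 1, ],
      tf$ds$sensitivity, tf$enc$drug_codes, tf$enc$cell_codes,
      predictor_spec(shared_layer_sizes = 16, dropout_rate = 0.2,
                     learning_rate = 1e-3, seed = 2, variant = variant),
      tf$plan, held_out_drug_fold = 0,
      opts = training_opts(batch_size = 64, max_epochs = 2, patience = 2, seed = 2)
    )$history
  }
  h_syn <- run_variant("only-synergy")
  expect_true(all(h_syn$val_mse_sen == 0) && all(h_syn$val_bce_sen == 0))
  expect_true(all(h_syn$val_mse_syn > 0))
  h_sen <- run_variant("only-sensitivity")
  expect_true(all(h_sen$val_mse_syn == 0) && all(h_sen$val_bce_syn == 0))
  expect_true(all(h_sen$val_mse_sen > 0))
  h_reg <- run_variant("regression-only")
  expect_true(all(h_reg$val_bce_syn == 0) && all(h_reg$val_bce_sen == 0))
  expect_true(all(h_reg$val_mse_syn > 0) && all(h_reg$val_mse_sen > 0))
})

test_that("grid search returns the argmin with the documented tie-breaks", {
  tf <- tiny_fit()
  opts <- training_opts(batch_size = 64, max_epochs = 2, patience = 2, seed = 3)
  gs <- grid_search(tf$syn[!tf$syn$combo_fold %in% c(0, 1), ],
                    tf$syn[tf$syn$combo_fold == 1, ],
                    tf$ds$sensitivity, tf$enc$drug_codes, tf$enc$cell_codes,
                    base_spec = predictor_spec(shared_layer_sizes = 16,
                                               dropout_rate = 0.2, seed = 3),
                    layer_sizes = c(8, 16), learning_rates = c(1e-3, 5e-4),
                    plan = tf$plan, held_out_drug_fold = 0, opts = opts)
  expect_equal(nrow(gs$results), 4)
  best <- gs$results[which.min(gs$results$val_loss), ]
  expect_equal(gs$best_spec$shared_layer_sizes[1], as.integer(best$layer_size))
  expect_equal(gs$best_spec$learning_rate, best$learning_rate)
  # degenerate 1x1 grid returns that cell
  gs1 <- grid_search(tf$syn[!tf$syn$combo_fold %in% c(0, 1), ],
                     tf$syn[tf$syn$combo_fold == 1, ],
                     tf$ds$sensitivity, tf$enc$drug_codes, tf$enc$cell_codes,
                     base_spec = predictor_spec(shared_layer_sizes = 16,
                                                dropout_rate = 0.2, seed = 3),
                     layer_sizes = 8, learning_rates = 1e-3,
                     plan = tf$plan, held_out_drug_fold = 0, opts = opts)
  expect_equal(gs1$best_spec$shared_layer_sizes[1], 8L)
  expect_equal(gs1$best_spec$learning_rate, 1e-3)
  # ties break toward the lower learning rate, then the smaller layer
  tied <- tibble::tibble(layer_size = c(16, 8, 8), learning_rate = c(1e-3, 1e-3, 5e-4),
                         val_loss = c(1, 1, 1), best_epoch = 1L)
  pick <- tied |> dplyr::arrange(val_loss, learning_rate, layer_size) |> dplyr::slice(1)
  expect_equal(pick$learning_rate, 5e-4)
  expect_equal(pick$layer_size, 8)
})

test_that("cross-validation gives every sample one out-of-fold synergy prediction", {
  tf <- tiny_fit()
  cv <- cached("tiny_cv", cross_validate(
    dplyr::select(tf$syn, -"combo_fold"), tf$ds$sensitivity,
    tf$enc$drug_codes, tf$enc$cell_codes, tf$plan,
    predictor_spec(shared_layer_sizes = 32, dropout_rate = 0.2,
                   learning_rate = 1e-3, seed = 7),
    training_opts(batch_size = 64, max_epochs = 6, patience = 6, seed = 7),
    seed = 7
  ))
  syn <- average_synergy_replicates(tf$ds$synergy)
  expect_equal(nrow(cv$synergy_predictions), nrow(syn))
  key <- paste(pair_key(cv$synergy_predictions$drug_row, cv$synergy_predictions$drug_col),
               cv$synergy_predictions$cell_id)
  expect_equal(anyDuplicated(key), 0L)
  # no sensitivity prediction for a drug trained on in that round
  joined <- dplyr::left_join(cv$sensitivity_predictions,
                             tf$plan$drug_folds, by = "drug_id")
  expect_true(all(joined$fold.y == joined$fold.x))
  # reproducible under the same seed
  cv2 <- cross_validate(
    dplyr::select(tf$syn, -"combo_fold"), tf$ds$sensitivity,
    tf$enc$drug_codes, tf$enc$cell_codes, tf$plan,
    predictor_spec(shared_layer_sizes = 32, dropout_rate = 0.2,
                   learning_rate = 1e-3, seed = 7),
    training_opts(batch_size = 64, max_epochs = 6, patience = 6, seed = 7),
    seed = 7
  )
  expect_identical(cv2$synergy_predictions$pred_score,
                   cv$synergy_predictions$pred_score)
  expect_identical(cv2$histories, cv$histories)
})
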