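#' Canonical key of an unordered drug pair
#' @param a,b Drug identifier vectors.
#' @return Character vector; `pair_key(a, b) == pair_key(b, a)`.
#' @export
pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "||")

new_cv_plan <- function(combo_folds = NULL, drug_folds = NULL, n_folds = 5L) {
  structure(list(combo_folds = combo_folds, drug_folds = drug_folds,
                 n_folds = as.integer(n_folds)), class = "cv_plan")
}

#' Assign drug combinations to cross-validation folds
#'
#' Unordered drug pairs are shuffled with the given seed and dealt round-robin
#' into `n_folds` groups, so a given combination exists in exactly one fold
#' and fold sizes differ by at most one pair. Samples inherit their pair's
#' fold (leave-combination-out splitting).
#'
#' @param samples Data frame with `drug_row`, `drug_col` columns.
#' @param n_folds Number of folds (default 5).
#' @param seed Shuffle seed.
#' @return A `cv_plan` with the `combo_folds` map (`pair_key`, `fold` in
#'   `0:(n_folds-1)`) filled in.
#' @export
assign_combo_folds <- function(samples, n_folds = 5, seed = 1) {
  keys <- sort(unique(pair_key(samples$drug_row, samples$drug_col)))
  if (length(keys) < n_folds) {
    abort(sprintf("only %d distinct pairs for %d folds", length(keys), n_folds))
  }
  set.seed(derive_seed(seed, "combo_folds"))
  keys <- sample(keys)
  new_cv_plan(
    combo_folds = tibble::tibble(pair_key = keys,
                                 fold = (seq_along(keys) - 1L) %% as.integer(n_folds)),
    n_folds = n_folds
  )
}

#' Assign drugs to cross-validation folds
#'
#' Analogous to [assign_combo_folds()] at single-drug granularity, used by the
#' monotherapy sensitivity task (leave-drug-out splitting).
#'
#' @param drugs Character vector of drug ids, or a data frame with `drug_id`.
#' @param n_folds Number of folds (default 5).
#' @param seed Shuffle seed.
#' @return A `cv_plan` with the `drug_folds` map filled in.
#' @export
assign_drug_folds <- function(drugs, n_folds = 5, seed = 1) {
  if (is.data.frame(drugs)) drugs <- drugs$drug_id
  drugs <- sort(unique(drugs))
  if (length(drugs) < n_folds) {
    abort(sprintf("only %d distinct drugs for %d folds", length(drugs), n_folds))
  }
  set.seed(derive_seed(seed, "drug_folds"))
  drugs <- sample(drugs)
  new_cv_plan(
    drug_folds = tibble::tibble(drug_id = drugs,
                                fold = (seq_along(drugs) - 1L) %% as.integer(n_folds)),
    n_folds = n_folds
  )
}

#' Build the dual cross-validation plan
#'
#' Combines leave-combination-out folds for the synergy task with
#' leave-drug-out folds for the sensitivity task, both derived from one seed.
#'
#' @param synergy Synergy sample table (`drug_row`, `drug_col`, ...).
#' @param drugs Drug ids for the sensitivity folds (default: all drugs
#'   appearing in `synergy`).
#' @param n_folds Number of folds (default 5).
#' @param seed Top-level seed.
#' @return A complete `cv_plan`.
#' @export
build_cv_plan <- function(synergy, drugs = NULL, n_folds = 5, seed = 1) {
  if (is.null(drugs)) drugs <- unique(c(synergy$drug_row, synergy$drug_col))
  p1 <- assign_combo_folds(synergy, n_folds, seed)
  p2 <- assign_drug_folds(drugs, n_folds, seed)
  new_cv_plan(combo_folds = p1$combo_folds, drug_folds = p2$drug_folds,
              n_folds = n_folds)
}

#' @export
print.cv_plan <- function(x, ...) {
  cat(sprintf("<cv_plan> %d folds; %s pairs, %s drugs\n", x$n_folds,
              if (is.null(x$combo_folds)) "no" else nrow(x$combo_folds),
              if (is.null(x$drug_folds)) "no" else nrow(x$drug_folds)))
  invisible(x)
}

#' Export / import a cross-validation plan
#'
#' Writes `combo_folds.csv` (`pair_key,fold`) and `drug_folds.csv`
#' (`drug_id,fold`) so a split can be reproduced exactly.
#'
#' @param plan A `cv_plan`.
#' @param dir Directory to write to / read from.
#' @return `write_cv_plan` returns `dir` invisibly; `read_cv_plan` a `cv_plan`.
#' @export
write_cv_plan <- function(plan, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(plan$combo_folds)) {
    utils::write.csv(plan$combo_folds, file.path(dir, "combo_folds.csv"), row.names = FALSE)
  }
  if (!is.null(plan$drug_folds)) {
    utils::write.csv(plan$drug_folds, file.path(dir, "drug_folds.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_cv_plan
#' @export
read_cv_plan <- function(dir) {
  cf <- file.path(dir, "combo_folds.csv")
  df <- file.path(dir, "drug_folds.csv")
  combo <- if (file.exists(cf)) tibble::as_tibble(utils::read.csv(cf)) else NULL
  drugf <- if (file.exists(df)) tibble::as_tibble(utils::read.csv(df)) else NULL
  n <- max(c(combo$fold, drugf$fold)) + 1L
  new_cv_plan(combo_folds = combo, drug_folds = drugf, n_folds = n)
}

combo_fold_of <- function(plan, drug_row, drug_col) {
  key <- pair_key(drug_row, drug_col)
  plan$combo_folds$fold[match(key, plan$combo_folds$pair_key)]
}

drug_fold_of <- function(plan, drug_id) {
  plan$drug_folds$fold[match(drug_id, plan$drug_folds$drug_id)]
}

#' Binary cross-entropy loss
#'
#' `-(1/n) * sum(y*log(y_hat) + (1-y)*log(1-y_hat))`, with predicted
#' probabilities clamped to `[1e-7, 1 - 1e-7]` to avoid `log(0)`.
#'
#' @param y Binary labels (0/1 or `"negative"`/`"positive"`).
#' @param y_hat Positive-class probabilities, same length.
#' @return A single number.
#' @export
bce_loss <- function(y, y_hat) {
  y <- as_binary_label(y)
  if (length(y) != length(y_hat)) abort("y and y_hat lengths differ")
  p <- clamp(y_hat, 1e-7, 1 - 1e-7)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Multi-task loss breakdown
#'
#' Computes the four loss components on their respective (possibly
#' different-sized) sub-batches and their plain unweighted sum. An empty
#' sensitivity sub-batch (e.g. after leakage filtering) contributes exactly 0
#' to both sensitivity terms; components without predictions (ablation
#' variants) are structurally 0. An empty synergy sub-batch is an error for
#' synergy-carrying variants: a training batch must carry synergy signal.
#'
#' @param predictions List with `syn_score`, `syn_prob` (positive-class),
#'   `sen_score`, `sen_prob`; any element may be `NULL`.
#' @param targets List with `syn_score`, `syn_label`, `sen_score`,
#'   `sen_label`, aligned with the corresponding predictions.
#' @return A one-row `loss_breakdown` tibble: `mse_syn`, `mse_sen`,
#'   `bce_syn`, `bce_sen`, `total`.
#' @export
total_loss <- function(predictions, targets) {
  has_syn <- !is.null(predictions$syn_score)
  if (has_syn && length(predictions$syn_score) == 0) {
    abort("empty synergy sub-batch: a training batch must carry synergy signal")
  }
  mse_syn <- if (has_syn) mean((targets$syn_score - predictions$syn_score)^2) else 0
  bce_syn <- if (has_syn && !is.null(predictions$syn_prob)) {
    bce_loss(targets$syn_label, predictions$syn_prob)
  } else 0
  has_sen <- !is.null(predictions$sen_score) && length(predictions$sen_score) > 0
  mse_sen <- if (has_sen) mean((targets$sen_score - predictions$sen_score)^2) else 0
  bce_sen <- if (has_sen && !is.null(predictions$sen_prob)) {
    bce_loss(targets$sen_label, predictions$sen_prob)
  } else 0
  tibble::tibble(mse_syn = mse_syn, mse_sen = mse_sen,
                 bce_syn = bce_syn, bce_sen = bce_sen,
                 total = mse_syn + mse_sen + bce_syn + bce_sen)
}

#' Remove held-out-drug rows from a mini-batch's sensitivity sub-batch
#'
#' Rows whose `drug_row` belongs to the held-out drug fold are removed from
#' the sensitivity sub-batch only; the synergy sub-batch is untouched. This is
#' the in-batch leakage control that keeps sensitivity evaluation drugs out of
#' sensitivity training.
#'
#' @param batch List with elements `synergy` (tibble) and `sensitivity`
#'   (tibble with a `drug_fold` column).
#' @param held_out_drug_fold Fold index to exclude.
#' @return The batch with the filtered sensitivity sub-batch (possibly empty).
#' @export
leakage_filter <- function(batch, held_out_drug_fold) {
  stopifnot(is.list(batch), !is.null(batch$sensitivity))
  keep <- is.na(batch$sensitivity$drug_fold) |
    batch$sensitivity$drug_fold != held_out_drug_fold
  batch$sensitivity <- batch$sensitivity[keep, , drop = FALSE]
  batch
}

#' Duplicate synergy samples into both drug orderings
#'
#' Each sample appears once as (drug_row, drug_col) and once swapped; targets
#' are unchanged. Used before batching so the model sees both presentations.
#'
#' @param samples Synergy sample tibble.
#' @return Tibble with twice the rows and an `.order` column (1 or 2).
#' @export
expand_orders <- function(samples) {
  swapped <- samples
  swapped$drug_row <- samples$drug_col
  swapped$drug_col <- samples$drug_row
  dplyr::bind_rows(
    dplyr::mutate(samples, .order = 1L),
    dplyr::mutate(swapped, .order = 2L)
  )
}

#' Predictor training options
#'
#' @param batch_size Mini-batch size (default 128).
#' @param max_epochs Hard cap on training epochs (default 500).
#' @param patience Early-stopping patience in epochs without validation
#'   improvement (default 100); `0` stops at the first non-improving epoch.
#' @param seed Seed driving initialization, batching and dropout.
#' @param eval_chunk Rows per forward chunk when evaluating.
#' @param verbose Print per-epoch losses.
#' @return A list of options.
#' @export
training_opts <- function(batch_size = 128, max_epochs = 500, patience = 100,
                          seed = 1, eval_chunk = 4096, verbose = FALSE) {
  list(batch_size = as.integer(batch_size), max_epochs = as.integer(max_epochs),
       patience = as.integer(patience), seed = as.integer(seed),
       eval_chunk = as.integer(eval_chunk), verbose = isTRUE(verbose))
}

# Attach per-row training annotations: sensitivity target of the drug_row on
# the cell (NA when absent) and the drug_row's sensitivity fold.
annotate_samples <- function(samples, sensitivity, plan,
                             synergy_threshold = 30, sensitivity_threshold = 50) {
  sen <- sensitivity |>
    dplyr::select(drug_row = "drug_id", "cell_id", "ri_score") |>
    dplyr::distinct(.data$drug_row, .data$cell_id, .keep_all = TRUE)
  out <- samples |>
    dplyr::left_join(sen, by = c("drug_row", "cell_id")) |>
    dplyr::mutate(
      syn_label = as.integer(.data$loewe_score > synergy_threshold),
      sen_label = as.integer(.data$ri_score > sensitivity_threshold)
    )
  out$drug_fold <- if (is.null(plan$drug_folds)) NA_integer_ else drug_fold_of(plan, out$drug_row)
  out
}

predictor_batch_forward <- function(model, xr, xc, sen_mask, training = TRUE) {
  fr <- nn_forward(model$trunk, xr, training)
  model$trunk <- fr$layers
  fc <- nn_forward(model$trunk, xc, training)
  model$trunk <- fc$layers
  out <- list(model = model, fr = fr, fc = fc)
  if (!is.null(model$syn)) {
    z <- cbind(fr$out, fc$out)
    br <- nn_forward(model$syn, z, training)
    model$syn <- br$layers
    hs <- nn_forward(model$syn_score, br$out, training)
    model$syn_score <- hs$layers
    out$syn <- list(branch = br, score = hs, pred = drop(hs$out))
    if (!is.null(model$syn_class)) {
      hc <- nn_forward(model$syn_class, br$out, training)
      model$syn_class <- hc$layers
      out$syn$class <- hc
      out$syn$prob <- softmax_rows(hc$out)
    }
  }
  if (!is.null(model$sen) && sum(sen_mask) > 0) {
    zs <- fr$out[sen_mask, , drop = FALSE]
    brs <- nn_forward(model$sen, zs, training)
    model$sen <- brs$layers
    hss <- nn_forward(model$sen_score, brs$out, training)
    model$sen_score <- hss$layers
    out$sen <- list(branch = brs, score = hss, pred = drop(hss$out))
    if (!is.null(model$sen_class)) {
      hsc <- nn_forward(model$sen_class, brs$out, training)
      model$sen_class <- hsc$layers
      out$sen$class <- hsc
      out$sen$prob <- softmax_rows(hsc$out)
    }
  }
  out$model <- model
  out
}

# Loss on an annotated, already order-expanded sample table, in eval mode.
eval_total_loss <- function(model, samples, drug_codes, cell_codes,
                            held_out_drug_fold = NA, chunk = 4096) {
  comp <- c(mse_syn = 0, mse_sen = 0, bce_syn = 0, bce_sen = 0)
  n_syn <- 0; n_sen <- 0
  for (start in seq(1, nrow(samples), by = chunk)) {
    b <- samples[start:min(start + chunk - 1, nrow(samples)), ]
    xr <- cbind(drug_codes[b$drug_row, , drop = FALSE], cell_codes[b$cell_id, , drop = FALSE])
    xc <- cbind(drug_codes[b$drug_col, , drop = FALSE], cell_codes[b$cell_id, , drop = FALSE])
    mask <- !is.na(b$ri_score) &
      (is.na(held_out_drug_fold) | is.na(b$drug_fold) | b$drug_fold != held_out_drug_fold)
    fw <- predictor_batch_forward(model, xr, xc, mask, training = FALSE)
    nb <- nrow(b)
    if (!is.null(fw$syn)) {
      comp["mse_syn"] <- comp["mse_syn"] + sum((fw$syn$pred - b$loewe_score)^2)
      if (!is.null(fw$syn$prob)) {
        p <- clamp(fw$syn$prob[, 2], 1e-7, 1 - 1e-7)
        comp["bce_syn"] <- comp["bce_syn"] -
          sum(b$syn_label * log(p) + (1 - b$syn_label) * log(1 - p))
      }
      n_syn <- n_syn + nb
    }
    if (!is.null(fw$sen)) {
      ys <- b$ri_score[mask]; ls <- b$sen_label[mask]
      comp["mse_sen"] <- comp["mse_sen"] + sum((fw$sen$pred - ys)^2)
      if (!is.null(fw$sen$prob)) {
        p <- clamp(fw$sen$prob[, 2], 1e-7, 1 - 1e-7)
        comp["bce_sen"] <- comp["bce_sen"] - sum(ls * log(p) + (1 - ls) * log(1 - p))
      }
      n_sen <- n_sen + sum(mask)
    }
  }
  if (n_syn > 0) comp[c("mse_syn", "bce_syn")] <- comp[c("mse_syn", "bce_syn")] / n_syn
  if (n_sen > 0) comp[c("mse_sen", "bce_sen")] <- comp[c("mse_sen", "bce_sen")] / n_sen
  c(comp, total = sum(comp))
}

#' Train the multi-task predictor
#'
#' Duplicates every synergy sample into both drug orderings, then iterates
#' mini-batches: synergy losses are computed on all rows; sensitivity losses
#' on the rows that carry a sensitivity target and survive the leakage filter
#' for `held_out_drug_fold`. The four-term total loss is minimized with Adam.
#' Early stopping monitors the total validation loss with the given patience
#' and epoch cap, and the parameters with the lowest validation loss are
#' returned together with the full loss history.
#'
#' @param train,val Annotated synergy tables (see [cross_validate()]); must be
#'   disjoint at the combination level.
#' @param sensitivity Sensitivity table `drug_id`, `cell_id`, `ri_score`.
#' @param drug_codes,cell_codes Encoded (or raw, for the no-autoencoder
#'   variant) feature matrices with entity ids as row names.
#' @param spec A [predictor_spec()].
#' @param plan A `cv_plan` carrying the drug folds (may be `NULL` when no
#'   leakage control is wanted).
#' @param held_out_drug_fold Sensitivity fold excluded from training batches.
#' @param opts [training_opts()].
#' @param synergy_threshold,sensitivity_threshold Label boundaries (30 / 50).
#' @return An `mtl_fit`: `model` (best `mtl_predictor`), `history` tibble,
#'   `best_epoch`, `best_val_loss`, `spec`, `held_out_drug_fold`.
#' @export
train_model <- function(train, val, sensitivity, drug_codes, cell_codes,
                        spec = predictor_spec(), plan = NULL,
                        held_out_drug_fold = NA, opts = training_opts(),
                        synergy_threshold = 30, sensitivity_threshold = 50) {
  plan <- plan %||% new_cv_plan()
  tr <- expand_orders(annotate_samples(train, sensitivity, plan,
                                       synergy_threshold, sensitivity_threshold))
  vl <- expand_orders(annotate_samples(val, sensitivity, plan,
                                       synergy_threshold, sensitivity_threshold))
  model <- build_predictor(spec, ncol(drug_codes) + ncol(cell_codes))
  # start the regression heads at the training-target means: Adam's step size
  # is tiny relative to the raw Loewe/RI scales, so a zero-initialized bias
  # would dominate the early loss for hundreds of epochs
  if (!is.null(model$syn_score)) {
    model$syn_score[[1]]$b <- mean(tr$loewe_score)
  }
  if (!is.null(model$sen_score) && any(!is.na(tr$ri_score))) {
    model$sen_score[[1]]$b <- mean(tr$ri_score, na.rm = TRUE)
  }
  opt_states <- lapply(model[nn_part_names(model)], adam_init)
  best <- list(loss = Inf, epoch = 0L, model = model)
  hist <- vector("list", opts$max_epochs)
  for (epoch in seq_len(opts$max_epochs)) {
    set.seed(derive_seed(opts$seed, paste0("epoch_", epoch)))
    perm <- sample.int(nrow(tr))
    train_total <- 0; n_batches <- 0
    for (start in seq(1, length(perm), by = opts$batch_size)) {
      idx <- perm[start:min(start + opts$batch_size - 1, length(perm))]
      b <- tr[idx, ]
      step <- predictor_train_step(model, opt_states, b, drug_codes, cell_codes,
                                   held_out_drug_fold, spec$learning_rate)
      model <- step$model; opt_states <- step$opt_states
      if (!is.finite(step$loss)) abort(sprintf("non-finite loss at epoch %d", epoch))
      train_total <- train_total + step$loss; n_batches <- n_batches + 1
    }
    vloss <- eval_total_loss(model, vl, drug_codes, cell_codes,
                             held_out_drug_fold, opts$eval_chunk)
    hist[[epoch]] <- tibble::tibble(
      epoch = epoch, train_total = train_total / n_batches,
      val_total = vloss[["total"]],
      val_mse_syn = vloss[["mse_syn"]], val_mse_sen = vloss[["mse_sen"]],
      val_bce_syn = vloss[["bce_syn"]], val_bce_sen = vloss[["bce_sen"]]
    )
    if (opts$verbose) {
      message(sprintf("epoch %3d train %.3f val %.3f", epoch,
                      train_total / n_batches, vloss[["total"]]))
    }
    if (vloss[["total"]] < best$loss) {
      best <- list(loss = vloss[["total"]], epoch = epoch, model = model)
    }
    if (epoch - best$epoch >= max(1L, opts$patience)) break
  }
  structure(
    list(model = best$model, history = dplyr::bind_rows(hist),
         best_epoch = best$epoch, best_val_loss = best$loss, spec = spec,
         held_out_drug_fold = held_out_drug_fold, opts = opts),
    class = "mtl_fit"
  )
}

nn_part_names <- function(model) {
  intersect(c("trunk", "syn", "syn_score", "syn_class", "sen", "sen_score", "sen_class"),
            names(model))
}

predictor_train_step <- function(model, opt_states, b, drug_codes, cell_codes,
                                 held_out_drug_fold, lr) {
  xr <- cbind(drug_codes[b$drug_row, , drop = FALSE], cell_codes[b$cell_id, , drop = FALSE])
  xc <- cbind(drug_codes[b$drug_col, , drop = FALSE], cell_codes[b$cell_id, , drop = FALSE])
  mask <- !is.na(b$ri_score) &
    (is.na(held_out_drug_fold) | is.na(b$drug_fold) | b$drug_fold != held_out_drug_fold)
  fw <- predictor_batch_forward(model, xr, xc, mask, training = TRUE)
  model <- fw$model
  nb <- nrow(b)
  loss <- 0
  d_repI <- matrix(0, nb, model$shared_out)
  d_repII <- matrix(0, nb, model$shared_out)
  grads <- list()
  if (!is.null(fw$syn)) {
    resid <- fw$syn$pred - b$loewe_score
    loss <- loss + mean(resid^2)
    gs <- nn_backward(model$syn_score, fw$syn$score$caches,
                      matrix(2 * resid / nb, ncol = 1))
    grads$syn_score <- gs$grads
    d_branch_out <- gs$dx
    if (!is.null(fw$syn$prob)) {
      pm <- fw$syn$prob
      y1 <- b$syn_label
      p1 <- clamp(pm[, 2], 1e-7, 1 - 1e-7)
      loss <- loss - mean(y1 * log(p1) + (1 - y1) * log(1 - p1))
      dlogits <- (pm - cbind(1 - y1, y1)) / nb
      gc_ <- nn_backward(model$syn_class, fw$syn$class$caches, dlogits)
      grads$syn_class <- gc_$grads
      d_branch_out <- d_branch_out + gc_$dx
    }
    gb <- nn_backward(model$syn, fw$syn$branch$caches, d_branch_out)
    grads$syn <- gb$grads
    d_repI <- d_repI + gb$dx[, seq_len(model$shared_out), drop = FALSE]
    d_repII <- d_repII + gb$dx[, model$shared_out + seq_len(model$shared_out), drop = FALSE]
  }
  if (!is.null(fw$sen)) {
    nm <- sum(mask)
    ys <- b$ri_score[mask]
    resid <- fw$sen$pred - ys
    loss <- loss + mean(resid^2)
    gss <- nn_backward(model$sen_score, fw$sen$score$caches,
                       matrix(2 * resid / nm, ncol = 1))
    grads$sen_score <- gss$grads
    d_sbranch <- gss$dx
    if (!is.null(fw$sen$prob)) {
      pm <- fw$sen$prob
      y1 <- b$sen_label[mask]
      p1 <- clamp(pm[, 2], 1e-7, 1 - 1e-7)
      loss <- loss - mean(y1 * log(p1) + (1 - y1) * log(1 - p1))
      dlogits <- (pm - cbind(1 - y1, y1)) / nm
      gsc <- nn_backward(model$sen_class, fw$sen$class$caches, dlogits)
      grads$sen_class <- gsc$grads
      d_sbranch <- d_sbranch + gsc$dx
    }
    gbs <- nn_backward(model$sen, fw$sen$branch$caches, d_sbranch)
    grads$sen <- gbs$grads
    d_repI[mask, ] <- d_repI[mask, , drop = FALSE] + gbs$dx
  }
  gr <- nn_backward(model$trunk, fw$fr$caches, d_repI)
  gcc <- nn_backward(model$trunk, fw$fc$caches, d_repII)
  grads$trunk <- nn_add_grads(gr$grads, gcc$grads)
  for (part in names(grads)) {
    if (is.null(grads[[part]])) next
    u <- adam_step(model[[part]], grads[[part]], opt_states[[part]], lr)
    model[[part]] <- u$layers
    opt_states[[part]] <- u$state
  }
  list(model = model, opt_states = opt_states, loss = loss)
}

#' Grid search over shared-layer size and learning rate
#'
#' Trains one model per grid cell on the given train/validation split and
#' returns the specification with the lowest validation total loss. Ties are
#' broken toward the lower learning rate, then the smaller first layer.
#'
#' @param train,val Synergy tables for the split.
#' @param sensitivity Sensitivity table.
#' @param drug_codes,cell_codes Encoded feature matrices.
#' @param base_spec Spec supplying everything the grid does not vary.
#' @param layer_sizes First-layer sizes (default {2048, 4096, 8192}).
#' @param learning_rates Learning rates (default {5e-4, 1e-4, 5e-5}).
#' @param plan,held_out_drug_fold,opts Passed through to [train_model()].
#' @return A `grid_search_result`: `best_spec` and the full `results` tibble
#'   (`layer_size`, `learning_rate`, `val_loss`, `best_epoch`).
#' @export
grid_search <- function(train, val, sensitivity, drug_codes, cell_codes,
                        base_spec = predictor_spec(),
                        layer_sizes = c(2048, 4096, 8192),
                        learning_rates = c(5e-4, 1e-4, 5e-5),
                        plan = NULL, held_out_drug_fold = NA,
                        opts = training_opts()) {
  cells <- expand.grid(layer_size = sort(layer_sizes),
                       learning_rate = sort(learning_rates))
  fits <- purrr::pmap(cells, function(layer_size, learning_rate) {
    spec <- base_spec
    spec$shared_layer_sizes <- as.integer(c(layer_size, max(1, layer_size %/% 2)))
    spec$learning_rate <- learning_rate
    fit <- train_model(train, val, sensitivity, drug_codes, cell_codes, spec,
                       plan, held_out_drug_fold, opts)
    tibble::tibble(layer_size = layer_size, learning_rate = learning_rate,
                   val_loss = fit$best_val_loss, best_epoch = fit$best_epoch)
  })
  results <- dplyr::bind_rows(fits)
  best_row <- results |>
    dplyr::arrange(.data$val_loss, .data$learning_rate, .data$layer_size) |>
    dplyr::slice(1)
  best_spec <- base_spec
  best_spec$shared_layer_sizes <- as.integer(c(best_row$layer_size,
                                               max(1, best_row$layer_size %/% 2)))
  best_spec$learning_rate <- best_row$learning_rate
  structure(list(best_spec = best_spec, results = results),
            class = "grid_search_result")
}

predict_synergy_batch <- function(model, samples, drug_codes, cell_codes,
                                  chunk = 4096) {
  out_score <- numeric(nrow(samples))
  out_prob <- rep(NA_real_, nrow(samples))
  for (start in seq(1, nrow(samples), by = chunk)) {
    ii <- start:min(start + chunk - 1, nrow(samples))
    b <- samples[ii, ]
    zc <- cell_codes[b$cell_id, , drop = FALSE]
    repA <- shared_forward(model, drug_codes[b$drug_row, , drop = FALSE], zc)
    repB <- shared_forward(model, drug_codes[b$drug_col, , drop = FALSE], zc)
    f1 <- synergy_forward(model, repA, repB)
    f2 <- synergy_forward(model, repB, repA)
    out_score[ii] <- (f1$score + f2$score) / 2
    if (!is.null(f1$prob)) out_prob[ii] <- (f1$prob[, 2] + f2$prob[, 2]) / 2
  }
  tibble::tibble(pred_score = out_score, pred_prob = out_prob)
}

predict_sensitivity_batch <- function(model, samples, drug_codes, cell_codes,
                                      chunk = 4096) {
  out_score <- numeric(nrow(samples))
  out_prob <- rep(NA_real_, nrow(samples))
  for (start in seq(1, nrow(samples), by = chunk)) {
    ii <- start:min(start + chunk - 1, nrow(samples))
    b <- samples[ii, ]
    repI <- shared_forward(model, drug_codes[b$drug_id, , drop = FALSE],
                           cell_codes[b$cell_id, , drop = FALSE])
    f <- sensitivity_forward(model, repI)
    out_score[ii] <- f$score
    if (!is.null(f$prob)) out_prob[ii] <- f$prob[, 2]
  }
  tibble::tibble(pred_score = out_score, pred_prob = out_prob)
}

#' Dual five-fold cross-validation of the multi-task predictor
#'
#' For each fold `f`: one of the remaining folds (rotating with `f`, offset
#' derived from the seed) is carved out as the validation set for early
#' stopping, the rest train the model with sensitivity leakage control for
#' drug fold `f`; synergy is then predicted for every fold-`f`
#' sample (both orders averaged), and sensitivity only for test-set
#' (drug_row, cell) pairs whose drug belongs to drug fold `f` — drugs whose
#' sensitivity entered training for that round are never scored.
#'
#' @param synergy Synergy table (`drug_row`, `drug_col`, `cell_id`,
#'   `loewe_score`), replicates already averaged.
#' @param sensitivity Sensitivity table (`drug_id`, `cell_id`, `ri_score`).
#' @param drug_codes,cell_codes Feature matrices fed to the trunk (encoded
#'   codes, or raw features for the no-autoencoder variant).
#' @param plan A complete `cv_plan`; `NULL` builds one from `seed`.
#' @param spec A [predictor_spec()] (its `variant` selects ablations).
#' @param opts [training_opts()].
#' @param seed Seed for plan construction and the validation-fold rotation.
#' @param synergy_threshold,sensitivity_threshold Label boundaries.
#' @return An `mtl_cv`: `synergy_predictions`, `sensitivity_predictions`,
#'   `fold_metrics`, `summary`, `plan`, `spec`, `histories`.
#' @export
cross_validate <- function(synergy, sensitivity, drug_codes, cell_codes,
                           plan = NULL, spec = predictor_spec(),
                           opts = training_opts(), seed = 1,
                           synergy_threshold = 30, sensitivity_threshold = 50) {
  plan <- plan %||% build_cv_plan(synergy, rownames(drug_codes),
                                  seed = seed)
  n_folds <- plan$n_folds
  synergy <- dplyr::mutate(synergy,
                           combo_fold = combo_fold_of(plan, .data$drug_row, .data$drug_col))
  rot <- 1L + (abs(seed) %% (n_folds - 1L))
  syn_pred <- list(); sen_pred <- list(); fold_metrics <- list(); histories <- list()
  for (f in 0:(n_folds - 1L)) {
    vf <- (f + rot) %% n_folds
    test <- synergy[synergy$combo_fold == f, ]
    val <- synergy[synergy$combo_fold == vf, ]
    train <- synergy[!synergy$combo_fold %in% c(f, vf), ]
    fit <- train_model(train, val, sensitivity, drug_codes, cell_codes, spec,
                       plan, held_out_drug_fold = f, opts = opts,
                       synergy_threshold = synergy_threshold,
                       sensitivity_threshold = sensitivity_threshold)
    histories[[f + 1L]] <- dplyr::mutate(fit$history, fold = f)
    fm <- tibble::tibble(fold = f)
    if (!is.null(fit$model$syn)) {
      p <- predict_synergy_batch(fit$model, test, drug_codes, cell_codes, opts$eval_chunk)
      syn_pred[[f + 1L]] <- dplyr::bind_cols(
        dplyr::mutate(test, fold = f,
                      label = label_synergy(.data$loewe_score, synergy_threshold)), p)
      rm_ <- regression_metrics(test$loewe_score, p$pred_score)
      fm <- dplyr::bind_cols(fm, dplyr::rename_with(rm_[, c("mse", "rmse", "pcc")],
                                                    ~ paste0("syn_", .x)))
      if (!all(is.na(p$pred_prob))) {
        cm <- classification_metrics(label_synergy(test$loewe_score, synergy_threshold),
                                     p$pred_prob)
        fm <- dplyr::bind_cols(fm, dplyr::rename_with(cm[, c("roc_auc", "pr_auc", "acc")],
                                                      ~ paste0("syn_", .x)))
      }
    }
    if (!is.null(fit$model$sen)) {
      held_drugs <- plan$drug_folds$drug_id[plan$drug_folds$fold == f]
      # test rows run in both orders, so each drug of a pair takes the
      # drug_row position once; collect (drug, cell) pairs from both columns
      test_pairs <- dplyr::distinct(dplyr::bind_rows(
        dplyr::select(test, drug_id = "drug_row", "cell_id"),
        dplyr::select(test, drug_id = "drug_col", "cell_id")
      ))
      stest <- sensitivity |>
        dplyr::filter(.data$drug_id %in% held_drugs) |>
        dplyr::semi_join(test_pairs, by = c("drug_id", "cell_id"))
      if (nrow(stest) >= 2) {
        ps <- predict_sensitivity_batch(fit$model, stest, drug_codes, cell_codes,
                                        opts$eval_chunk)
        sen_pred[[f + 1L]] <- dplyr::bind_cols(
          dplyr::mutate(stest, fold = f,
                        label = label_sensitivity(.data$ri_score, sensitivity_threshold)), ps)
        rms <- regression_metrics(stest$ri_score, ps$pred_score)
        fm <- dplyr::bind_cols(fm, dplyr::rename_with(rms[, c("mse", "rmse", "pcc")],
                                                      ~ paste0("sen_", .x)))
        if (!all(is.na(ps$pred_prob))) {
          cms <- classification_metrics(
            label_sensitivity(stest$ri_score, sensitivity_threshold), ps$pred_prob)
          fm <- dplyr::bind_cols(fm, dplyr::rename_with(cms[, c("roc_auc", "pr_auc", "acc")],
                                                        ~ paste0("sen_", .x)))
        }
      }
    }
    fold_metrics[[f + 1L]] <- fm
  }
  fold_metrics <- dplyr::bind_rows(fold_metrics)
  metric_cols <- setdiff(names(fold_metrics), "fold")
  summary <- fold_metrics |>
    tidyr::pivot_longer(dplyr::all_of(metric_cols), names_to = "metric") |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     sd = stats::sd(.data$value, na.rm = TRUE), .by = "metric")
  structure(
    list(synergy_predictions = dplyr::bind_rows(syn_pred),
         sensitivity_predictions = dplyr::bind_rows(sen_pred),
         fold_metrics = fold_metrics, summary = summary,
         plan = plan, spec = spec, histories = dplyr::bind_rows(histories)),
    class = "mtl_cv"
  )
}

#' @export
print.mtl_cv <- function(x, ...) {
  cat(sprintf("<mtl_cv> %d folds, %d synergy predictions, %d sensitivity predictions\n",
              x$plan$n_folds, nrow(x$synergy_predictions),
              nrow(x$sensitivity_predictions %||% tibble::tibble())))
  print(x$summary, n = Inf)
  invisible(x)
}
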