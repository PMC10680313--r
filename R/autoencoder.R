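#' Autoencoder architecture specification
#'
#' Two fully connected encoder layers (ReLU and dropout between them, linear
#' code) compress the input to a `code_dim`-dimensional representation; two
#' decoder layers (ReLU between, linear output, no dropout) reconstruct it. The
#' default hidden width is the geometric mean of `input_dim` and `code_dim`
#' rounded to a power of two.
#'
#' @param input_dim Width of the feature vectors.
#' @param code_dim Encoder output width (128 for drugs and 256 for cell lines
#'   in the default configuration).
#' @param hidden_dim Width of the intermediate layer; `NULL` for the default.
#' @param dropout_rate Dropout probability in the encoder (default 0.2).
#' @param seed Seed for parameter initialization.
#' @return An `autoencoder_spec` list.
#' @export
autoencoder_spec <- function(input_dim, code_dim, hidden_dim = NULL,
                             dropout_rate = 0.2, seed = 1) {
  stopifnot(input_dim >= 2, code_dim >= 1)
  if (code_dim >= input_dim) abort("code_dim must be smaller than input_dim")
  if (dropout_rate < 0 || dropout_rate >= 1) abort("dropout_rate must be in [0, 1)")
  if (is.null(hidden_dim)) {
    hidden_dim <- 2^round(log2(sqrt(input_dim * code_dim)))
  }
  structure(
    list(input_dim = as.integer(input_dim), hidden_dim = as.integer(hidden_dim),
         code_dim = as.integer(code_dim), dropout_rate = dropout_rate,
         seed = as.integer(seed)),
    class = "autoencoder_spec"
  )
}

#' Reconstruction loss of an autoencoder
#'
#' The per-sample sum of squared differences between input and reconstruction,
#' averaged over the `n` samples (rows): `sum_i ||x_i - xhat_i||^2 / n`.
#'
#' @param x,x_hat Numeric matrices of identical shape, samples in rows.
#' @return A single number.
#' @examples
#' reconstruction_loss(matrix(2), matrix(0))  # 4
#' @export
reconstruction_loss <- function(x, x_hat) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (!is.matrix(x_hat)) x_hat <- as.matrix(x_hat)
  if (!all(dim(x) == dim(x_hat))) abort("x and x_hat must have identical shapes")
  sum((x - x_hat)^2) / nrow(x)
}

#' Autoencoder pretraining options
#'
#' @param batch_size Mini-batch size (default 64).
#' @param max_epochs Epoch cap (default 300).
#' @param patience Early-stopping patience on the monitored reconstruction
#'   loss (default 100).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param val_fraction Fraction of rows held out to monitor reconstruction
#'   (default 0.1; training rows are monitored when too few).
#' @param seed Seed driving the split, batching and dropout.
#' @return A list of options.
#' @export
ae_training_opts <- function(batch_size = 64, max_epochs = 300, patience = 100,
                             learning_rate = 1e-3, val_fraction = 0.1, seed = 1) {
  list(batch_size = batch_size, max_epochs = max_epochs, patience = patience,
       learning_rate = learning_rate, val_fraction = val_fraction, seed = seed)
}

build_ae_layers <- function(spec) {
  # ReLU sits between the FC layers of each half; the code layer itself is
  # linear (as in PCA-style autoencoders), so signed low-dimensional
  # structure survives the bottleneck
  enc <- list(
    nn_dense(spec$input_dim, spec$hidden_dim), nn_relu(), nn_dropout(spec$dropout_rate),
    nn_dense(spec$hidden_dim, spec$code_dim)
  )
  dec <- list(
    nn_dense(spec$code_dim, spec$hidden_dim), nn_relu(),
    nn_dense(spec$hidden_dim, spec$input_dim)
  )
  list(enc = enc, dec = dec)
}

#' Pre-train an autoencoder on a feature matrix
#'
#' Minimizes the reconstruction loss with Adam and mini-batches, monitoring a
#' held-out fraction of rows; the parameters with the lowest monitored loss
#' are kept (early stopping). Fully deterministic under `opts$seed`.
#'
#' @param features Numeric matrix, samples x features (finite values).
#' @param spec An [autoencoder_spec()].
#' @param opts Options from `ae_training_opts()`.
#' @return A `trained_autoencoder`: `spec`, `encoder`, `decoder` (parameter
#'   lists), `history` tibble (epoch, train_loss, val_loss), `best_epoch`.
#' @export
pretrain_autoencoder <- function(features, spec, opts = ae_training_opts()) {
  stopifnot(inherits(spec, "autoencoder_spec"), is.matrix(features))
  if (nrow(features) < 2) abort("need at least 2 rows to pretrain")
  if (any(!is.finite(features))) abort("non-finite values in features")
  if (ncol(features) != spec$input_dim) {
    abort(sprintf("feature width %d does not match spec input_dim %d",
                  ncol(features), spec$input_dim))
  }
  set.seed(derive_seed(spec$seed, "ae_init"))
  nets <- build_ae_layers(spec)
  st_enc <- adam_init(nets$enc)
  st_dec <- adam_init(nets$dec)

  set.seed(derive_seed(opts$seed, "ae_split"))
  n <- nrow(features)
  n_val <- floor(opts$val_fraction * n)
  val_idx <- if (n_val >= 1) sample.int(n, n_val) else integer(0)
  tr_idx <- setdiff(seq_len(n), val_idx)
  monitor_idx <- if (length(val_idx) >= 2) val_idx else tr_idx

  best <- list(loss = Inf, epoch = 0L, enc = nets$enc, dec = nets$dec)
  hist <- vector("list", opts$max_epochs)
  for (epoch in seq_len(opts$max_epochs)) {
    set.seed(derive_seed(opts$seed, paste0("ae_epoch_", epoch)))
    perm <- sample(tr_idx)
    tr_loss_num <- 0
    for (start in seq(1, length(perm), by = opts$batch_size)) {
      idx <- perm[start:min(start + opts$batch_size - 1, length(perm))]
      xb <- features[idx, , drop = FALSE]
      fe <- nn_forward(nets$enc, xb, training = TRUE)
      fd <- nn_forward(nets$dec, fe$out, training = TRUE)
      nets$enc <- fe$layers
      nets$dec <- fd$layers
      resid <- fd$out - xb
      tr_loss_num <- tr_loss_num + sum(resid^2)
      dout <- 2 * resid / nrow(xb)
      bd <- nn_backward(nets$dec, fd$caches, dout)
      be <- nn_backward(nets$enc, fe$caches, bd$dx)
      if (!all(is.finite(dout))) abort("non-finite reconstruction loss; aborting")
      ud <- adam_step(nets$dec, bd$grads, st_dec, opts$learning_rate)
      nets$dec <- ud$layers; st_dec <- ud$state
      ue <- adam_step(nets$enc, be$grads, st_enc, opts$learning_rate)
      nets$enc <- ue$layers; st_enc <- ue$state
    }
    mon <- features[monitor_idx, , drop = FALSE]
    recon <- nn_forward(nets$dec, nn_forward(nets$enc, mon, FALSE)$out, FALSE)$out
    val_loss <- reconstruction_loss(mon, recon)
    hist[[epoch]] <- tibble::tibble(
      epoch = epoch,
      train_loss = tr_loss_num / length(tr_idx),
      val_loss = val_loss
    )
    if (val_loss < best$loss) {
      best <- list(loss = val_loss, epoch = epoch, enc = nets$enc, dec = nets$dec)
    }
    if (epoch - best$epoch >= max(1L, opts$patience)) break
  }
  structure(
    list(spec = spec, encoder = best$enc, decoder = best$dec,
         history = dplyr::bind_rows(hist), best_epoch = best$epoch,
         best_loss = best$loss),
    class = "trained_autoencoder"
  )
}

#' Encode features with a trained autoencoder
#'
#' Runs the encoder half in inference mode (dropout disabled); the output has
#' `spec$code_dim` columns and preserves row names.
#'
#' @param model A `trained_autoencoder`.
#' @param features Numeric matrix whose width equals `spec$input_dim`.
#' @return Numeric matrix, samples x code_dim.
#' @export
encode <- function(model, features) {
  stopifnot(inherits(model, "trained_autoencoder"))
  if (!is.matrix(features)) features <- matrix(features, nrow = 1)
  if (ncol(features) != model$spec$input_dim) {
    abort(sprintf("feature width %d does not match encoder input_dim %d",
                  ncol(features), model$spec$input_dim))
  }
  out <- nn_forward(model$encoder, features, training = FALSE)$out
  rownames(out) <- rownames(features)
  out
}

#' Reconstruct features with a trained autoencoder
#' @param model A `trained_autoencoder`.
#' @param features Numeric matrix whose width equals `spec$input_dim`.
#' @return Reconstructed matrix of the same shape.
#' @export
reconstruct <- function(model, features) {
  nn_forward(model$decoder, encode(model, features), training = FALSE)$out
}

#' @export
print.trained_autoencoder <- function(x, ...) {
  cat(sprintf("<trained_autoencoder> %d -> %d -> %d, best val loss %.4g (epoch %d)\n",
              x$spec$input_dim, x$spec$hidden_dim, x$spec$code_dim,
              x$best_loss, x$best_epoch))
  invisible(x)
}
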