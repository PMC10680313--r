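#' Multi-task predictor architecture specification
#'
#' The predictor is a shared trunk of two fully connected layers (each with
#' batch normalization and ReLU) applied to the concatenation of one encoded
#' drug and one encoded cell line, followed by two task branches. The synergy
#' branch consumes the concatenated representations of both drug orderings;
#' the sensitivity branch consumes the first representation only. Each branch
#' is a stack of FC+ReLU+dropout layers topped by a linear regression head and
#' a 2-unit softmax classification head.
#'
#' @param shared_layer_sizes Two integers, the trunk layer widths. The default
#'   grid explores first-layer sizes {2048, 4096, 8192}; the second layer
#'   defaults to half the first.
#' @param synergy_branch_sizes,sensitivity_branch_sizes Hidden widths of the
#'   branches; `NULL` derives `[w, w/2, w/4]` from each branch's input width.
#' @param dropout_rate Dropout in the branches (default 0.5; the trunk has
#'   batch normalization instead of dropout).
#' @param learning_rate Adam learning rate (default grid
#'   {0.0005, 0.0001, 0.00005}).
#' @param seed Seed for parameter initialization.
#' @param variant One of `"full"`, `"only-synergy"`, `"only-sensitivity"`,
#'   `"regression-only"` (ablation variants; `"no-ae"` is selected at training
#'   time by feeding raw features and is architecturally `"full"`).
#' @return A `predictor_spec` list.
#' @export
predictor_spec <- function(shared_layer_sizes = c(2048, 1024),
                           synergy_branch_sizes = NULL,
                           sensitivity_branch_sizes = NULL,
                           dropout_rate = 0.5, learning_rate = 5e-4,
                           seed = 1, variant = "full") {
  if (length(shared_layer_sizes) == 1) {
    shared_layer_sizes <- c(shared_layer_sizes, max(1, shared_layer_sizes %/% 2))
  }
  stopifnot(length(shared_layer_sizes) == 2, all(shared_layer_sizes >= 1))
  if (learning_rate <= 0) abort("learning_rate must be > 0")
  if (dropout_rate < 0 || dropout_rate >= 1) abort("dropout_rate must be in [0, 1)")
  variant %one_of% c("full", "only-synergy", "only-sensitivity", "regression-only")
  structure(
    list(shared_layer_sizes = as.integer(shared_layer_sizes),
         synergy_branch_sizes = synergy_branch_sizes,
         sensitivity_branch_sizes = sensitivity_branch_sizes,
         dropout_rate = dropout_rate, learning_rate = learning_rate,
         seed = as.integer(seed), variant = variant),
    class = "predictor_spec"
  )
}

default_branch_sizes <- function(input_width) {
  unique(pmax(1L, c(input_width, input_width %/% 2L, input_width %/% 4L)))
}

branch_layers <- function(n_in, sizes, dropout_rate) {
  layers <- list()
  prev <- n_in
  for (s in sizes) {
    layers <- c(layers, list(nn_dense(prev, s), nn_relu(), nn_dropout(dropout_rate)))
    prev <- s
  }
  list(layers = layers, out_width = prev)
}

#' Build an untrained multi-task predictor
#'
#' @param spec A [predictor_spec()].
#' @param input_dim Width of the concatenated drug and cell-line codes fed to
#'   the shared trunk.
#' @return An `mtl_predictor` with randomly initialized parameters.
#' @export
build_predictor <- function(spec, input_dim) {
  stopifnot(inherits(spec, "predictor_spec"), input_dim >= 2)
  set.seed(derive_seed(spec$seed, "predictor_init"))
  s1 <- spec$shared_layer_sizes[1]
  s2 <- spec$shared_layer_sizes[2]
  trunk <- list(nn_dense(input_dim, s1), nn_bn(s1), nn_relu(),
                nn_dense(s1, s2), nn_bn(s2), nn_relu())
  model <- list(trunk = trunk, spec = spec, input_dim = as.integer(input_dim),
                shared_out = as.integer(s2), variant = spec$variant)
  with_class <- !identical(spec$variant, "regression-only")
  if (spec$variant != "only-sensitivity") {
    sizes <- spec$synergy_branch_sizes %||% default_branch_sizes(2L * s2)
    br <- branch_layers(2L * s2, sizes, spec$dropout_rate)
    model$syn <- br$layers
    model$syn_score <- list(nn_dense(br$out_width, 1L))
    if (with_class) model$syn_class <- list(nn_dense(br$out_width, 2L))
  }
  if (spec$variant != "only-synergy") {
    sizes <- spec$sensitivity_branch_sizes %||% default_branch_sizes(s2)
    br <- branch_layers(s2, sizes, spec$dropout_rate)
    model$sen <- br$layers
    model$sen_score <- list(nn_dense(br$out_width, 1L))
    if (with_class) model$sen_class <- list(nn_dense(br$out_width, 2L))
  }
  structure(model, class = "mtl_predictor")
}

as_code_matrix <- function(x, what) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (!is.matrix(x)) abort(sprintf("%s must be a numeric vector or matrix", what))
  x
}

#' Shared-trunk forward pass
#'
#' Produces the shared representation of one drug--cell line pair from the
#' encoded drug and cell-line vectors (or row-aligned matrices). Inference
#' mode: batch normalization uses running statistics and dropout is off, so a
#' row's output does not depend on the rest of the batch.
#'
#' @param model An `mtl_predictor`.
#' @param drug_code,cell_code Encoded feature vectors or matrices.
#' @return Matrix of shared representations (rows align with inputs).
#' @export
shared_forward <- function(model, drug_code, cell_code) {
  stopifnot(inherits(model, "mtl_predictor"))
  d <- as_code_matrix(drug_code, "drug_code")
  c_ <- as_code_matrix(cell_code, "cell_code")
  if (nrow(d) != nrow(c_)) abort("drug_code and cell_code must have matching rows")
  x <- cbind(d, c_)
  if (ncol(x) != model$input_dim) {
    abort(sprintf("input width %d does not match trunk input_dim %d",
                  ncol(x), model$input_dim))
  }
  nn_forward(model$trunk, x, training = FALSE)$out
}

head_forward <- function(model, branch, score_head, class_head, z) {
  br <- nn_forward(branch, z, training = FALSE)
  score <- unname(drop(nn_forward(score_head, br$out, training = FALSE)$out))
  prob <- if (!is.null(class_head)) {
    softmax_rows(nn_forward(class_head, br$out, training = FALSE)$out)
  } else {
    NULL
  }
  list(score = score, prob = prob)
}

#' Synergy-branch forward pass
#'
#' Concatenates the two shared representations (order-sensitive) and runs the
#' synergy branch, returning the regression score and the 2-class softmax
#' distribution (columns: negative, positive).
#'
#' @param model An `mtl_predictor`.
#' @param rep_I,rep_II Shared representations (vectors or row-aligned
#'   matrices) of the (drug_row, cell) and (drug_col, cell) pairs.
#' @return List with `score` (numeric vector) and `prob` (matrix with columns
#'   `negative`, `positive`; `NULL` for the regression-only variant).
#' @export
synergy_forward <- function(model, rep_I, rep_II) {
  stopifnot(inherits(model, "mtl_predictor"))
  if (is.null(model$syn)) abort(sprintf("variant '%s' has no synergy branch", model$variant))
  r1 <- as_code_matrix(rep_I, "rep_I"); r2 <- as_code_matrix(rep_II, "rep_II")
  if (ncol(r1) != ncol(r2)) abort("rep_I and rep_II widths differ")
  if (ncol(r1) != model$shared_out) abort("representation width does not match the trunk output")
  out <- head_forward(model, model$syn, model$syn_score, model$syn_class, cbind(r1, r2))
  if (!is.null(out$prob)) colnames(out$prob) <- c("negative", "positive")
  out
}

#' Sensitivity-branch forward pass
#'
#' Runs the monotherapy sensitivity branch on representation I alone; by
#' construction the output is independent of the paired drug.
#'
#' @param model An `mtl_predictor`.
#' @param rep_I Shared representation(s) of the (drug_row, cell) pair.
#' @return List with `score` and `prob` as in [synergy_forward()].
#' @export
sensitivity_forward <- function(model, rep_I) {
  stopifnot(inherits(model, "mtl_predictor"))
  if (is.null(model$sen)) abort(sprintf("variant '%s' has no sensitivity branch", model$variant))
  r1 <- as_code_matrix(rep_I, "rep_I")
  if (ncol(r1) != model$shared_out) abort("representation width does not match the trunk output")
  out <- head_forward(model, model$sen, model$sen_score, model$sen_class, r1)
  if (!is.null(out$prob)) colnames(out$prob) <- c("negative", "positive")
  out
}

#' @export
print.mtl_predictor <- function(x, ...) {
  cat(sprintf("<mtl_predictor> variant '%s': %d -> [%d, %d] trunk",
              x$variant, x$input_dim, x$spec$shared_layer_sizes[1], x$spec$shared_layer_sizes[2]))
  cat(sprintf("; branches: %s\n", paste(
    c(if (!is.null(x$syn)) "synergy", if (!is.null(x$sen)) "sensitivity"),
    collapse = " + "
  )))
  invisible(x)
}
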