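small_model <- function(variant = "full", seed = 3) {
  build_predictor(
    predictor_spec(shared_layer_sizes = c(8, 4), dropout_rate = 0.3,
                   learning_rate = 1e-3, seed = seed, variant = variant),
    input_dim = 6
  )
}

test_that("the shared trunk obeys its shape contract and stays finite", {
  m <- small_model()
  out <- shared_forward(m, matrix(rnorm(10 * 4), 10, 4), matrix(rnorm(10 * 2), 10, 2))
  expect_equal(dim(out), c(10, 4))  # second shared layer width
  z <- shared_forward(m, rep(0, 4), rep(0, 2))
  expect_true(all(is.finite(z)))
  expect_error(shared_forward(m, matrix(0, 2, 5), matrix(0, 2, 2)), "width")
  expect_error(shared_forward(m, matrix(0, 2, 4), matrix(0, 3, 2)), "rows")
})

test_that("inference is batch-independent row by row", {
  m <- small_model()
  d <- matrix(rnorm(12 * 4), 12, 4); c_ <- matrix(rnorm(12 * 2), 12, 2)
  batch <- shared_forward(m, d, c_)
  single <- shared_forward(m, d[5, ], c_[5, ])
  expect_equal(unname(batch[5, ]), unname(drop(single)), tolerance = 1e-12)
})

test_that("softmax heads emit normalized distributions", {
  m <- small_model()
  r1 <- matrix(rnorm(20 * 4, sd = 5), 20, 4)
  r2 <- matrix(rnorm(20 * 4, sd = 5), 20, 4)
  fs <- synergy_forward(m, r1, r2)
  expect_true(all(abs(rowSums(fs$prob) - 1) < 1e-6))
  expect_true(all(fs$prob >= 0 & fs$prob <= 1))
  fsen <- sensitivity_forward(m, r1)
  expect_true(all(abs(rowSums(fsen$prob) - 1) < 1e-6))
})

test_that("synergy branch is order-sensitive but the two-order mean is symmetric", {
  m <- small_model()
  r1 <- rnorm(4); r2 <- rnorm(4)
  a <- synergy_forward(m, r1, r2)
  b <- synergy_forward(m, r2, r1)
  expect_false(isTRUE(all.equal(a$score, b$score)))  # concatenation order matters
  expect_identical((a$score + b$score) / 2, (b$score + a$score) / 2)
})

test_that("the sensitivity branch depends only on representation I", {
  m <- small_model()
  r1 <- matrix(rnorm(4), 1)
  out1 <- sensitivity_forward(m, r1)
  out2 <- sensitivity_forward(m, r1)  # rep_II never enters the computation
  expect_identical(out1, out2)
})

test_that("eval-mode forward passes match an explicit-loop oracle", {
  m <- small_model()
  set.seed(21)
  # run a training batch first so batch-norm running stats are non-trivial
  xb1 <- matrix(rnorm(16 * 6), 16, 6); xb2 <- matrix(rnorm(16 * 6), 16, 6)
  fw <- mtsynergy:::predictor_batch_forward(m, xb1, xb2, rep(TRUE, 16), training = TRUE)
  m <- fw$model
  zd <- rnorm(4); zc <- rnorm(2)
  rep_I <- drop(shared_forward(m, zd, zc))
  expect_equal(rep_I, oracle_forward_eval(m$trunk, c(zd, zc)), tolerance = 1e-12)
  f <- synergy_forward(m, rep_I, rep_I)
  branch_out <- oracle_forward_eval(m$syn, c(rep_I, rep_I))
  expect_equal(unname(f$score), oracle_forward_eval(m$syn_score, branch_out),
               tolerance = 1e-12)
  expect_equal(unname(drop(f$prob)),
               oracle_softmax(oracle_forward_eval(m$syn_class, branch_out)),
               tolerance = 1e-12)
  s <- sensitivity_forward(m, rep_I)
  sbranch <- oracle_forward_eval(m$sen, rep_I)
  expect_equal(unname(s$score), oracle_forward_eval(m$sen_score, sbranch),
               tolerance = 1e-12)
})

test_that("ablation variants drop the excluded branches structurally", {
  expect_null(small_model("only-synergy")$sen)
  expect_null(small_model("only-sensitivity")$syn)
  reg <- small_model("regression-only")
  expect_null(reg$syn_class); expect_null(reg$sen_class)
  expect_error(sensitivity_forward(small_model("only-synergy"), rnorm(4)), "no sensitivity")
  expect_error(synergy_forward(small_model("only-sensitivity"), rnorm(4), rnorm(4)),
               "no synergy")
})

test_that("engine gradients match finite differences through all layer kinds", {
  set.seed(42)
  layers <- list(mtsynergy:::nn_dense(5, 4), mtsynergy:::nn_bn(4),
                 mtsynergy:::nn_relu(), mtsynergy:::nn_dense(4, 2))
  X <- matrix(rnorm(30), 6, 5); Y <- matrix(rnorm(12), 6, 2)
  f <- mtsynergy:::nn_forward(layers, X, training = TRUE)
  bk <- mtsynergy:::nn_backward(f$layers, f$caches, 2 * (f$out - Y))
  loss_of <- function(ls) {
    sum((mtsynergy:::nn_forward(ls, X, training = TRUE)$out - Y)^2)
  }
  eps <- 1e-6
  for (probe in list(c(1, "W", 2, 3), c(2, "gamma", 2, NA), c(4, "b", 1, NA))) {
    i <- as.integer(probe[1]); p <- probe[2]
    idx <- as.integer(probe[3]); jdx <- suppressWarnings(as.integer(probe[4]))
    bump <- function(ls, e) {
      if (is.na(jdx)) ls[[i]][[p]][idx] <- ls[[i]][[p]][idx] + e
      else ls[[i]][[p]][idx, jdx] <- ls[[i]][[p]][idx, jdx] + e
      ls
    }
    num <- (loss_of(bump(layers, eps)) - loss_of(bump(layers, -eps))) / (2 * eps)
    ana <- if (is.na(jdx)) bk$grads[[i]][[p]][idx] else bk$grads[[i]][[p]][idx, jdx]
    expect_equal(num, ana, tolerance = 1e-5)
  }
})

test_that("predict_pair averages both orders and is exactly drug-symmetric", {
  tf <- tiny_fit()
  model <- structure(
    list(predictor = tf$fit$model, drug_codes = tf$enc$drug_codes,
         cell_codes = tf$enc$cell_codes,
         thresholds = c(synergy = 30, sensitivity = 50)),
    class = "synergy_model"
  )
  p_ab <- predict_pair(model, "drug_01", "drug_02", "cell_01")
  p_ba <- predict_pair(model, "drug_02", "drug_01", "cell_01")
  expect_identical(p_ab$synergy_score, p_ba$synergy_score)
  expect_identical(p_ab$synergy_prob, p_ba$synergy_prob)
  # sensitivity is reported per drug: swapping swaps the per-drug outputs
  expect_identical(p_ab$sensitivity_score_a, p_ba$sensitivity_score_b)
  # self-combination equals the single-order output
  repA <- shared_forward(model$predictor, model$drug_codes["drug_01", ],
                         model$cell_codes["cell_01", ])
  single <- synergy_forward(model$predictor, repA, repA)
  p_aa <- predict_pair(model, "drug_01", "drug_01", "cell_01")
  expect_equal(p_aa$synergy_score, unname(single$score), tolerance = 1e-12)
  # composition oracle: mean of two explicit forward calls
  repB <- shared_forward(model$predictor, model$drug_codes["drug_02", ],
                         model$cell_codes["cell_01", ])
  f1 <- synergy_forward(model$predictor, repA, repB)
  f2 <- synergy_forward(model$predictor, repB, repA)
  expect_equal(p_ab$synergy_score, unname((f1$score + f2$score) / 2), tolerance = 1e-12)
  expect_error(predict_pair(model, "nope", "drug_02", "cell_01"), "unknown drug")
  expect_error(predict_pair(model, "drug_01", "drug_02", "nope"), "unknown cell")
})
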