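# Frozen with this package's featurizer (see featurizer_version()): the bit
# positions of ethanol's radius-3/1024-bit circular fingerprint.
ETHANOL_BITS <- c(24, 202, 262, 266, 308, 408, 527, 802, 840, 866, 905, 1014)

test_that("circular fingerprints are deterministic, frozen, and spelling-invariant", {
  fp <- compute_fingerprint("CCO")
  expect_length(fp, 1024)
  expect_true(all(fp %in% c(0L, 1L)))
  expect_identical(which(fp == 1L), as.integer(ETHANOL_BITS))
  expect_identical(fp, compute_fingerprint("CCO"))
  expect_identical(fp, compute_fingerprint("OCC"))
  # respellings of a branched molecule also collapse to one vector
  expect_identical(compute_fingerprint("CC(C)O"), compute_fingerprint("OC(C)C"))
  expect_gt(sum(compute_fingerprint("C")), 0)  # smallest valid input
})

test_that("unparseable SMILES raise a featurization error naming the drug", {
  expect_error(compute_fingerprint("not_a_molecule"), "unparseable")
  expect_error(compute_fingerprint("xx!!", drug_id = "drugX"), "drugX")
  expect_error(compute_descriptors("not_a_molecule"), "unparseable")
})

test_that("descriptor panel holds standard physicochemical values", {
  d <- compute_descriptors("CCO")
  expect_equal(unname(d[["MW"]]), 46.07, tolerance = 1e-3)  # C2H6O
  expect_true(all(is.finite(compute_descriptors("C"))))
})

test_that("descriptor filtering drops missing-value and zero-variance columns", {
  panel <- cbind(A = c(1, 1, 1), B = c(1, 2, 3), C = c(1, NA, 2))
  expect_identical(filter_descriptors(panel), "B")
  full <- cbind(A = c(1, 2, 4), B = c(0, 5, 1))
  expect_identical(filter_descriptors(full), c("A", "B"))
  expect_error(filter_descriptors(panel[1, , drop = FALSE]), "at least 2")
  expect_error(filter_descriptors(cbind(A = c(1, 1), B = c(NA, 2))), "degenerate")
})

test_that("descriptor filtering equals a brute-force column scan", {
  set.seed(101)
  for (rep in 1:5) {
    m <- matrix(rnorm(10 * 8), 10, 8, dimnames = list(NULL, paste0("d", 1:8)))
    m[sample(80, 5)] <- NA
    m[, sample(8, 1)] <- 1  # constant column
    kept <- character(0)
    for (j in 1:8) {  # brute force
      col <- m[, j]
      if (!anyNA(col) && length(unique(col)) > 1) kept <- c(kept, colnames(m)[j])
    }
    if (length(kept) == 0) next
    expect_identical(filter_descriptors(m), kept)
  }
})

test_that("drug feature sets concatenate fingerprint and descriptors with exact z-scoring", {
  ds <- tiny_dataset()
  fs <- ds$drug_features
  expect_equal(ncol(fs$feature_matrix), 1024 + length(fs$kept_descriptor_names))
  expect_equal(nrow(fs$feature_matrix), 12)
  # stored statistics reproduce each column's sample mean / sd
  m <- fs$feature_matrix
  sds <- apply(m, 2, sd)
  nonconst <- fs$zscore_stds != 1 | sds > 0
  expect_lt(max(abs(colMeans(m))), 1e-6)
  expect_lt(max(abs(sds[nonconst] - 1)), 1e-6)
  # re-applying stored stats to the raw features reproduces the matrix exactly
  raw <- sweep(sweep(m, 2, fs$zscore_stds, "*"), 2, fs$zscore_means, "+")
  back <- mtsynergy:::zscore_apply(raw, list(means = fs$zscore_means,
                                             sds = fs$zscore_stds))
  expect_equal(back, m, tolerance = 1e-12)
})

test_that("zero-variance columns are centered, not divided by zero", {
  st <- mtsynergy:::zscore_fit(cbind(a = c(3, 3, 3), b = c(1, 2, 3)))
  expect_equal(unname(st$sds[["a"]]), 1)
  z <- mtsynergy:::zscore_apply(cbind(a = c(3, 3, 3), b = c(1, 2, 3)), st)
  expect_equal(unname(z[, "a"]), c(0, 0, 0))
})

test_that("missing genes are imputed with reference means", {
  ref <- matrix(c(2, 4, 1, 5), 2, 2, byrow = TRUE,
                dimnames = list(c("g1", "g2"), c("c1", "c2")))
  target <- c(g2 = 7)
  out <- impute_missing_genes(ref, target)
  expect_equal(unname(out["g1"]), 3)  # mean of 2 and 4
  expect_equal(unname(out["g2"]), 7)
  full <- c(g1 = 1, g2 = 2)
  expect_equal(impute_missing_genes(ref, full)[c("g1", "g2")], full)
  expect_error(impute_missing_genes(ref, c(zz = 1)), "no genes")
})

test_that("imputation matches brute-force per-gene means on a random fixture", {
  set.seed(7)
  ref <- matrix(rnorm(20 * 5), 20, 5,
                dimnames = list(paste0("g", 1:20), paste0("c", 1:5)))
  target <- stats::setNames(rnorm(8), sample(rownames(ref), 8))
  out <- impute_missing_genes(ref, target)
  for (g in rownames(ref)) {
    expected <- if (g %in% names(target)) target[[g]] else mean(ref[g, ])
    expect_equal(unname(out[[g]]), unname(expected))
  }
})

test_that("top-variance gene selection matches a brute-force sort", {
  set.seed(11)
  expr <- matrix(rnorm(10 * 4, sd = rep(runif(10, 0.1, 3), 4)), 10, 4,
                 dimnames = list(paste0("g", 10:1), paste0("c", 1:4)))
  fs <- build_cell_features(expr, k = 3)
  v <- apply(expr, 1, var)
  brute <- rownames(expr)[order(-v, rownames(expr))][1:3]
  expect_identical(fs$selected_genes, brute)
  # k equal to the gene count keeps everything
  expect_length(build_cell_features(expr, k = 10)$selected_genes, 10)
  expect_error(build_cell_features(expr, k = 11), "k = 11")
})

test_that("variance ties break by gene identifier order", {
  expr <- matrix(c(1, 2, 1, 2, 1, 2), 3, 2,
                 dimnames = list(c("gB", "gA", "gC"), c("c1", "c2")))
  fs <- build_cell_features(expr, k = 2)
  expect_identical(fs$selected_genes, c("gA", "gB"))
})

test_that("cell feature matrices are z-scored under stored statistics", {
  fs <- tiny_dataset()$cell_features
  expect_equal(ncol(fs$feature_matrix), 100)
  expect_lt(max(abs(colMeans(fs$feature_matrix))), 1e-6)
  expect_lt(max(abs(apply(fs$feature_matrix, 2, sd) - 1)), 1e-6)
})

test_that("synergy loader averages replicates over unordered pairs", {
  tbl <- tibble::tibble(
    drug_row = c("a", "b", "a"), drug_col = c("b", "a", "c"),
    cell_id = c("c1", "c1", "c1"), loewe_score = c(10, 20, 5)
  )
  avg <- average_synergy_replicates(tbl)
  expect_equal(nrow(avg), 2)
  expect_equal(avg$loewe_score[avg$drug_row == "a" & avg$drug_col == "b"], 15)
})

test_that("tables round-trip through the delimited-text loaders", {
  ds <- tiny_dataset()
  dir <- withr::local_tempdir()
  write_synthetic_dataset(ds, dir)
  drugs <- read_drug_table(file.path(dir, "drugs.csv"))
  expect_identical(drugs, ds$drugs)
  expr <- read_expression_matrix(file.path(dir, "expression.csv"))
  expect_equal(expr, log2(ds$tpm + 1), tolerance = 1e-12)
  syn <- read_synergy_table(file.path(dir, "synergy.csv"))
  expect_identical(nrow(syn), nrow(average_synergy_replicates(ds$synergy)))
  sen <- read_sensitivity_table(file.path(dir, "sensitivity.csv"))
  expect_equal(nrow(sen), nrow(ds$sensitivity))
})
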