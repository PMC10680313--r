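#' Synthetic dataset configuration
#'
#' Defines the miniature study conditions emulated by the generator: a drug
#' panel with valid SMILES from a fragment grammar, a log-normal TPM
#' expression matrix with tissue labels, and synergy / sensitivity tables
#' planted as noisy functions of projections of the engineered features, so
#' the signal is learnable and feature-pipeline bugs break recovery.
#'
#' @param n_drugs,n_cells,n_genes Panel sizes (defaults 40, 20, 2000).
#' @param pair_fraction Fraction of all unordered drug pairs measured
#'   (default 0.6); every selected pair is screened on every cell line.
#' @param noise_sd_synergy,noise_sd_sensitivity Gaussian noise added to the
#'   planted scores, on the Loewe / RI scales (defaults 5 and 5).
#' @param positive_rate_target Fraction of synergy samples planted above the
#'   positive threshold of 30 (default 0.1).
#' @param replicate_fraction Fraction of synergy rows duplicated with fresh
#'   noise to exercise replicate averaging (default 0.05).
#' @param n_tissues Number of synthetic tissue labels (default 4, >= 3).
#' @param k_genes Top-variance genes used for cell features (default 1000;
#'   must not exceed `n_genes`).
#' @param projection_rank Rank of the planted signal (default 4).
#' @param seed Generator seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_drugs = 40, n_cells = 20, n_genes = 2000,
                             pair_fraction = 0.6, noise_sd_synergy = 5,
                             noise_sd_sensitivity = 5, positive_rate_target = 0.1,
                             replicate_fraction = 0.05, n_tissues = 4,
                             k_genes = 1000, projection_rank = 4, seed = 1) {
  stopifnot(n_drugs >= 2, n_cells >= 2, n_genes >= 2, n_tissues >= 3,
            k_genes <= n_genes, projection_rank >= 1)
  if (pair_fraction <= 0 || pair_fraction > 1) abort("pair_fraction must be in (0, 1]")
  if (positive_rate_target <= 0 || positive_rate_target > 1) {
    abort("positive_rate_target must be in (0, 1]")
  }
  structure(as.list(environment()), class = "synthetic_config")
}

# Fragment grammar: two-slot templates filled with terminal groups. The
# prefix slot attaches through a group's last written atom, so groups ending
# in a monovalent atom or a nitrile nitrogen are suffix-only. Any combination
# that still fails to parse is rejected and resampled.
.smiles_templates <- c(
  "%sc1ccc(%s)cc1", "%sc1ccc(%s)cn1", "%sC1CCC(%s)CC1", "%sC1CCN(%s)CC1",
  "%sCC(=O)N%s", "%sCC(%s)C", "%sCCO%s", "%sc1ccc(OC%s)cc1", "%sCC(=O)O%s",
  "%sC(=O)c1ccc(%s)cc1"
)
.smiles_suffix_groups <- c(
  "C", "CC", "CCC", "CC(C)C", "CCO", "CO", "N", "NC", "Cl", "F",
  "C#N", "C(F)(F)F", "OC", "CN(C)C", "CCN", "c1ccccc1", "C1CCCC1"
)
.smiles_prefix_groups <- setdiff(.smiles_suffix_groups, c("C#N", "C(F)(F)F"))

#' Generate valid SMILES strings from a fragment grammar
#'
#' Composes molecules from aromatic/aliphatic ring cores, linkers and common
#' heteroatom groups. Every output parses with the package featurizer;
#' uniqueness is enforced by rejection sampling. Deterministic under `seed`.
#'
#' @param n Number of distinct SMILES to produce.
#' @param seed RNG seed.
#' @return Character vector of length `n`.
#' @export
generate_smiles <- function(n, seed = 1) {
  set.seed(derive_seed(seed, "smiles"))
  out <- character(0)
  attempts <- 0L
  while (length(out) < n) {
    attempts <- attempts + 1L
    if (attempts > 200L * n) abort("SMILES rejection sampling failed to converge")
    cand <- sprintf(sample(.smiles_templates, 1),
                    sample(.smiles_prefix_groups, 1), sample(.smiles_suffix_groups, 1))
    if (cand %in% out) next
    ok <- tryCatch({ parse_smiles_graph(cand); TRUE }, error = function(e) FALSE)
    if (ok) out <- c(out, cand)
  }
  out
}

#' Generate a synthetic TPM expression matrix with tissue labels
#'
#' Log-normal TPM draws with gene-specific location and scale parameters, so
#' the gene-variance ranking used by feature selection is non-degenerate.
#' Cell lines are assigned round-robin to `n_tissues` synthetic tissues.
#'
#' @param n_cells,n_genes Matrix dimensions.
#' @param n_tissues Number of tissue labels (>= 3).
#' @param seed RNG seed.
#' @return List with `tpm` (genes x cells, non-negative) and `annotation`
#'   (tibble `cell_id`, `tissue`).
#' @export
generate_expression <- function(n_cells, n_genes, n_tissues = 4, seed = 1) {
  set.seed(derive_seed(seed, "expression"))
  meanlog <- stats::rnorm(n_genes, mean = 1, sd = 1.5)
  sdlog <- stats::runif(n_genes, 0.2, 1.2)
  tpm <- matrix(stats::rlnorm(n_genes * n_cells, meanlog = rep(meanlog, n_cells),
                              sdlog = rep(sdlog, n_cells)),
                nrow = n_genes, ncol = n_cells)
  rownames(tpm) <- sprintf("gene_%05d", seq_len(n_genes))
  colnames(tpm) <- sprintf("cell_%02d", seq_len(n_cells))
  annotation <- tibble::tibble(
    cell_id = colnames(tpm),
    tissue = sprintf("tissue_%d", ((seq_len(n_cells) - 1L) %% n_tissues) + 1L)
  )
  list(tpm = tpm, annotation = annotation)
}

# Haar-ish random orthogonal rotation via QR of a Gaussian matrix.
random_rotation <- function(r) {
  q <- qr.Q(qr(matrix(stats::rnorm(r * r), r, r)))
  q * sign(diag(q))[1]
}

#' Plant synergy and sensitivity scores on engineered features
#'
#' Projects the z-scored drug and cell-line feature matrices to
#' `projection_rank` dimensions along seeded random rotations of their top
#' principal axes, then plants:
#' sensitivity as an affine function of the drug and cell projections,
#' rescaled to roughly the 0-100 RI range; synergy as a
#' symmetric bilinear/trilinear function of the two drug projections and the
#' cell projection, affinely scaled so the target fraction of samples falls
#' above the Loewe threshold of 30 before noise. Gaussian noise is added to
#' both. The same projections drive both tasks, so they are genuinely
#' related — the situation multi-task learning is meant to exploit.
#'
#' @param drug_features A `drug_feature_set`.
#' @param cell_features A `cell_feature_set`.
#' @param config A [synthetic_config()].
#' @return List with `synergy` and `sensitivity` tibbles (replicate rows
#'   appended when configured), `clean` noise-free score tables, and
#'   `weights` (all planted projections/coefficients and scaling constants,
#'   sufficient to recompute the clean scores exactly).
#' @export
plant_scores <- function(drug_features, cell_features, config) {
  stopifnot(inherits(config, "synthetic_config"))
  Zd <- drug_features$feature_matrix
  Zc <- cell_features$feature_matrix
  r <- config$projection_rank
  set.seed(derive_seed(config$seed, "plant"))
  # project onto seeded random rotations of the top principal axes of the
  # feature matrices: the planted signal then rides the dominant axes of
  # chemical / transcriptional variation (as real structure-activity signal
  # does), so it is estimable from a finite drug panel, rather than hiding in
  # directions no held-out drug constrains
  Pd <- svd(Zd, nu = 0, nv = r)$v %*% random_rotation(r)
  Pc <- svd(Zc, nu = 0, nv = r)$v %*% random_rotation(r)
  U <- scale(Zd %*% Pd)
  V <- scale(Zc %*% Pc)
  a_d <- stats::rnorm(r); a_c <- stats::rnorm(r)
  c_tri <- stats::rnorm(r); c_pair <- stats::rnorm(r)

  drugs <- rownames(Zd); cells <- rownames(Zc)
  sens_grid <- expand.grid(drug_id = drugs, cell_id = cells,
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ud <- U[sens_grid$drug_id, , drop = FALSE]
  vc <- V[sens_grid$cell_id, , drop = FALSE]
  sens_raw <- ud %*% a_d + vc %*% a_c
  sens_center <- mean(sens_raw); sens_scale <- 18 / stats::sd(sens_raw)
  sens_clean <- 50 + (sens_raw - sens_center) * sens_scale

  all_pairs <- t(utils::combn(drugs, 2))
  n_sel <- max(1L, ceiling(config$pair_fraction * nrow(all_pairs)))
  sel <- all_pairs[sample.int(nrow(all_pairs), n_sel), , drop = FALSE]
  flip <- stats::runif(nrow(sel)) < 0.5  # emit pairs in arbitrary orientation
  pairs <- tibble::tibble(drug_row = ifelse(flip, sel[, 2], sel[, 1]),
                          drug_col = ifelse(flip, sel[, 1], sel[, 2]))
  syn_grid <- tidyr::crossing(pairs, cell_id = cells)
  u1 <- U[syn_grid$drug_row, , drop = FALSE]
  u2 <- U[syn_grid$drug_col, , drop = FALSE]
  vs <- V[syn_grid$cell_id, , drop = FALSE]
  syn_raw <- (u1 * u2 * vs) %*% c_tri + ((u1 + u2) * vs) %*% c_pair
  syn_sd <- stats::sd(syn_raw)
  syn_q <- stats::quantile(syn_raw / syn_sd, 1 - config$positive_rate_target,
                           names = FALSE, type = 7)
  syn_scale <- 20
  syn_clean <- 30 + (syn_raw / syn_sd - syn_q) * syn_scale

  sensitivity <- dplyr::mutate(
    tibble::as_tibble(sens_grid),
    ri_score = as.numeric(sens_clean) + stats::rnorm(nrow(sens_grid),
                                                     sd = config$noise_sd_sensitivity)
  )
  synergy <- dplyr::mutate(
    syn_grid,
    loewe_score = as.numeric(syn_clean) + stats::rnorm(nrow(syn_grid),
                                                       sd = config$noise_sd_synergy)
  )
  if (config$replicate_fraction > 0) {
    idx <- which(stats::runif(nrow(synergy)) < config$replicate_fraction)
    if (length(idx) > 0) {
      reps <- synergy[idx, ]
      reps$loewe_score <- as.numeric(syn_clean)[idx] +
        stats::rnorm(length(idx), sd = config$noise_sd_synergy)
      synergy <- dplyr::bind_rows(synergy, reps)
    }
  }
  list(
    synergy = synergy,
    sensitivity = sensitivity,
    clean = list(
      synergy = dplyr::mutate(syn_grid, loewe_score = as.numeric(syn_clean)),
      sensitivity = dplyr::mutate(tibble::as_tibble(sens_grid),
                                  ri_score = as.numeric(sens_clean))
    ),
    weights = list(Pd = Pd, Pc = Pc,
                   U_center = attr(U, "scaled:center"), U_scale = attr(U, "scaled:scale"),
                   V_center = attr(V, "scaled:center"), V_scale = attr(V, "scaled:scale"),
                   a_d = a_d, a_c = a_c, c_tri = c_tri, c_pair = c_pair,
                   sens_center = sens_center, sens_scale = sens_scale,
                   syn_sd = syn_sd, syn_q = syn_q, syn_scale = syn_scale)
  )
}

#' Recompute planted noise-free scores from stored weights
#'
#' Reconstructs the clean synergy and sensitivity scores of [plant_scores()]
#' from its `weights` element and the feature sets; used to audit that the
#' planted signal is exactly a function of the engineered features.
#'
#' @param weights The `weights` element returned by [plant_scores()].
#' @param drug_features,cell_features The feature sets used for planting.
#' @param synergy,sensitivity Tables naming the rows to recompute.
#' @return List of numeric vectors `synergy`, `sensitivity`.
#' @export
recompute_planted_scores <- function(weights, drug_features, cell_features,
                                     synergy, sensitivity) {
  U <- sweep(sweep(drug_features$feature_matrix %*% weights$Pd, 2,
                   weights$U_center, "-"), 2, weights$U_scale, "/")
  V <- sweep(sweep(cell_features$feature_matrix %*% weights$Pc, 2,
                   weights$V_center, "-"), 2, weights$V_scale, "/")
  u1 <- U[synergy$drug_row, , drop = FALSE]
  u2 <- U[synergy$drug_col, , drop = FALSE]
  vs <- V[synergy$cell_id, , drop = FALSE]
  syn_raw <- (u1 * u2 * vs) %*% weights$c_tri + ((u1 + u2) * vs) %*% weights$c_pair
  ud <- U[sensitivity$drug_id, , drop = FALSE]
  vc <- V[sensitivity$cell_id, , drop = FALSE]
  sens_raw <- ud %*% weights$a_d + vc %*% weights$a_c
  list(
    synergy = as.numeric(30 + (syn_raw / weights$syn_sd - weights$syn_q) * weights$syn_scale),
    sensitivity = as.numeric(50 + (sens_raw - weights$sens_center) * weights$sens_scale)
  )
}

#' Generate a complete miniature dataset
#'
#' Runs the full generator: SMILES, expression, feature engineering through
#' the package's own pipeline, and planted synergy/sensitivity tables.
#'
#' @param config A [synthetic_config()].
#' @return A `synthetic_dataset`: `drugs`, `tpm`, `annotation`, `synergy`,
#'   `sensitivity` tables plus `drug_features`, `cell_features`, `planted`
#'   (clean scores and weights) and the `config`.
#' @export
simulate_synergy_dataset <- function(config = synthetic_config()) {
  drugs <- tibble::tibble(
    drug_id = sprintf("drug_%02d", seq_len(config$n_drugs)),
    smiles = generate_smiles(config$n_drugs, config$seed)
  )
  expr <- generate_expression(config$n_cells, config$n_genes, config$n_tissues,
                              config$seed)
  drug_features <- build_drug_features(drugs)
  cell_features <- build_cell_features(log2(expr$tpm + 1), expr$annotation,
                                       k = config$k_genes)
  planted <- plant_scores(drug_features, cell_features, config)
  structure(
    list(drugs = drugs, tpm = expr$tpm, annotation = expr$annotation,
         synergy = planted$synergy, sensitivity = planted$sensitivity,
         drug_features = drug_features, cell_features = cell_features,
         planted = planted[c("clean", "weights")], config = config),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset> %d drugs, %d cell lines, %d genes; %d synergy rows, %d sensitivity rows\n",
    x$config$n_drugs, x$config$n_cells, x$config$n_genes,
    nrow(x$synergy), nrow(x$sensitivity)))
  invisible(x)
}

#' Write a synthetic dataset in the loader formats
#'
#' Emits `drugs.csv`, `expression.csv` (TPM), `cells.csv`, `synergy.csv`,
#' `sensitivity.csv` plus a `provenance.yaml` with all generator parameters,
#' so the files round-trip through the package loaders.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(dataset$drugs, file.path(dir, "drugs.csv"), row.names = FALSE)
  expr <- data.frame(gene_id = rownames(dataset$tpm), dataset$tpm,
                     check.names = FALSE)
  utils::write.csv(expr, file.path(dir, "expression.csv"), row.names = FALSE)
  utils::write.csv(dataset$annotation, file.path(dir, "cells.csv"), row.names = FALSE)
  utils::write.csv(dataset$synergy, file.path(dir, "synergy.csv"), row.names = FALSE)
  utils::write.csv(dataset$sensitivity, file.path(dir, "sensitivity.csv"), row.names = FALSE)
  prov <- c(unclass(dataset$config), list(featurizer = featurizer_version()))
  yaml::write_yaml(prov, file.path(dir, "provenance.yaml"))
  invisible(dir)
}
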