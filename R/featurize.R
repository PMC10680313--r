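#' Filter a molecular descriptor panel
#'
#' Drops every descriptor column that contains any missing value or has zero
#' variance across the drug set, mirroring the preprocessing used before
#' concatenating descriptors with fingerprints. Surviving names keep the
#' panel's native column order so the feature layout is reproducible.
#'
#' @param panel Numeric matrix, drugs x descriptors, with column names.
#' @return Character vector of surviving descriptor names, in panel order.
#' @export
filter_descriptors <- function(panel) {
  stopifnot(is.matrix(panel), !is.null(colnames(panel)))
  if (nrow(panel) < 2) abort("descriptor filtering needs at least 2 drugs")
  keep <- vapply(seq_len(ncol(panel)), function(j) {
    col <- panel[, j]
    !anyNA(col) && stats::var(col) > 0
  }, TRUE)
  if (!any(keep)) abort("degenerate drug set: all descriptor columns dropped")
  colnames(panel)[keep]
}

zscore_fit <- function(m) {
  means <- colMeans(m)
  sds <- col_sds(m)
  # a column constant across the fitting set has no scale; divide by 1 so the
  # centered column is returned instead of NaN (common for rare fingerprint bits)
  sds[sds == 0] <- 1
  list(means = means, sds = sds)
}

zscore_apply <- function(m, stats) {
  sweep(sweep(m, 2, stats$means, "-"), 2, stats$sds, "/")
}

#' Build the drug feature set
#'
#' Featurizes each drug as `fingerprint || kept descriptors` and z-scores every
#' column, storing the normalization statistics for reuse on unseen drugs.
#'
#' @param drugs Data frame with columns `drug_id`, `smiles`.
#' @param kept_descriptor_names Descriptor columns to keep; default `NULL`
#'   filters the computed panel with [filter_descriptors()].
#' @param radius,n_bits Fingerprint parameters (defaults 3, 1024).
#' @return A `drug_feature_set`: list with `records` (tibble of drug_id,
#'   smiles), `kept_descriptor_names`, `feature_matrix` (drugs x D, z-scored,
#'   rownames = drug ids), `zscore_means`, `zscore_stds`, `featurizer`.
#' @export
build_drug_features <- function(drugs, kept_descriptor_names = NULL,
                                radius = 3, n_bits = 1024) {
  drugs <- tibble::as_tibble(drugs)
  stopifnot(all(c("drug_id", "smiles") %in% names(drugs)), nrow(drugs) >= 1)
  fps <- t(mapply(function(s, id) compute_fingerprint(s, radius, n_bits, drug_id = id),
                  drugs$smiles, drugs$drug_id))
  colnames(fps) <- sprintf("fp_%04d", seq_len(n_bits))
  desc <- t(mapply(function(s, id) compute_descriptors(s, drug_id = id),
                   drugs$smiles, drugs$drug_id))
  if (is.null(kept_descriptor_names)) {
    kept_descriptor_names <- filter_descriptors(desc)
  }
  if (length(kept_descriptor_names) == 0) abort("kept_descriptor_names is empty")
  missing_cols <- setdiff(kept_descriptor_names, colnames(desc))
  if (length(missing_cols) > 0) {
    abort(sprintf("descriptor panel lacks columns: %s", paste(missing_cols, collapse = ", ")))
  }
  fm <- cbind(fps, desc[, kept_descriptor_names, drop = FALSE])
  rownames(fm) <- drugs$drug_id
  if (anyNA(fm)) abort("missing values in drug feature matrix after filtering")
  st <- zscore_fit(fm)
  structure(
    list(
      records = drugs[, c("drug_id", "smiles")],
      kept_descriptor_names = kept_descriptor_names,
      feature_matrix = zscore_apply(fm, st),
      zscore_means = st$means,
      zscore_stds = st$sds,
      featurizer = featurizer_version()
    ),
    class = "drug_feature_set"
  )
}

#' @export
print.drug_feature_set <- function(x, ...) {
  cat(sprintf(
    "<drug_feature_set> %d drugs x %d features (%d fingerprint bits + %d descriptors)\n",
    nrow(x$feature_matrix), ncol(x$feature_matrix),
    ncol(x$feature_matrix) - length(x$kept_descriptor_names),
    length(x$kept_descriptor_names)
  ))
  cat("featurizer:", x$featurizer, "\n")
  invisible(x)
}

#' Fill missing genes of a cell line from reference averages
#'
#' Genes present in the reference expression matrix but absent from the target
#' profile are filled with the per-gene mean over the reference cell lines
#' (all values on the log2(TPM+1) scale).
#'
#' @param reference Numeric matrix, genes x cell lines, with gene rownames.
#' @param target Named numeric vector of expression for the target cell line.
#' @return Named numeric vector covering every reference gene, in reference
#'   row order.
#' @export
impute_missing_genes <- function(reference, target) {
  stopifnot(is.matrix(reference), !is.null(rownames(reference)), !is.null(names(target)))
  shared <- intersect(rownames(reference), names(target))
  if (length(shared) == 0) abort("target cell line shares no genes with the reference matrix")
  out <- rowMeans(reference)
  out[shared] <- target[shared]
  out
}

#' Build the cell-line feature set
#'
#' Selects the `k` genes with largest expression variance across cell lines
#' (ties broken by gene identifier order), then z-scores each selected gene.
#' Expression is expected on the log2(TPM+1) scale; see
#' [read_expression_matrix()] for the transformation at load time.
#'
#' @param expression Numeric matrix, genes x cell lines, log2(TPM+1), with
#'   gene rownames and cell-line colnames.
#' @param annotation Data frame `cell_id`, `tissue` (optional; tissues default
#'   to `NA`).
#' @param k Number of genes to keep (default 5000).
#' @return A `cell_feature_set`: list with `records` (tibble cell_id, tissue),
#'   `selected_genes`, `feature_matrix` (cells x k, z-scored), `zscore_means`,
#'   `zscore_stds`.
#' @export
build_cell_features <- function(expression, annotation = NULL, k = 5000) {
  stopifnot(is.matrix(expression), !is.null(rownames(expression)), !is.null(colnames(expression)))
  if (ncol(expression) < 2) abort("need at least 2 cell lines")
  if (nrow(expression) < k) {
    abort(sprintf("only %d genes available but k = %d requested", nrow(expression), k))
  }
  if (any(!is.finite(expression))) abort("non-finite expression values")
  v <- apply(expression, 1, stats::var)
  ord <- order(-v, rownames(expression), method = "radix")
  selected <- rownames(expression)[ord[seq_len(k)]]
  fm <- t(expression[selected, , drop = FALSE])
  st <- zscore_fit(fm)
  if (is.null(annotation)) {
    annotation <- tibble::tibble(cell_id = colnames(expression), tissue = NA_character_)
  }
  annotation <- tibble::as_tibble(annotation)
  stopifnot(all(colnames(expression) %in% annotation$cell_id))
  annotation <- annotation[match(colnames(expression), annotation$cell_id), ]
  structure(
    list(
      records = annotation[, c("cell_id", "tissue")],
      selected_genes = selected,
      feature_matrix = zscore_apply(fm, st),
      zscore_means = st$means,
      zscore_stds = st$sds
    ),
    class = "cell_feature_set"
  )
}

#' @export
print.cell_feature_set <- function(x, ...) {
  cat(sprintf("<cell_feature_set> %d cell lines x %d genes (top-variance selection)\n",
              nrow(x$feature_matrix), ncol(x$feature_matrix)))
  invisible(x)
}

# ---- loaders -----------------------------------------------------------------

#' Read a drug table
#'
#' Delimited text with header columns `drug_id,smiles`.
#' @param path File path.
#' @param sep Field separator (default comma).
#' @return Tibble with columns `drug_id`, `smiles`.
#' @export
read_drug_table <- function(path, sep = ",") {
  d <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(all(c("drug_id", "smiles") %in% names(d)))
  tibble::as_tibble(d[, c("drug_id", "smiles")])
}

#' Read a gene expression matrix
#'
#' First column gene identifier, remaining columns one per cell line. Values
#' are TPM and are transformed to log2(TPM+1) unless `already_log2 = TRUE`.
#'
#' @param path File path.
#' @param already_log2 Set `TRUE` if the file already holds log2(TPM+1).
#' @param sep Field separator (default comma).
#' @return Numeric matrix genes x cell lines on the log2(TPM+1) scale.
#' @export
read_expression_matrix <- function(path, already_log2 = FALSE, sep = ",") {
  d <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  if (!already_log2) m <- log2(m + 1)
  m
}

#' Read a cell line annotation table
#' @param path File path to delimited text with columns `cell_id,tissue`.
#' @param sep Field separator (default comma).
#' @return Tibble `cell_id`, `tissue`.
#' @export
read_cell_annotation <- function(path, sep = ",") {
  d <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
  stopifnot(all(c("cell_id", "tissue") %in% names(d)))
  tibble::as_tibble(d[, c("cell_id", "tissue")])
}

#' Read a synergy table, averaging replicates
#'
#' Delimited text `drug_row,drug_col,cell_id,loewe_score`. Replicate
#' measurements of the same unordered drug pair on the same cell line are
#' averaged at load time.
#'
#' @param path File path.
#' @param sep Field separator (default comma).
#' @return Tibble `drug_row`, `drug_col`, `cell_id`, `loewe_score`, one row
#'   per (unordered pair, cell line).
#' @export
read_synergy_table <- function(path, sep = ",") {
  d <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
  stopifnot(all(c("drug_row", "drug_col", "cell_id", "loewe_score") %in% names(d)))
  average_synergy_replicates(tibble::as_tibble(d))
}

#' Average replicate synergy measurements
#'
#' Collapses rows sharing the same unordered drug pair and cell line to their
#' mean Loewe score. The returned `drug_row`/`drug_col` are the pair in
#' lexicographic order.
#'
#' @param synergy Data frame `drug_row`, `drug_col`, `cell_id`, `loewe_score`.
#' @return Tibble with one row per (unordered pair, cell line).
#' @export
average_synergy_replicates <- function(synergy) {
  synergy |>
    dplyr::mutate(
      .a = pmin(.data$drug_row, .data$drug_col),
      .b = pmax(.data$drug_row, .data$drug_col)
    ) |>
    dplyr::summarise(
      loewe_score = mean(.data$loewe_score),
      .by = c(".a", ".b", "cell_id")
    ) |>
    dplyr::rename(drug_row = ".a", drug_col = ".b") |>
    dplyr::select("drug_row", "drug_col", "cell_id", "loewe_score")
}

#' Read a monotherapy sensitivity table
#'
#' Delimited text `drug_id,cell_id,ri_score` (RI = Relative Inhibition, the
#' normalized log10-transformed area under the single-drug dose-response
#' curve). Replicates are averaged.
#'
#' @param path File path.
#' @param sep Field separator (default comma).
#' @return Tibble `drug_id`, `cell_id`, `ri_score`.
#' @export
read_sensitivity_table <- function(path, sep = ",") {
  d <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
  stopifnot(all(c("drug_id", "cell_id", "ri_score") %in% names(d)))
  tibble::as_tibble(d) |>
    dplyr::summarise(ri_score = mean(.data$ri_score), .by = c("drug_id", "cell_id"))
}
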