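#' Default configuration
#'
#' Every tunable default in one place: featurization (fingerprint radius 3,
#' 1024 bits, 5000 top-variance genes), encoder code widths (drug 128, cell
#' line 256), the grid-search space ({2048, 4096, 8192} first-layer sizes by
#' {5e-4, 1e-4, 5e-5} learning rates), early stopping (patience 100, cap 500),
#' label thresholds (synergy 30, sensitivity 50), and the synthetic-data
#' generator conditions.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    fp_radius = 3L, fp_bits = 1024L, k_genes = 5000L,
    already_log2 = FALSE, zscore_scope = "global",
    c_drug = 128L, c_cell = 256L,
    ae_dropout = 0.2, ae_batch_size = 64L, ae_max_epochs = 300L,
    ae_learning_rate = 1e-3,
    shared_layer_size = 2048L, dropout_branch = 0.5, learning_rate = 5e-4,
    grid_layer_sizes = c(2048L, 4096L, 8192L),
    grid_learning_rates = c(5e-4, 1e-4, 5e-5),
    batch_size = 128L, max_epochs = 500L, patience = 100L,
    synergy_threshold = 30, sensitivity_threshold = 50,
    n_folds = 5L, variant = "full",
    n_drugs = 40L, n_cells = 20L, n_genes = 2000L, pair_fraction = 0.6,
    noise_sd_synergy = 5, noise_sd_sensitivity = 5, positive_rate_target = 0.1,
    replicate_fraction = 0.05, n_tissues = 4L, sim_k_genes = 1000L,
    projection_rank = 4L
  )
}

config_checks <- list(
  fp_radius = function(v) v >= 0, fp_bits = function(v) v >= 2,
  k_genes = function(v) v >= 1, sim_k_genes = function(v) v >= 1,
  c_drug = function(v) v >= 1, c_cell = function(v) v >= 1,
  ae_dropout = function(v) v >= 0 && v < 1,
  dropout_branch = function(v) v >= 0 && v < 1,
  learning_rate = function(v) v > 0, ae_learning_rate = function(v) v > 0,
  grid_learning_rates = function(v) all(v > 0),
  grid_layer_sizes = function(v) all(v >= 1),
  shared_layer_size = function(v) v >= 1,
  batch_size = function(v) v >= 1, ae_batch_size = function(v) v >= 1,
  max_epochs = function(v) v >= 1, ae_max_epochs = function(v) v >= 1,
  patience = function(v) v >= 0,
  n_folds = function(v) v >= 2,
  variant = function(v) v %in% c("full", "only-synergy", "only-sensitivity",
                                 "no-ae", "regression-only"),
  n_drugs = function(v) v >= 2, n_cells = function(v) v >= 2,
  n_genes = function(v) v >= 2, n_tissues = function(v) v >= 3,
  pair_fraction = function(v) v > 0 && v <= 1,
  positive_rate_target = function(v) v > 0 && v <= 1,
  replicate_fraction = function(v) v >= 0 && v < 1,
  noise_sd_synergy = function(v) v >= 0, noise_sd_sensitivity = function(v) v >= 0,
  projection_rank = function(v) v >= 1,
  zscore_scope = function(v) v %in% c("global", "train")
)

#' Load and validate a configuration file
#'
#' Reads a YAML file; unknown keys are rejected, missing keys are filled with
#' the documented defaults, and every value is validated (errors name the
#' offending key). `path = NULL` or an empty file yields the full default
#' configuration.
#'
#' @param path Path to a YAML configuration file, or `NULL`.
#' @return Validated configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown) > 0) {
    abort(sprintf("unknown configuration key(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(cfg, user)
  for (key in names(config_checks)) {
    v <- cfg[[key]]
    ok <- tryCatch(is.numeric(v) || is.character(v) || is.logical(v), error = function(e) FALSE)
    if (!ok || !isTRUE(all(config_checks[[key]](v)))) {
      abort(sprintf("invalid value for configuration key '%s'", key))
    }
  }
  cfg
}

#' Save a configuration to YAML
#' @param config Configuration list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run: the full configuration
#' snapshot, the seed, software and featurizer versions, digests of the input
#' files, and a timestamp. Every output directory holds exactly one manifest.
#'
#' @param dir Output directory.
#' @param config Configuration list.
#' @param seed Top-level seed of the run.
#' @param inputs Character vector of input file paths (digested with MD5).
#' @return Path to the manifest, invisibly.
#' @export
write_run_manifest <- function(dir, config, seed, inputs = character(0)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  digests <- if (length(inputs) > 0) {
    as.list(tools::md5sum(inputs))
  } else {
    list()
  }
  manifest <- list(
    package = tryCatch(as.character(utils::packageVersion("mtsynergy")),
                       error = function(e) "unversioned"),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    featurizer = featurizer_version(),
    seed = as.integer(seed),
    config = config,
    input_digests = digests,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' Read a run manifest
#' @param dir Directory holding `manifest.yaml`.
#' @return The manifest list.
#' @export
read_run_manifest <- function(dir) {
  yaml::read_yaml(file.path(dir, "manifest.yaml"))
}
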