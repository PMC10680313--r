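#' Featurizer version string
#'
#' Identifies the fingerprint implementation and the underlying SMILES engine.
#' The exact bit mapping of a hashed circular fingerprint depends on the
#' featurizer, so this string is recorded alongside every feature matrix and
#' in run manifests; frozen test fixtures are tied to it.
#'
#' @return A single character string.
#' @export
featurizer_version <- function() {
  ob <- tryCatch(as.character(utils::packageVersion("ChemmineOB")), error = function(e) "unknown")
  sprintf("mtsynergy-circular-fp/1.0 (ChemmineOB %s)", ob)
}

# Parse one SMILES into a heavy-atom molecular graph via OpenBabel.
# Returns list(elements = character, bonds = matrix[a1, a2, order]).
parse_smiles_graph <- function(smiles, drug_id = NULL) {
  who <- if (is.null(drug_id)) sprintf("SMILES '%s'", smiles) else sprintf("drug '%s'", drug_id)
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) abort(sprintf("featurization error for %s: unparseable SMILES", who))
  )
  mol <- tryCatch(sdf[[1]], error = function(e) NULL)
  ab <- if (is.null(mol)) NULL else tryCatch(ChemmineR::atomblock(mol), error = function(e) NULL)
  if (is.null(ab) || nrow(ab) == 0) {
    abort(sprintf("featurization error for %s: unparseable SMILES", who))
  }
  elements <- sub("_\\d+$", "", rownames(ab))
  bb <- tryCatch(ChemmineR::bondblock(mol), error = function(e) NULL)
  bonds <- if (is.null(bb) || !is.matrix(bb) || nrow(bb) == 0 || ncol(bb) < 3) {
    matrix(numeric(0), ncol = 3)
  } else {
    unname(cbind(bb[, 1], bb[, 2], bb[, 3]))
  }
  list(elements = elements, bonds = bonds)
}

# Atomic numbers for the elements the fragment grammar and common drugs use;
# unknown elements fall back to a hash of the symbol.
.atomic_numbers <- c(
  H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15, S = 16,
  Cl = 17, Br = 35, I = 53
)

atomic_number <- function(sym) {
  z <- .atomic_numbers[sym]
  unknown <- is.na(z)
  if (any(unknown)) z[unknown] <- 90 + (vapply(sym[unknown], function(s) sum(utf8ToInt(s)), 0) %% 10)
  unname(z)
}

# Order-invariant integer hash folded over a numeric vector. All arithmetic in
# doubles; intermediate values stay below 2^53 so the fold is exact.
.hash_fold <- function(v) {
  acc <- 5381
  for (x in v) acc <- (acc * 65599 + x) %% 2147483629
  acc
}

#' Hashed circular (Morgan-style) fingerprint of a molecule
#'
#' Computes an ECFP-like fingerprint: atoms start from invariants built on
#' element, heavy-atom degree and total bond order; neighbourhood identifiers
#' are grown iteratively out to `radius` bonds and hashed into `n_bits`
#' presence/absence bits. Radius 3 corresponds to ECFP6-style environments.
#' The bit mapping is specific to this featurizer (see [featurizer_version()]):
#' it is deterministic and canonicalization-invariant (different SMILES
#' spellings of one molecule give identical vectors), but not interchangeable
#' with other toolkits' Morgan bits.
#'
#' @param smiles A single SMILES string.
#' @param radius Neighbourhood radius in bonds (default 3).
#' @param n_bits Folded fingerprint length (default 1024).
#' @param drug_id Optional identifier used in error messages.
#' @return Integer vector of 0/1 of length `n_bits`.
#' @examples
#' fp <- compute_fingerprint("CCO")
#' sum(fp)                       # a handful of bits set
#' identical(fp, compute_fingerprint("OCC"))  # spelling-invariant
#' @export
compute_fingerprint <- function(smiles, radius = 3, n_bits = 1024, drug_id = NULL) {
  stopifnot(radius >= 0, n_bits >= 2)
  g <- parse_smiles_graph(smiles, drug_id)
  n <- length(g$elements)
  deg <- integer(n)
  bosum <- numeric(n)
  nb <- vector("list", n)
  if (nrow(g$bonds) > 0) {
    for (i in seq_len(nrow(g$bonds))) {
      a <- g$bonds[i, 1]; b <- g$bonds[i, 2]; o <- g$bonds[i, 3]
      deg[a] <- deg[a] + 1L; deg[b] <- deg[b] + 1L
      bosum[a] <- bosum[a] + o; bosum[b] <- bosum[b] + o
      nb[[a]] <- rbind(nb[[a]], c(b, o))
      nb[[b]] <- rbind(nb[[b]], c(a, o))
    }
  }
  inv <- vapply(seq_len(n), function(i) {
    .hash_fold(c(atomic_number(g$elements[i]), deg[i], bosum[i]))
  }, 0)
  ids <- inv  # radius-0 identifiers
  if (radius > 0) {
    for (r in seq_len(radius)) {
      new_inv <- vapply(seq_len(n), function(i) {
        if (is.null(nb[[i]])) return(.hash_fold(c(r, inv[i])))
        contrib <- nb[[i]]
        key <- contrib[, 2] * 2147483629 + inv[contrib[, 1]]
        ord <- order(key)
        .hash_fold(c(r, inv[i], as.vector(t(cbind(contrib[ord, 2], inv[contrib[ord, 1]])))))
      }, 0)
      inv <- new_inv
      ids <- c(ids, inv)
    }
  }
  bits <- unique(floor(ids %% n_bits)) + 1
  out <- integer(n_bits)
  out[bits] <- 1L
  out
}

#' Molecular descriptor panel for a molecule
#'
#' Returns the full numeric descriptor panel of the underlying OpenBabel
#' engine (hydrogen-bond acceptor/donor counts, logP, molar refractivity,
#' molecular weight, fluorine count, topological polar surface area).
#' Non-computable entries are returned as `NA`, never silently zeroed;
#' downstream filtering ([filter_descriptors()]) removes such columns.
#'
#' @param smiles A single SMILES string.
#' @param drug_id Optional identifier used in error messages.
#' @return Named numeric vector.
#' @examples
#' d <- compute_descriptors("CCO")
#' d[["MW"]]  # ~46.07 for ethanol
#' @export
compute_descriptors <- function(smiles, drug_id = NULL) {
  who <- if (is.null(drug_id)) sprintf("SMILES '%s'", smiles) else sprintf("drug '%s'", drug_id)
  parse_smiles_graph(smiles, drug_id)  # consistent parse validation
  p <- tryCatch(
    ChemmineOB::prop_OB(ChemmineOB::forEachMol("SMILES", smiles, identity)),
    error = function(e) abort(
      sprintf("featurization error for %s: descriptor computation failed", who)
    )
  )
  num <- vapply(p, is.numeric, TRUE)
  out <- unlist(p[1, num, drop = TRUE])
  out[!is.finite(out)] <- NA_real_
  out
}
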