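# Molecular feature matrices: hashed circular fingerprints and
# physicochemical descriptors, row-aligned with the screen table.

new_feature_matrix <- function(values, representation, screen, params = list()) {
  rownames(values) <- screen$compound_id
  attr(values, "representation") <- representation
  attr(values, "params") <- params
  values
}

#' Feature representation tag
#'
#' @param x A feature matrix produced by [fingerprint_matrix()] or
#'   [descriptor_matrix()].
#' @return `"fingerprint"` or `"descriptor"`.
#' @export
representation <- function(x) attr(x, "representation")

#' Morgan fingerprint matrix
#'
#' Computes hashed (bit-folded) circular fingerprints for every compound
#' of a standardized screen: binary presence/absence of circular
#' substructures up to `radius` bonds, folded to `n_bits` positions.
#' Identical canonical structures yield identical rows.
#'
#' @param screen A standardized screen table (all structures parseable).
#' @param radius Circular substructure radius in bonds (default 2,
#'   i.e. ECFP4-equivalent).
#' @param n_bits Folded fingerprint length (default 1024).
#' @return An `n x n_bits` binary matrix, rows named by compound id.
#' @export
fingerprint_matrix <- function(screen, radius = 2, n_bits = 1024) {
  validate_screen(screen, require_smiles = TRUE)
  res <- chem_morgan_bits(screen$smiles, radius = radius, n_bits = n_bits)
  if (any(!res$ok)) {
    bad <- screen$compound_id[!res$ok][1]
    stop("fingerprint failure for record '", bad,
         "'; standardize the screen first", call. = FALSE)
  }
  m <- matrix(0L, nrow = nrow(screen), ncol = n_bits)
  for (i in seq_along(res$bits)) m[i, res$bits[[i]]] <- 1L
  new_feature_matrix(m, "fingerprint", screen,
                     params = list(radius = radius, n_bits = n_bits))
}

#' Physicochemical descriptor matrix
#'
#' Computes the pinned set of 208 RDKit descriptors for every compound.
#' Non-finite values are imputed to the column median (recorded in the
#' `imputed` attribute); columns more than half non-finite raise a
#' warning. Column order is fixed by the descriptor registry and stored
#' in `colnames`.
#'
#' @param screen A standardized screen table.
#' @return An `n x 208` real matrix with named columns.
#' @export
descriptor_matrix <- function(screen) {
  validate_screen(screen, require_smiles = TRUE)
  res <- chem_descriptor_table(screen$smiles)
  if (any(!res$ok)) {
    bad <- screen$compound_id[!res$ok][1]
    stop("descriptor failure for record '", bad, "'", call. = FALSE)
  }
  vals <- res$values
  n_imputed <- integer(ncol(vals))
  for (j in seq_len(ncol(vals))) {
    miss <- !is.finite(vals[, j])
    if (any(miss)) {
      if (mean(miss) > 0.5) {
        warning("descriptor '", colnames(vals)[j], "' is >50% non-finite",
                call. = FALSE)
      }
      med <- stats::median(vals[!miss, j])
      vals[miss, j] <- if (is.finite(med)) med else 0
      n_imputed[j] <- sum(miss)
    }
  }
  out <- new_feature_matrix(vals, "descriptor", screen)
  attr(out, "imputed") <- stats::setNames(n_imputed, colnames(vals))
  out
}
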