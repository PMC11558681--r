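# Chemistry layer: canonical SMILES, Morgan fingerprints, physicochemical
# descriptors and structural-alert matching.
#
# Structure handling is delegated to RDKit through a small bridge script
# shipped with the package (inst/python/chem_bridge.py) and executed with
# the system `python`. All exchange happens over JSON temp files, one
# batched call per operation, so process start-up cost is paid once per
# dataset rather than once per molecule.

chem_python <- function() {
  py <- Sys.getenv("SCREENVAL_PYTHON", "")
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) {
    stop("no `python` interpreter with RDKit found on PATH; ",
         "set SCREENVAL_PYTHON to point at one", call. = FALSE)
  }
  py
}

chem_bridge <- function(op, smiles, ...) {
  script <- system.file("python", "chem_bridge.py", package = "screenval")
  if (!nzchar(script)) stop("chem_bridge.py not found in installed package", call. = FALSE)
  # I() keeps length-1 vectors as JSON arrays under auto_unbox
  extra <- lapply(list(...), function(x) if (length(x) > 1 || is.character(x)) I(x) else x)
  req <- c(list(op = op, smiles = I(as.character(smiles))), extra)
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(req, fin, auto_unbox = TRUE, null = "null", digits = NA)
  status <- system2(chem_python(), c(shQuote(script), shQuote(fin), shQuote(fout)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0 || !file.exists(fout)) {
    stop(sprintf("chemistry bridge failed for op '%s' (exit %s)", op, status),
         call. = FALSE)
  }
  jsonlite::read_json(fout, simplifyVector = FALSE)
}

#' Canonicalize SMILES strings
#'
#' Parses each structure with RDKit and returns its canonical SMILES.
#' Unparsable structures yield `NA` rather than an error, so callers can
#' report and drop them.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES, `NA` where parsing failed.
#' @export
#' @examples
#' \dontrun{
#' canonical_smiles(c("C1=CC=CC=C1", "c1ccccc1"))  # identical output
#' }
canonical_smiles <- function(smiles) {
  if (length(smiles) == 0) return(character(0))
  res <- chem_bridge("canonicalize", smiles)
  vapply(res$canonical, function(x) if (is.null(x)) NA_character_ else x, character(1))
}

#' Structural alert catalog
#'
#' Reads the packaged catalog of REOS/Glaxo-type substructure alerts
#' (reactive, interference-prone or otherwise artifact-associated
#' functional groups) used by the filter benchmark in triage.
#'
#' @param path Optional path to an alternative tab-separated catalog with
#'   columns `catalog`, `rule_id`, `description`, `smarts`.
#' @return A tibble of alert rules.
#' @export
structural_alerts <- function(path = NULL) {
  path <- path %||% system.file("extdata", "structural_alerts.tsv", package = "screenval")
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  tibble::as_tibble(df)
}

#' Count structural-alert matches per compound
#'
#' Matches each compound against every SMARTS pattern of the alert
#' catalog and returns the number of distinct rules matched. Unparsable
#' structures count zero alerts and are flagged in the `ok` attribute.
#'
#' @param smiles Character vector of SMILES strings.
#' @param alerts Alert catalog tibble, see [structural_alerts()].
#' @return Integer vector of matched-rule counts.
#' @export
alert_counts <- function(smiles, alerts = structural_alerts()) {
  if (length(smiles) == 0) return(integer(0))
  res <- chem_bridge("alerts", smiles, smarts = alerts$smarts)
  counts <- vapply(res$counts, as.integer, integer(1))
  attr(counts, "ok") <- vapply(res$ok, isTRUE, logical(1))
  attr(counts, "catalog") <- unique(alerts$catalog)
  counts
}

# Morgan (extended-connectivity) fingerprints as 1-based set-bit indices.
chem_morgan_bits <- function(smiles, radius = 2, n_bits = 1024) {
  res <- chem_bridge("morgan", smiles, radius = radius, n_bits = n_bits)
  list(
    bits = lapply(res$bits, function(b) vapply(b, as.integer, integer(1))),
    ok = vapply(res$ok, isTRUE, logical(1))
  )
}

# Full descriptor table; NULLs (failed or non-finite descriptors) map to NA.
chem_descriptor_table <- function(smiles) {
  res <- chem_bridge("descriptors", smiles)
  names <- vapply(res$names, as.character, character(1))
  vals <- t(vapply(res$values, function(row) {
    vapply(row, function(v) if (is.null(v)) NA_real_ else as.numeric(v), numeric(1))
  }, numeric(length(names))))
  colnames(vals) <- names
  list(values = vals, ok = vapply(res$ok, isTRUE, logical(1)))
}
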