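# Screen tables: the canonical in-memory representation of an HTS dataset.
#
# A screen is a tibble with one row per compound and columns
#   compound_id        opaque unique identifier
#   smiles             structure string (may be NA for feature-first data)
#   activity_score     primary-screen readout on a 0-100 scale
#   primary_label      0/1 primary activity call
#   confirmatory_label 0/1 confirmatory call, NA when not screened
# plus the class "screen_tbl" and a `screen_name` attribute.

screen_columns <- c("compound_id", "smiles", "activity_score",
                    "primary_label", "confirmatory_label")

new_screen_tbl <- function(df, name = "screen", drop_report = NULL) {
  out <- tibble::as_tibble(df)[, screen_columns]
  class(out) <- c("screen_tbl", class(tibble::tibble()))
  attr(out, "screen_name") <- name
  attr(out, "drop_report") <- drop_report %||%
    tibble::tibble(reason = character(0), n = integer(0))
  out
}

validate_screen <- function(screen, require_smiles = FALSE) {
  missing <- setdiff(screen_columns, names(screen))
  if (length(missing) > 0) {
    stop("not a screen table; missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(screen$compound_id)) {
    stop("compound_id values must be unique", call. = FALSE)
  }
  if (any(!is.na(screen$confirmatory_label) & screen$primary_label != 1)) {
    stop("confirmatory labels are only defined for primary actives", call. = FALSE)
  }
  if (require_smiles && anyNA(screen$smiles)) {
    stop("screen has missing structures", call. = FALSE)
  }
  invisible(screen)
}

#' Drop/merge report of a screen table
#'
#' Loading and standardization record how many rows were dropped or
#' merged and why; this accessor returns that report.
#'
#' @param screen A screen table.
#' @return A tibble with columns `reason` and `n`.
#' @export
drop_report <- function(screen) {
  attr(screen, "drop_report") %||% tibble::tibble(reason = character(0), n = integer(0))
}

#' Read a screen CSV into a screen table
#'
#' Reads a comma-separated screen file (UTF-8, header row) with one row
#' per compound, maps its columns onto the standard schema, validates
#' structures and scores, and drops unusable rows with a report.
#' Activity scores are expected on a 0-100 scale; datasets reporting a
#' different scale are min-max rescaled to 0-100.
#'
#' @param path Path to the CSV file.
#' @param columns Named character vector mapping schema roles to file
#'   column names. Roles: `smiles`, `score`, `primary`, `confirmatory`
#'   (optional), `id` (optional; row numbers are used when absent).
#' @param validate_structures If `TRUE` (default) and a SMILES column is
#'   present, structures are parsed and unparsable rows dropped.
#' @param name Dataset name stored on the result.
#' @return A screen table; see [drop_report()] for dropped-row counts.
#' @export
read_screen <- function(path,
                        columns = c(smiles = "smiles", score = "score",
                                    primary = "primary", confirmatory = "confirmatory"),
                        validate_structures = TRUE,
                        name = tools::file_path_sans_ext(basename(path))) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (role in c("smiles", "score", "primary")) {
    col <- columns[[role]] %||% NA_character_
    if (is.na(col) || !col %in% names(raw)) {
      stop(sprintf("schema error: mandatory column '%s' (role %s) not in file",
                   col, role), call. = FALSE)
    }
  }
  drops <- list()
  n0 <- nrow(raw)

  score <- suppressWarnings(as.numeric(raw[[columns[["score"]]]]))
  primary <- suppressWarnings(as.integer(raw[[columns[["primary"]]]]))
  smiles <- as.character(raw[[columns[["smiles"]]]])
  conf_col <- columns["confirmatory"]
  confirmatory <- if (!is.na(conf_col) && conf_col %in% names(raw)) {
    suppressWarnings(as.integer(raw[[conf_col]]))
  } else {
    rep(NA_integer_, n0)
  }
  id_col <- columns["id"]
  ids <- if (!is.na(id_col) && id_col %in% names(raw)) {
    as.character(raw[[id_col]])
  } else {
    sprintf("row%06d", seq_len(n0))
  }

  smiles[!is.na(smiles) & !nzchar(smiles)] <- NA_character_
  keep <- !is.na(score) & !is.na(primary) & primary %in% c(0L, 1L)
  if (validate_structures) keep <- keep & !is.na(smiles)
  if (sum(!keep) > 0) drops$unparsable_row <- sum(!keep)

  if (validate_structures && any(keep)) {
    canon_ok <- !is.na(canonical_smiles(smiles[keep]))
    if (any(!canon_ok)) {
      drops$unparsable_structure <- sum(!canon_ok)
      keep[keep] <- canon_ok
    }
  }
  if (sum(keep) == 0) stop("empty dataset: no parseable rows in ", path, call. = FALSE)

  score <- score[keep]
  if (any(score < 0 | score > 100)) {
    rng <- range(score)
    score <- if (rng[2] > rng[1]) (score - rng[1]) / (rng[2] - rng[1]) * 100 else rep(50, length(score))
    drops$rescaled_scores <- length(score)
  }
  confirmatory[!is.na(confirmatory) & primary != 1L] <- NA_integer_

  report <- tibble::tibble(
    reason = names(drops) %||% character(0),
    n = as.integer(unlist(drops)) %||% integer(0)
  )
  new_screen_tbl(
    tibble::tibble(
      compound_id = ids[keep],
      smiles = smiles[keep],
      activity_score = score,
      primary_label = primary[keep],
      confirmatory_label = confirmatory[keep]
    ),
    name = name, drop_report = report
  )
}

#' Write a screen table to CSV
#'
#' Inverse of [read_screen()]: writes the five standard columns so that a
#' round trip reproduces the records field-for-field.
#'
#' @param screen A screen table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_screen <- function(screen, path) {
  validate_screen(screen)
  utils::write.csv(as.data.frame(screen)[, screen_columns], path,
                   row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Standardize structures and deduplicate a screen
#'
#' Replaces every SMILES by its canonical form, drops structures that
#' fail sanitization (with a logged reason), and merges records whose
#' canonical forms collide: the first occurrence is kept, labels are
#' aggregated by maximum (an active call wins), and the merge is counted
#' in the drop report. The operation is idempotent.
#'
#' @param screen A screen table with structures.
#' @return A standardized screen table.
#' @export
standardize_screen <- function(screen) {
  validate_screen(screen)
  if (nrow(screen) == 0) stop("cannot standardize an empty screen", call. = FALSE)
  canon <- canonical_smiles(screen$smiles)
  drops <- drop_report(screen)
  failed <- is.na(canon)
  if (any(failed)) {
    drops <- dplyr::bind_rows(drops,
      tibble::tibble(reason = "failed_sanitization", n = sum(failed)))
  }
  kept <- screen[!failed, ]
  kept$smiles <- canon[!failed]

  dup <- duplicated(kept$smiles)
  if (any(dup)) {
    agg <- kept |>
      dplyr::mutate(.ord = dplyr::row_number()) |>
      dplyr::group_by(.data$smiles) |>
      dplyr::summarise(
        compound_id = .data$compound_id[1],
        activity_score = .data$activity_score[1],
        primary_label = max(.data$primary_label),
        confirmatory_label = if (all(is.na(.data$confirmatory_label))) NA_integer_
          else max(.data$confirmatory_label, na.rm = TRUE),
        .ord = min(.data$.ord),
        .groups = "drop"
      ) |>
      dplyr::arrange(.data$.ord)
    drops <- dplyr::bind_rows(drops,
      tibble::tibble(reason = "merged_duplicate_structure", n = sum(dup)))
    kept <- agg[, screen_columns]
  }
  kept$confirmatory_label[kept$primary_label != 1L] <- NA_integer_
  new_screen_tbl(kept, name = attr(screen, "screen_name") %||% "screen",
                 drop_report = drops)
}

#' Build validation and initialization splits for a screen
#'
#' The validation set is the `val_fraction` of compounds with the highest
#' primary activity scores (the curation rule for valuation engines that
#' need a held-out set); ties at the boundary are broken by ascending
#' record index, so the split is deterministic. A stratified random
#' initialization subset of the training records, preserving the
#' active:inactive ratio, is drawn for active-learning starts.
#'
#' @param screen A screen table with at least 20 records and 1 active.
#' @param val_fraction Fraction held out by top score (default 0.10).
#' @param init_fraction Fraction for the stratified initial batch
#'   (default 0.015).
#' @param seed Integer seed driving the stratified draw.
#' @return An object of class `screen_splits`: a list with integer
#'   indices `train_idx`, `val_idx`, `init_idx` plus the resolved
#'   fractions and seed.
#' @export
screen_splits <- function(screen, val_fraction = 0.10, init_fraction = 0.015,
                          seed = 1) {
  validate_screen(screen)
  n <- nrow(screen)
  if (n < 20) stop("need at least 20 records to split", call. = FALSE)
  if (sum(screen$primary_label) < 1) stop("need at least one active", call. = FALSE)
  if (val_fraction <= 0 || val_fraction >= 1) stop("val_fraction outside (0,1)", call. = FALSE)
  if (init_fraction <= 0 || init_fraction >= 1) stop("init_fraction outside (0,1)", call. = FALSE)

  n_val <- round(val_fraction * n)
  ord <- order(-screen$activity_score, seq_len(n))
  val_idx <- sort(ord[seq_len(n_val)])
  train_idx <- setdiff(seq_len(n), val_idx)

  n_init <- max(1L, round(init_fraction * n))
  y_train <- screen$primary_label[train_idx]
  if (sum(y_train) == 0) stop("stratification error: no actives in training split", call. = FALSE)
  init_local <- stratified_sample(y_train, n_init, seed = derive_seed(seed, 11L))
  init_idx <- train_idx[init_local]

  structure(
    list(train_idx = train_idx, val_idx = val_idx, init_idx = init_idx,
         val_fraction = val_fraction, init_fraction = init_fraction, seed = seed),
    class = "screen_splits"
  )
}

#' @export
print.screen_splits <- function(x, ...) {
  cat(sprintf("<screen_splits> train %d | val %d (top %.0f%% score) | init %d\n",
              length(x$train_idx), length(x$val_idx), 100 * x$val_fraction,
              length(x$init_idx)))
  invisible(x)
}

#' @export
print.screen_tbl <- function(x, ...) {
  cat(sprintf("# screen '%s': %d compounds, %d primary actives, %d confirmatory-labeled\n",
              attr(x, "screen_name") %||% "screen", nrow(x),
              sum(x$primary_label == 1), sum(!is.na(x$confirmatory_label))))
  NextMethod()
}
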