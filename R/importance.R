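# Importance vectors: the common return type of all valuation engines.
# A tibble with one row per training record (index into the training
# matrix, score), carrying the engine, mode, seed and config as
# attributes so downstream workflows can orient rankings.

new_importance <- function(scores, engine, mode, seed, config = list(),
                           flags = NULL) {
  stopifnot(all(is.finite(scores)))
  out <- tibble::tibble(index = seq_along(scores), score = as.numeric(scores))
  class(out) <- c("importance_tbl", class(tibble::tibble()))
  attr(out, "engine") <- engine
  attr(out, "mode") <- mode
  attr(out, "seed") <- seed
  attr(out, "config") <- config
  attr(out, "flags") <- flags
  out
}

importance_engine <- function(x) attr(x, "engine")
importance_mode <- function(x) attr(x, "mode")

#' @export
print.importance_tbl <- function(x, ...) {
  cat(sprintf("# importance scores: engine=%s mode=%s seed=%s (%d samples)\n",
              attr(x, "engine"), attr(x, "mode"),
              format(attr(x, "seed")), nrow(x)))
  NextMethod()
}

#' Compute per-compound importance scores for a screen
#'
#' Front door over the five valuation engines. Trains on the training
#' split of the screen (all compounds minus the top-score validation
#' split) and returns one importance score per training compound.
#' Engines that need a held-out set (`knn_shapley`, `dvrl`,
#' `leaf_influence` in test mode, `tracin` in test/pos mode) use the
#' validation split.
#'
#' @param screen A screen table.
#' @param features Feature matrix row-aligned with `screen`.
#' @param engine One of `"mvsa"`, `"knn_shapley"`, `"leaf_influence"`,
#'   `"tracin"`, `"dvrl"`.
#' @param mode Engine mode: `"self"`, `"test"`, or (tracin only)
#'   `"pos"`. Defaults to each engine's natural mode.
#' @param splits A [screen_splits()] object; built with defaults when
#'   omitted.
#' @param seed Integer seed for the engine.
#' @param ... Engine-specific parameters passed through.
#' @return A tibble with columns `compound_id`, `index` (row in
#'   `screen`), `score`, plus engine metadata attributes.
#' @export
screen_importance <- function(screen, features,
                              engine = c("mvsa", "knn_shapley", "leaf_influence",
                                         "tracin", "dvrl"),
                              mode = NULL, splits = NULL, seed = 1, ...) {
  engine <- match.arg(engine)
  validate_screen(screen)
  stopifnot(nrow(features) == nrow(screen))
  splits <- splits %||% screen_splits(screen, seed = seed)
  tr <- splits$train_idx
  va <- splits$val_idx
  Xt <- features[tr, , drop = FALSE]
  yt <- screen$primary_label[tr]
  Xv <- features[va, , drop = FALSE]
  yv <- screen$primary_label[va]

  default_mode <- c(mvsa = "self", knn_shapley = "test", leaf_influence = "test",
                    tracin = "self", dvrl = "test")[[engine]]
  mode <- mode %||% default_mode
  if (engine == "knn_shapley" && mode != "test") {
    stop("knn_shapley only supports mode='test'", call. = FALSE)
  }
  if (mode == "pos" && engine != "tracin") {
    stop("mode='pos' is only valid for the tracin engine", call. = FALSE)
  }

  imp <- switch(engine,
    mvsa = mvsa_scores(Xt, yt, seed = seed, ...),
    knn_shapley = knn_shapley_scores(Xt, yt, Xv, yv, seed = seed, ...),
    leaf_influence = leaf_influence_scores(Xt, yt, mode = mode,
                                           X_target = Xv, y_target = yv,
                                           seed = seed, ...),
    tracin = tracin_scores(Xt, yt, X_val = Xv, y_val = yv, mode = mode,
                           seed = seed, ...),
    dvrl = dvrl_scores(Xt, yt, Xv, yv, seed = seed, ...)
  )
  out <- tibble::tibble(
    compound_id = screen$compound_id[tr],
    index = tr,
    score = imp$score
  )
  class(out) <- c("importance_tbl", class(tibble::tibble()))
  for (a in c("engine", "mode", "seed", "config", "flags")) {
    attr(out, a) <- attr(imp, a)
  }
  out
}

#' Write importance scores as CSV
#'
#' Emits the tidy score table (`compound_id,engine,mode,seed,score`) and
#' an engine-config JSON sidecar next to it.
#'
#' @param importance An importance table from [screen_importance()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_importance <- function(importance, path) {
  df <- tibble::tibble(
    compound_id = importance$compound_id %||% importance$index,
    engine = attr(importance, "engine"),
    mode = attr(importance, "mode"),
    seed = attr(importance, "seed"),
    score = importance$score
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  cfg <- attr(importance, "config") %||% list()
  jsonlite::write_json(cfg, paste0(tools::file_path_sans_ext(path), "_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
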