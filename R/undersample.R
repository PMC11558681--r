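# Importance-guided undersampling of the inactive majority class:
# importance is computed once on the full training set, then inactives
# are removed in steps of 5% of the original training size -- highest
# scores first, lowest first, or at random -- retraining a boosted-tree
# classifier after every step and tracking average precision on a
# held-out split. Actives are never removed; retained sets are strictly
# nested.

#' Run an undersampling trace
#'
#' @param screen A screen table.
#' @param X Feature matrix aligned with `screen`.
#' @param train_idx,val_idx Training and evaluation indices (disjoint).
#' @param policy `"drop_high"` (remove most important inactives first),
#'   `"drop_low"`, or `"random"`.
#' @param step Removal step as a fraction of the original training size
#'   (default 0.05).
#' @param max_removed Stop once this fraction of the original training
#'   set has been removed (default 0.95).
#' @param engine Valuation engine for the importance ranking (default
#'   `"mvsa"`, computed once up front on the full training set).
#' @param nrounds Boosting rounds of the evaluation classifier
#'   (default 100).
#' @param seed Integer seed (engine, random policy, classifier).
#' @return An `undersample_trace` tibble with columns `step`,
#'   `frac_removed`, `n_retained`, `avg_precision`; retained index sets
#'   are in the `retained` attribute and an `exhausted` attribute flags
#'   early stops.
#' @export
run_undersampling <- function(screen, X, train_idx, val_idx,
                              policy = c("drop_high", "drop_low", "random"),
                              step = 0.05, max_removed = 0.95,
                              engine = "mvsa", nrounds = 100, seed = 1) {
  policy <- match.arg(policy)
  validate_screen(screen)
  if (step <= 0 || step > 0.5) stop("step outside (0, 0.5]", call. = FALSE)
  if (max_removed >= 1) stop("max_removed must be < 1", call. = FALSE)
  if (length(intersect(train_idx, val_idx)) > 0) stop("train and val overlap", call. = FALSE)
  y <- screen$primary_label
  if (length(val_idx) == 0) stop("empty validation split", call. = FALSE)
  n_train0 <- length(train_idx)
  n_remove <- max(1L, round(step * n_train0))
  inact_local <- which(y[train_idx] == 0)
  if (length(inact_local) < n_remove) stop("training split has fewer inactives than one step", call. = FALSE)

  removal_order <- if (policy == "random") {
    withr::with_seed(derive_seed(seed, 51L), sample(inact_local))
  } else {
    imp <- switch(engine,
      mvsa = mvsa_scores(X[train_idx, , drop = FALSE], y[train_idx], seed = seed),
      stop("unsupported undersampling engine: ", engine, call. = FALSE)
    )
    sc <- imp$score[inact_local]
    if (policy == "drop_high") inact_local[order(-sc, inact_local)]
    else inact_local[order(sc, inact_local)]
  }

  Xv <- X[val_idx, , drop = FALSE]
  yv <- y[val_idx]
  fit_and_score <- function(keep_local) {
    m <- fit_gbm(X[train_idx[keep_local], , drop = FALSE], y[train_idx[keep_local]],
                 nrounds = nrounds, seed = seed)
    p <- gbm_predict(m, Xv)
    average_precision(ranks_from_scores(p, yv), length(yv))
  }

  keep <- seq_len(n_train0)
  retained <- list(train_idx[keep])
  rows <- list(tibble::tibble(step = 0L, frac_removed = 0,
                              n_retained = n_train0,
                              avg_precision = fit_and_score(keep)))
  max_steps <- floor(max_removed / step + 1e-9)
  exhausted <- FALSE
  for (s in seq_len(max_steps)) {
    chunk <- removal_order[seq.int((s - 1) * n_remove + 1,
                                   min(s * n_remove, length(removal_order)))]
    chunk <- chunk[!is.na(chunk)]
    keep <- setdiff(keep, chunk)
    if (s * n_remove >= length(removal_order)) exhausted <- TRUE
    retained[[s + 1]] <- train_idx[keep]
    rows[[s + 1]] <- tibble::tibble(
      step = s, frac_removed = (n_train0 - length(keep)) / n_train0,
      n_retained = length(keep), avg_precision = fit_and_score(keep))
    if (exhausted) break
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("undersample_trace", class(tibble::tibble()))
  attr(out, "retained") <- retained
  attr(out, "exhausted") <- exhausted
  attr(out, "config") <- list(policy = policy, step = step,
                              max_removed = max_removed, engine = engine,
                              nrounds = nrounds, seed = seed)
  out
}
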