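# Active learning over a compound library: iterative batch screening
# with random, greedy (predicted activity) or importance-based
# selection. The importance strategy scores the labeled pool with a
# valuation engine, fits a secondary regressor from features to
# importance, and screens the compounds predicted most important --
# deliberately sampling informative actives AND inactives instead of
# only likely actives.

#' Select the next screening batch
#'
#' @param labeled_idx Indices already screened.
#' @param remainder_idx Unscreened indices (nonempty).
#' @param X Feature matrix for the whole library.
#' @param y_labeled Primary labels revealed for `labeled_idx`.
#' @param strategy `"random"`, `"greedy"` or `"importance"`.
#' @param batch Batch size; if the remainder is smaller, the entire
#'   remainder is returned.
#' @param engine Valuation engine for the importance strategy
#'   (default `"mvsa"`; must be a self-mode engine).
#' @param regressor `"gaussian_process"` (default) or
#'   `"boosted_trees"`: the secondary model mapping features to
#'   importance.
#' @param nrounds Boosting rounds for greedy/boosted-trees fits
#'   (default 100).
#' @param seed Integer seed; identical inputs and seed give identical
#'   batches.
#' @return Integer vector of selected indices (subset of
#'   `remainder_idx`), with a `fallback` attribute when a single-class
#'   labeled set forced a random step.
#' @export
select_batch <- function(labeled_idx, remainder_idx, X, y_labeled,
                         strategy = c("random", "greedy", "importance"),
                         batch, engine = "mvsa",
                         regressor = c("gaussian_process", "boosted_trees"),
                         nrounds = 100, seed = 1) {
  strategy <- match.arg(strategy)
  regressor <- match.arg(regressor)
  if (length(remainder_idx) == 0) stop("remainder is empty", call. = FALSE)
  if (length(remainder_idx) <= batch) return(remainder_idx)

  random_pick <- function() {
    withr::with_seed(seed, sample(remainder_idx)[seq_len(batch)])
  }
  if (strategy == "random") return(random_pick())

  single_class <- length(unique(y_labeled)) < 2
  if (single_class) {
    out <- random_pick()
    attr(out, "fallback") <- "single-class labeled set: random step"
    return(out)
  }
  Xl <- X[labeled_idx, , drop = FALSE]
  Xr <- X[remainder_idx, , drop = FALSE]

  if (strategy == "greedy") {
    model <- fit_gbm(Xl, y_labeled, nrounds = nrounds, seed = seed)
    pred <- gbm_predict(model, Xr)
  } else {
    imp <- switch(engine,
      mvsa = mvsa_scores(Xl, y_labeled, seed = seed),
      tracin = tracin_scores(Xl, y_labeled, mode = "self", seed = seed),
      leaf_influence = leaf_influence_scores(Xl, y_labeled, mode = "self",
                                             seed = seed),
      stop("importance strategy needs a self-mode engine, got: ", engine,
           call. = FALSE)
    )
    pred <- tryCatch(
      if (regressor == "gaussian_process") {
        utils::capture.output(
          fit <- withr::with_seed(seed, suppressWarnings(
            kernlab::gausspr(x = Xl, y = imp$score, kernel = "rbfdot",
                             scaled = FALSE, variance.model = FALSE))))
        as.vector(kernlab::predict(fit, Xr))
      } else {
        d <- xgboost::xgb.DMatrix(Xl, label = imp$score, nthread = 1)
        m <- xgboost::xgb.train(
          params = list(objective = "reg:squarederror", eta = 0.1,
                        nthread = 1, seed = as.integer(seed)),
          data = d, nrounds = nrounds, verbose = 0)
        predict(m, xgboost::xgb.DMatrix(Xr, nthread = 1))
      },
      error = function(e) stop("regressor fit failed (strategy=importance): ",
                               conditionMessage(e), call. = FALSE)
    )
  }
  ord <- order(-pred, seq_along(pred))
  remainder_idx[ord[seq_len(batch)]]
}

#' Run an active-learning screening campaign
#'
#' Initializes with a stratified random batch of `round(step_fraction *
#' n)` compounds (preserving the library's active:inactive ratio), then
#' repeatedly selects batches of the same absolute size by the chosen
#' strategy, revealing primary labels after each step. The trace
#' records cumulative active retrieval per step.
#'
#' @param screen A screen table (>= 1 active).
#' @param X Feature matrix aligned with `screen`.
#' @param n_steps Number of selection steps after initialization.
#' @param strategy,engine,regressor,nrounds See [select_batch()].
#' @param step_fraction Batch size as a fraction of the library
#'   (default 0.015).
#' @param seed Integer seed; the whole trace is reproducible from
#'   (screen, config, seed).
#' @return A `campaign_trace` tibble with columns `step`, `n_selected`,
#'   `actives_step`, `cum_actives`, `cum_fraction`, `elapsed`; selected
#'   index sets are in the `selected` attribute.
#' @export
run_campaign <- function(screen, X, n_steps,
                         strategy = c("random", "greedy", "importance"),
                         step_fraction = 0.015, engine = "mvsa",
                         regressor = c("gaussian_process", "boosted_trees"),
                         nrounds = 100, seed = 1) {
  strategy <- match.arg(strategy)
  regressor <- match.arg(regressor)
  validate_screen(screen)
  if (step_fraction <= 0 || step_fraction >= 0.5) stop("step_fraction outside (0, 0.5)", call. = FALSE)
  # one trailing truncated batch is allowed, so only reject configs that
  # could not finish even with it
  if ((n_steps - 1) * step_fraction >= 1) stop("n_steps * step_fraction exceeds 1", call. = FALSE)
  y <- screen$primary_label
  n <- nrow(screen)
  n_act_total <- sum(y)
  if (n_act_total < 1) stop("need at least one active", call. = FALSE)
  batch <- max(1L, round(step_fraction * n))

  init <- stratified_sample(y, batch, seed = derive_seed(seed, 100L))
  selected <- list(init)
  labeled <- init
  rows <- list(tibble::tibble(
    step = 0L, n_selected = length(init), actives_step = sum(y[init]),
    cum_actives = sum(y[labeled]), cum_fraction = sum(y[labeled]) / n_act_total,
    elapsed = 0
  ))
  truncated <- FALSE
  fallbacks <- character(0)

  for (step in seq_len(n_steps)) {
    remainder <- setdiff(seq_len(n), labeled)
    if (length(remainder) == 0) break
    t0 <- proc.time()[["elapsed"]]
    picked <- select_batch(labeled, remainder, X, y[labeled],
                           strategy = strategy, batch = batch,
                           engine = engine, regressor = regressor,
                           nrounds = nrounds,
                           seed = derive_seed(seed, 100L + step))
    if (!is.null(attr(picked, "fallback"))) {
      fallbacks <- c(fallbacks, sprintf("step %d: %s", step, attr(picked, "fallback")))
    }
    if (length(picked) < batch) truncated <- TRUE
    labeled <- c(labeled, picked)
    selected[[step + 1]] <- as.integer(picked)
    rows[[step + 1]] <- tibble::tibble(
      step = step, n_selected = length(picked), actives_step = sum(y[picked]),
      cum_actives = sum(y[labeled]), cum_fraction = sum(y[labeled]) / n_act_total,
      elapsed = proc.time()[["elapsed"]] - t0
    )
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("campaign_trace", class(tibble::tibble()))
  attr(out, "selected") <- selected
  attr(out, "config") <- list(strategy = strategy, engine = engine,
                              regressor = regressor, step_fraction = step_fraction,
                              n_steps = n_steps, nrounds = nrounds, seed = seed)
  attr(out, "truncated") <- truncated
  attr(out, "fallbacks") <- fallbacks
  out
}

#' Write a campaign trace to CSV
#'
#' One row per step with the selected compound ids collapsed into a
#' `;`-separated field.
#'
#' @param trace A [run_campaign()] trace.
#' @param screen The screen the campaign ran on.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_campaign <- function(trace, screen, path) {
  sel <- attr(trace, "selected")
  df <- dplyr::mutate(
    tibble::as_tibble(trace),
    selected_ids = vapply(sel, function(ix) paste(screen$compound_id[ix], collapse = ";"),
                          character(1))
  )
  # wall time stays in the in-memory trace only; the primary output file
  # must be byte-identical across reruns with the same seed
  df$elapsed <- NULL
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
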