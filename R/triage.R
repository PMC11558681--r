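# False/true-positive triage: rank primary-screen actives by an
# importance vector (or a benchmark), nominate the extreme deciles as
# false-positive and true-positive candidates, and evaluate against
# confirmatory labels.
#
# Orientation is data, not code: each engine/mode declares whether a
# HIGH score marks a false positive. Self-importance methods (mvsa,
# tracin self, leaf_influence self -- whose active target set contains
# the removed sample, so a false positive's removal blows up its own
# target loss) put false positives at the TOP; methods that measure
# help for held-out predictions (knn_shapley, dvrl, tracin test/pos,
# leaf_influence test) put false positives at the BOTTOM.

#' Default engine orientation table
#'
#' @return A tibble with columns `engine`, `mode`, `high_is_fp`.
#' @export
engine_orientation <- function() {
  tibble::tribble(
    ~engine,          ~mode,  ~high_is_fp,
    "mvsa",           "self", TRUE,
    "tracin",         "self", TRUE,
    "tracin",         "test", FALSE,
    "tracin",         "pos",  FALSE,
    "knn_shapley",    "test", FALSE,
    "leaf_influence", "test", FALSE,
    "leaf_influence", "self", TRUE,
    "dvrl",           "test", FALSE
  )
}

#' Rank primary actives and nominate false/true positives
#'
#' Sorts the primary-screen actives covered by an importance vector (or
#' by a benchmark) into a false-positive-first and a true-positive-first
#' order, and nominates the extreme `decile_fraction` of each as FP and
#' TP candidates. Benchmarks: `"filters"` ranks actives by the number
#' of matched structural-alert patterns (more alerts = more FP-like;
#' needs structures), `"score"` by ascending activity score (lowest
#' score = most FP-like), `"random"` by a seeded shuffle.
#'
#' @param screen A screen table.
#' @param importance An importance table from [screen_importance()]
#'   covering all actives to rank, or `NULL` when using a benchmark.
#' @param benchmark `"filters"`, `"score"` or `"random"` (ignored when
#'   `importance` is given).
#' @param decile_fraction Fraction of actives nominated at each extreme
#'   (default 0.10; must be < 0.5 so the sets cannot overlap).
#' @param orientation Orientation table, see [engine_orientation()].
#' @param alerts Alert catalog for the filter benchmark.
#' @param seed Seed for the random benchmark.
#' @return A `triage_result`: list with `ranked` (tibble of actives with
#'   `fp_rank`, `tp_rank`, `nominated_as`), `fp_nominees`,
#'   `tp_nominees` (compound ids) and the resolved config.
#' @export
rank_candidates <- function(screen, importance = NULL,
                            benchmark = c("filters", "score", "random"),
                            decile_fraction = 0.10,
                            orientation = engine_orientation(),
                            alerts = structural_alerts(), seed = 1) {
  validate_screen(screen)
  if (decile_fraction <= 0 || decile_fraction >= 0.5) {
    stop("decile_fraction outside (0, 0.5)", call. = FALSE)
  }

  if (!is.null(importance)) {
    idx <- importance$index
    act_rows <- idx[screen$primary_label[idx] == 1]
    if (length(act_rows) == 0) stop("importance covers no actives", call. = FALSE)
    sc <- importance$score[match(act_rows, importance$index)]
    eng <- importance_engine(importance)
    mod <- importance_mode(importance)
    o <- orientation[orientation$engine == eng & orientation$mode == mod, ]
    if (nrow(o) != 1) {
      stop(sprintf("unknown engine orientation for %s/%s", eng, mod), call. = FALSE)
    }
    fp_score <- if (o$high_is_fp) sc else -sc
    method <- paste(eng, mod, sep = "_")
  } else {
    benchmark <- match.arg(benchmark)
    act_rows <- which(screen$primary_label == 1)
    fp_score <- switch(benchmark,
      filters = as.numeric(alert_counts(screen$smiles[act_rows], alerts)),
      score = -screen$activity_score[act_rows],
      random = withr::with_seed(derive_seed(seed, 41L),
                                stats::runif(length(act_rows)))
    )
    method <- paste0("benchmark_", benchmark)
  }

  n_act <- length(act_rows)
  fp_ord <- order(-fp_score, seq_len(n_act))   # most FP-like first
  fp_rank <- integer(n_act); fp_rank[fp_ord] <- seq_len(n_act)
  tp_rank <- n_act + 1L - fp_rank              # exact reversal
  n_nom <- max(1L, round(decile_fraction * n_act))
  nominated <- rep(NA_character_, n_act)
  nominated[fp_rank <= n_nom] <- "FP"
  nominated[tp_rank <= n_nom] <- "TP"

  ranked <- tibble::tibble(
    compound_id = screen$compound_id[act_rows],
    index = act_rows,
    score = if (!is.null(importance)) sc else fp_score,
    fp_rank = fp_rank,
    tp_rank = tp_rank,
    nominated_as = nominated,
    confirmatory_label = screen$confirmatory_label[act_rows]
  )
  structure(
    list(ranked = ranked,
         fp_nominees = ranked$compound_id[!is.na(nominated) & nominated == "FP"],
         tp_nominees = ranked$compound_id[!is.na(nominated) & nominated == "TP"],
         method = method, decile_fraction = decile_fraction,
         catalog = if (is.null(importance)) unique(alerts$catalog) else NULL),
    class = "triage_result"
  )
}

#' Evaluate a triage ranking against confirmatory labels
#'
#' Restricted to the confirmatory-labeled actives: the FP task treats
#' confirmatory = 0 as positive and uses the FP-first order, the TP
#' task treats confirmatory = 1 as positive and uses the TP-first
#' order. Reports precision over the nominated decile, relative
#' precision (precision minus the task base rate; a random ranking
#' scores 0), enrichment factor and BEDROC. Unlabeled actives keep
#' their ranks for nomination but are skipped in metric computation.
#'
#' @param result A [rank_candidates()] result.
#' @param alpha BEDROC alpha (default 20).
#' @param ef_fraction Enrichment-factor fraction (default 0.10).
#' @param k Precision cutoff over labeled actives: fraction or count
#'   (default the nomination decile fraction).
#' @return A tibble with one row per (task, metric), plus base rates;
#'   the `degenerate` attribute flags base rates of 0 or 1.
#' @export
evaluate_triage <- function(result, alpha = 20, ef_fraction = 0.10, k = NULL) {
  ranked <- result$ranked
  lab <- ranked[!is.na(ranked$confirmatory_label), ]
  if (nrow(lab) == 0) stop("no confirmatory-labeled actives to evaluate", call. = FALSE)
  k <- k %||% result$decile_fraction

  eval_task <- function(rank_col, positive_value) {
    ord <- order(lab[[rank_col]])
    labels <- as.integer(lab$confirmatory_label[ord] == positive_value)
    n <- length(labels)
    base <- mean(labels)
    if (base == 0 || base == 1) {
      return(tibble::tibble(metric = c("precision", "relative_precision",
                                       "enrichment_factor", "bedroc"),
                            value = NA_real_, base_rate = base,
                            degenerate = TRUE))
    }
    pr <- which(labels == 1)
    p <- precision_at(pr, n, k)
    tibble::tibble(
      metric = c("precision", "relative_precision", "enrichment_factor", "bedroc"),
      value = c(p$precision, p$relative_precision,
                enrichment_factor(pr, n, ef_fraction),
                if (length(pr) < n) bedroc(pr, n, alpha) else NA_real_),
      base_rate = base,
      degenerate = FALSE
    )
  }
  out <- dplyr::bind_rows(
    dplyr::mutate(eval_task("fp_rank", 0L), task = "false_positive"),
    dplyr::mutate(eval_task("tp_rank", 1L), task = "true_positive")
  )
  dplyr::relocate(out, "task")
}

#' Mean pairwise similarity within the FP nominee set
#'
#' Structural-diversity readout: mean pairwise Tanimoto similarity of
#' the fingerprint rows of the nominated false positives (lower =
#' more diverse nominees).
#'
#' @param result A [rank_candidates()] result.
#' @param X Binary fingerprint matrix aligned with the screen the
#'   result came from (rows named by compound id).
#' @return Mean pairwise Tanimoto similarity, `NA` if fewer than two
#'   nominees.
#' @export
fp_nominee_similarity <- function(result, X) {
  ids <- result$fp_nominees
  if (length(ids) < 2) return(NA_real_)
  M <- X[ids, , drop = FALSE]
  inter <- M %*% t(M)
  ones <- rowSums(M)
  uni <- outer(ones, ones, "+") - inter
  sim <- inter / pmax(uni, 1)
  mean(sim[upper.tri(sim)])
}

#' @export
print.triage_result <- function(x, ...) {
  cat(sprintf("<triage_result> method=%s | %d actives ranked | %d FP and %d TP nominees\n",
              x$method, nrow(x$ranked), length(x$fp_nominees), length(x$tp_nominees)))
  invisible(x)
}

#' Tidy a triage result
#'
#' @param x A `triage_result`.
#' @param ... Unused.
#' @return The ranked actives tibble.
#' @export
tidy.triage_result <- function(x, ...) x$ranked

#' Glance at a triage result
#'
#' @param x A `triage_result`.
#' @param ... Unused.
#' @return One-row tibble with method and nominee counts.
#' @export
glance.triage_result <- function(x, ...) {
  tibble::tibble(method = x$method, n_actives = nrow(x$ranked),
                 n_fp_nominees = length(x$fp_nominees),
                 n_tp_nominees = length(x$tp_nominees),
                 decile_fraction = x$decile_fraction)
}
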