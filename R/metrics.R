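# Early-recognition ranking metrics and the paired statistical
# comparison harness. All metrics are rank-based: they depend only on
# the positions of the positives in the ranking, never on raw scores.

check_ranks <- function(positive_ranks, n) {
  if (any(positive_ranks < 1 | positive_ranks > n) ||
      anyDuplicated(positive_ranks)) {
    stop("positive ranks must be distinct integers in 1..n", call. = FALSE)
  }
}

#' BEDROC early-recognition score
#'
#' Boltzmann-enhanced discrimination of the ROC: an exponentially
#' weighted measure of how early the positives appear in a ranking.
#' With weight `exp(-alpha * r / n)` on a positive at rank `r`, the
#' robust initial enhancement (RIE) is the ratio of the observed weight
#' sum to its expectation under a uniform ranking; BEDROC rescales RIE
#' between its attainable minimum and maximum so the result lies in
#' `[0, 1]`:
#' \deqn{RIE = \frac{\sum_i e^{-\alpha r_i / n}}{
#'   \frac{n_{pos}}{n}\,\frac{1 - e^{-\alpha}}{e^{\alpha/n} - 1}}}
#' \deqn{BEDROC = \frac{RIE \cdot R_a \sinh(\alpha/2)}{\cosh(\alpha/2) -
#'   \cosh(\alpha/2 - \alpha R_a)} + \frac{1}{1 - e^{\alpha (1 - R_a)}}}
#' with \eqn{R_a = n_{pos}/n}.
#'
#' @param positive_ranks Ranks (1 = best) of the positives.
#' @param n Total length of the ranking.
#' @param alpha Early-recognition weight parameter (default 20; roughly
#'   the top 8% of the list accounts for 80% of the score).
#' @return A number in `[0, 1]`.
#' @export
bedroc <- function(positive_ranks, n, alpha = 20) {
  n_pos <- length(positive_ranks)
  if (n_pos == 0 || n_pos >= n) stop("degenerate ranking: need 1 <= n_pos < n", call. = FALSE)
  if (alpha <= 0) stop("alpha must be positive", call. = FALSE)
  check_ranks(positive_ranks, n)
  ra <- n_pos / n
  s <- sum(exp(-alpha * positive_ranks / n))
  rie <- s / (ra * n * (1 - exp(-alpha)) / (exp(alpha / n) - 1) / n)
  rie * ra * sinh(alpha / 2) / (cosh(alpha / 2) - cosh(alpha / 2 - alpha * ra)) +
    1 / (1 - exp(alpha * (1 - ra)))
}

#' Enrichment factor at a top fraction
#'
#' Hit rate among the top `ceiling(fraction * n)` ranked items divided by
#' the overall hit rate. EF equals 1 for a ranking no better than
#' uniform and is bounded by `min(1/fraction, n/n_pos)`.
#'
#' @inheritParams bedroc
#' @param fraction Top fraction of the ranking considered (default 0.10).
#' @return The enrichment factor.
#' @export
enrichment_factor <- function(positive_ranks, n, fraction = 0.10) {
  n_pos <- length(positive_ranks)
  if (n_pos == 0) stop("no positives: enrichment undefined", call. = FALSE)
  if (fraction * n < 1) stop("fraction * n must be at least 1", call. = FALSE)
  check_ranks(positive_ranks, n)
  cutoff <- ceiling(fraction * n)
  (sum(positive_ranks <= cutoff) / cutoff) / (n_pos / n)
}

#' Precision and relative precision at a cutoff
#'
#' Precision over the top `k` ranked items, and relative precision =
#' precision minus the base rate (the expected precision of a random
#' ordering), so random performance maps to 0.
#'
#' @inheritParams bedroc
#' @param k Cutoff: an integer count, or a fraction in (0,1) interpreted
#'   as `round(k * n)`.
#' @return A list with `precision`, `relative_precision`, `base_rate`,
#'   `cutoff`.
#' @export
precision_at <- function(positive_ranks, n, k = 0.10) {
  n_pos <- length(positive_ranks)
  cutoff <- if (k < 1) max(1L, round(k * n)) else as.integer(k)
  if (cutoff < 1 || cutoff > n) stop("cutoff outside 1..n", call. = FALSE)
  check_ranks(positive_ranks, n)
  prec <- sum(positive_ranks <= cutoff) / cutoff
  base <- n_pos / n
  list(precision = prec, relative_precision = prec - base,
       base_rate = base, cutoff = cutoff)
}

#' Average precision of a ranking
#'
#' Step-interpolated area under the precision-recall curve: the mean,
#' over positives, of the precision at each positive's rank. Invariant
#' to negatives appended after the last positive.
#'
#' @inheritParams bedroc
#' @return A number in `(0, 1]`.
#' @export
average_precision <- function(positive_ranks, n) {
  n_pos <- length(positive_ranks)
  if (n_pos == 0 || n_pos >= n) stop("need at least one positive and one negative", call. = FALSE)
  check_ranks(positive_ranks, n)
  r <- sort(positive_ranks)
  mean(seq_along(r) / r)
}

# Ranks of positives induced by descending scores; ties broken by
# ascending index (stable), so metrics are deterministic.
ranks_from_scores <- function(scores, labels) {
  ord <- order(-scores, seq_along(scores))
  which(labels[ord] == 1)
}

#' Ranking metrics from scores and labels
#'
#' Convenience wrapper computing all four ranking metrics from raw
#' scores (higher = ranked earlier) and binary labels. Score ties are
#' broken by ascending index before ranking.
#'
#' @param scores Numeric scores, higher first.
#' @param labels Binary 0/1 labels aligned with `scores`.
#' @param alpha BEDROC alpha (default 20).
#' @param ef_fraction Enrichment-factor top fraction (default 0.10).
#' @param k Precision cutoff count or fraction (default 0.10).
#' @return A one-row tibble of metric values.
#' @export
ranking_metrics <- function(scores, labels, alpha = 20, ef_fraction = 0.10, k = 0.10) {
  n <- length(scores)
  pr <- ranks_from_scores(scores, labels)
  p <- precision_at(pr, n, k)
  tibble::tibble(
    precision = p$precision,
    relative_precision = p$relative_precision,
    base_rate = p$base_rate,
    enrichment_factor = enrichment_factor(pr, n, ef_fraction),
    bedroc = bedroc(pr, n, alpha),
    average_precision = average_precision(pr, n)
  )
}

#' Paired comparison of methods across replicates
#'
#' The statistical harness used by every workflow: an omnibus Friedman
#' rank test across all methods first, then pairwise two-tailed Wilcoxon
#' signed-rank tests of each method against a reference, with
#' Benjamini-Hochberg (step-up false-discovery) adjustment across the
#' pairwise family at level 0.05. Zero paired differences follow the
#' discard-zeros convention; a pair whose differences are all zero is
#' flagged degenerate with p = 1.
#'
#' @param data A data frame with one observation per method and
#'   replicate (or dataset).
#' @param method,replicate,value Column names (strings) identifying the
#'   method, the pairing unit, and the measured value.
#' @param reference Reference method name for pairwise tests (default:
#'   first method in the data).
#' @return An object of class `method_comparison`; see
#'   [tidy.method_comparison()] and [glance.method_comparison()].
#' @export
method_comparison <- function(data, method = "method", replicate = "replicate",
                              value = "value", reference = NULL) {
  df <- tibble::tibble(
    method = as.character(data[[method]]),
    replicate = data[[replicate]],
    value = as.numeric(data[[value]])
  )
  methods <- unique(df$method)
  if (length(methods) < 2) stop("need at least two methods to compare", call. = FALSE)
  wide <- tidyr::pivot_wider(df, names_from = "method", values_from = "value")
  if (anyNA(wide[methods])) stop("unpaired observations: every method needs a value per replicate", call. = FALSE)
  reference <- reference %||% methods[1]
  if (!reference %in% methods) stop("unknown reference method: ", reference, call. = FALSE)

  m <- as.matrix(wide[methods])
  omnibus <- stats::friedman.test(m)

  others <- setdiff(methods, reference)
  pw <- purrr::map_dfr(others, function(meth) {
    d <- m[, meth] - m[, reference]
    if (all(d == 0)) {
      tibble::tibble(method = meth, reference = reference,
                     statistic = NA_real_, p_value = 1.0, degenerate = TRUE)
    } else {
      wt <- suppressWarnings(
        stats::wilcox.test(m[, meth], m[, reference], paired = TRUE,
                           alternative = "two.sided")
      )
      tibble::tibble(method = meth, reference = reference,
                     statistic = unname(wt$statistic), p_value = wt$p.value,
                     degenerate = FALSE)
    }
  })
  pw$p_adjusted <- stats::p.adjust(pw$p_value, method = "BH")

  structure(
    list(omnibus = omnibus, pairwise = pw, reference = reference,
         n_replicates = nrow(wide), methods = methods),
    class = "method_comparison"
  )
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("Friedman chi-squared = %.4g, df = %d, p = %.3g (%d methods, %d replicates)\n",
              unname(x$omnibus$statistic), unname(x$omnibus$parameter),
              x$omnibus$p.value, length(x$methods), x$n_replicates))
  cat(sprintf("Pairwise signed-rank vs '%s' (BH-adjusted):\n", x$reference))
  print(x$pairwise)
  invisible(x)
}

#' Tidy a method comparison
#'
#' @param x A [method_comparison()] result.
#' @param ... Unused.
#' @return The pairwise test tibble (statistic, raw and adjusted p).
#' @export
tidy.method_comparison <- function(x, ...) x$pairwise

#' Glance at a method comparison
#'
#' @param x A [method_comparison()] result.
#' @param ... Unused.
#' @return One-row tibble with the omnibus Friedman test.
#' @export
glance.method_comparison <- function(x, ...) {
  tibble::tibble(
    statistic = unname(x$omnibus$statistic),
    df = unname(x$omnibus$parameter),
    p_value = x$omnibus$p.value,
    n_methods = length(x$methods),
    n_replicates = x$n_replicates
  )
}
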