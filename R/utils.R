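# Internal helpers shared across modules.

sigmoid <- function(x) 1 / (1 + exp(-x))

# Mean binary log-loss with clipping for numerical safety.
logloss <- function(p, y, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# Derive a reproducible sub-seed from a base seed and an integer offset,
# kept inside the 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) %% 1e6) * 1009 + 104729 * (offset %% 1000) + offset) %% .Machine$integer.max
}

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_binary_labels <- function(y, arg = "y") {
  if (!all(y %in% c(0, 1))) {
    stop(sprintf("`%s` must be binary 0/1 labels", arg), call. = FALSE)
  }
  if (length(unique(y)) < 2) {
    stop(sprintf("`%s` must contain both classes", arg), call. = FALSE)
  }
  invisible(TRUE)
}

# Stratified random subset of size n_pick preserving the active:inactive
# ratio (active count rounded to the nearest integer). Returns indices
# into `labels`.
stratified_sample <- function(labels, n_pick, seed) {
  n <- length(labels)
  if (n_pick < 1 || n_pick > n) stop("invalid stratified sample size", call. = FALSE)
  act <- which(labels == 1)
  inact <- which(labels == 0)
  if (length(act) == 0) stop("stratification error: no actives in pool", call. = FALSE)
  n_act <- round(n_pick * length(act) / n)
  n_act <- min(max(n_act, 0L), length(act), n_pick)
  n_in <- n_pick - n_act
  if (n_in > length(inact)) {
    n_in <- length(inact)
    n_act <- n_pick - n_in
  }
  withr::with_seed(seed, {
    picked <- c(
      if (n_act > 0) sample(act, n_act) else integer(0),
      if (n_in > 0) sample(inact, n_in) else integer(0)
    )
  })
  sort(picked)
}

# Rank-based area under the ROC curve (Wilcoxon statistic form).
auc_score <- function(scores, labels) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUC undefined for single-class labels", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
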