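# Leaf influence: leave-one-out influence of each training sample on a
# target set's loss, under a frozen tree ensemble. The tree structures
# (split decisions, hence leaf assignments) come from a fitted boosted
# model and are held fixed; leaf values are re-derived from the
# second-order statistics v_L = -eta * sum(g) / (sum(h) + lambda).
# Removing sample j removes its g/h contribution from its leaf at every
# round, and the resulting prediction deltas are propagated to the
# g/h statistics of all subsequent rounds (an exact sequential refit of
# the leaf values; only the structures are approximate with respect to
# full retraining).
#
# Sign convention: score_j = loss_target(without j) - loss_target(full),
# so positive means removal hurts the target (the sample is helpful).

# Precompute per-round integer leaf-group indices for the training and
# target sets. Every leaf of a tree carries training mass, so training
# groups enumerate all leaves; target rows falling outside get NA.
leaf_groups <- function(leaf_train, leaf_target) {
  nt <- ncol(leaf_train)
  grp_tr <- matrix(0L, nrow(leaf_train), nt)
  grp_tg <- matrix(NA_integer_, nrow(leaf_target), nt)
  n_grp <- integer(nt)
  for (t in seq_len(nt)) {
    ul <- sort(unique(leaf_train[, t]))
    grp_tr[, t] <- match(leaf_train[, t], ul)
    grp_tg[, t] <- match(leaf_target[, t], ul)
    n_grp[t] <- length(ul)
  }
  list(train = grp_tr, target = grp_tg, n = n_grp)
}

# Sequential frozen-structure refit; `drop` excludes one training index
# from the leaf statistics. Returns target margins.
frozen_refit_margins <- function(groups, y, eta, lambda, drop = 0L) {
  n <- length(y)
  f_train <- numeric(n)
  f_target <- numeric(nrow(groups$target))
  w <- rep(1, n)
  if (drop > 0) w[drop] <- 0
  for (t in seq_len(ncol(groups$train))) {
    p <- sigmoid(f_train)
    g <- (p - y) * w
    h <- p * (1 - p) * w
    grp <- groups$train[, t]
    gs <- rowsum(g, grp, reorder = TRUE)[, 1]
    hs <- rowsum(h, grp, reorder = TRUE)[, 1]
    vals <- -eta * gs / (hs + lambda)
    f_train <- f_train + vals[grp]
    add_tg <- vals[groups$target[, t]]
    add_tg[is.na(add_tg)] <- 0
    f_target <- f_target + add_tg
  }
  f_target
}

#' Leaf-influence importance scores
#'
#' For each training sample, approximates the change in the target
#' set's binary log-loss if that sample were removed, keeping the tree
#' structures of a fitted gradient-boosted model frozen and re-deriving
#' leaf values round by round. `mode = "test"` targets an external
#' validation set; `mode = "self"` targets the active training samples
#' (self-importance). Positive score = removal increases target loss
#' (the sample is helpful); false positives therefore score low,
#' especially in self mode.
#'
#' @param X,y Training features and binary labels.
#' @param mode `"test"` (external target set) or `"self"` (training
#'   actives as target).
#' @param X_target,y_target Target features/labels, required for
#'   `mode = "test"`.
#' @param nrounds Boosting rounds of the underlying model (default 100).
#' @param eta Learning rate / leaf shrinkage (default 0.1).
#' @param lambda L2 leaf regularization (default 1).
#' @param seed Integer seed for the tree backend.
#' @return An importance table.
#' @export
leaf_influence_scores <- function(X, y, mode = c("test", "self"),
                                  X_target = NULL, y_target = NULL,
                                  nrounds = 100, eta = 0.1, lambda = 1,
                                  seed = 1) {
  mode <- match.arg(mode)
  assert_binary_labels(y)
  if (mode == "self") {
    act <- which(y == 1)
    if (length(act) == 0) stop("no active training samples for self mode", call. = FALSE)
    X_target <- X[act, , drop = FALSE]
    y_target <- y[act]
  }
  if (is.null(X_target) || nrow(X_target) == 0) {
    stop("target set is empty", call. = FALSE)
  }
  model <- fit_gbm(X, y, nrounds = nrounds, eta = eta, lambda = lambda,
                   seed = seed)
  groups <- leaf_groups(gbm_leaf_indices(model, X),
                        gbm_leaf_indices(model, X_target))
  f_full <- frozen_refit_margins(groups, y, eta, lambda)
  loss_full <- logloss(sigmoid(f_full), y_target)
  scores <- vapply(seq_len(nrow(X)), function(j) {
    f_j <- frozen_refit_margins(groups, y, eta, lambda, drop = j)
    logloss(sigmoid(f_j), y_target) - loss_full
  }, numeric(1))
  new_importance(scores, engine = "leaf_influence", mode = mode, seed = seed,
                 config = list(nrounds = nrounds, eta = eta, lambda = lambda))
}
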