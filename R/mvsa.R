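# MVS-A: sample importance from the per-round loss gradients and
# Hessians of a gradient-boosted tree classifier. Every boosting round
# acts as a checkpoint; a sample that keeps receiving large regularized
# gradients is one the ensemble keeps struggling with, which is exactly
# the signature of label noise / false positives (high self-importance).

# The per-round combination rule, isolated so it can be swapped: the
# minimal-variance-sampling regularized gradient sqrt(g^2 + lambda h^2).
mvsa_combine <- function(g, h, lambda) {
  sqrt(g^2 + lambda * h^2)
}

#' MVS-A importance scores
#'
#' Trains a gradient-boosted tree classifier (binary log-loss) and
#' accumulates, for every training sample j and boosting round i, the
#' regularized gradient magnitude
#' \deqn{score_j = \sum_i \sqrt{g_{ij}^2 + \lambda h_{ij}^2}}
#' where `g = p - y` and `h = p (1 - p)` are evaluated at the model's
#' running prediction before round i. Round 1 uses the constant 0.5
#' initialization, so its contribution is identical for every sample.
#' Higher score means larger self-importance; among primary actives,
#' false positives rank high.
#'
#' @param X Feature matrix (training samples by features).
#' @param y Binary 0/1 labels, both classes present.
#' @param nrounds Boosting rounds / checkpoints (default 100).
#' @param lambda L2 leaf regularization, also the Hessian weight in the
#'   score (default 1).
#' @param colsample_bytree Column subsampling per tree (default 0.95).
#' @param eta Learning rate of the backend (default 0.1).
#' @param seed Integer seed for the tree backend.
#' @return An importance table (one row per training sample).
#' @export
mvsa_scores <- function(X, y, nrounds = 100, lambda = 1,
                        colsample_bytree = 0.95, eta = 0.1, seed = 1) {
  assert_binary_labels(y)
  if (!all(is.finite(X))) stop("non-finite feature values", call. = FALSE)
  model <- fit_gbm(X, y, nrounds = nrounds, eta = eta, lambda = lambda,
                   colsample_bytree = colsample_bytree, seed = seed)
  probs <- gbm_round_probs(model, X, nrounds)
  g <- probs - y            # recycled by column
  h <- probs * (1 - probs)
  scores <- rowSums(mvsa_combine(g, h, lambda))
  new_importance(scores, engine = "mvsa", mode = "self", seed = seed,
                 config = list(nrounds = nrounds, lambda = lambda,
                               colsample_bytree = colsample_bytree, eta = eta))
}
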