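# Thin wrappers around the xgboost backend used by the MVS-A and
# leaf-influence engines, the greedy active-learning selector, the
# undersampling classifier and the DVRL predictor.
#
# base_score is pinned to 0.5 so the round-0 margin is exactly zero for
# every sample (constant initialization), which the per-round gradient
# bookkeeping of the valuation engines relies on.

gbm_params <- function(eta = 0.1, lambda = 1, colsample_bytree = 1,
                       max_depth = 6, seed = 1, ...) {
  list(objective = "binary:logistic", eta = eta, lambda = lambda,
       colsample_bytree = colsample_bytree, max_depth = max_depth,
       base_score = 0.5, nthread = 1, seed = as.integer(seed), ...)
}

fit_gbm <- function(X, y, nrounds = 100, ...) {
  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  xgboost::xgb.train(params = gbm_params(...), data = dtrain,
                     nrounds = nrounds, verbose = 0)
}

gbm_predict <- function(model, X, iterationrange = NULL) {
  d <- xgboost::xgb.DMatrix(X, nthread = 1)
  if (is.null(iterationrange)) predict(model, d)
  else predict(model, d, iterationrange = iterationrange)
}

# Leaf index per sample and boosting round (n x nrounds).
gbm_leaf_indices <- function(model, X) {
  d <- xgboost::xgb.DMatrix(X, nthread = 1)
  m <- predict(model, d, predleaf = TRUE)
  if (is.null(dim(m))) m <- matrix(m, nrow = nrow(X))
  m
}

# Probability predictions before each boosting round: column i holds
# p_{i-1}, the model's output using the first i-1 trees (column 1 is the
# constant 0.5 initialization). Dimensions n x nrounds.
gbm_round_probs <- function(model, X, nrounds) {
  n <- nrow(X)
  out <- matrix(0.5, nrow = n, ncol = nrounds)
  if (nrounds >= 2) {
    d <- xgboost::xgb.DMatrix(X, nthread = 1)
    for (i in 2:nrounds) {
      out[, i] <- predict(model, d, iterationrange = c(1, i - 1))
    }
  }
  out
}
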