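# Independent oracles used by both the unit and the acceptance tests.
# They never call the implementation paths they check.

# Exact Shapley values by enumerating all training subsets under the
# KNN utility v(S) = (1/K) sum_{k<=min(K,|S|)} 1[label match], v({})=0.
enum_shapley <- function(X_train, y_train, x_val, y_val, k) {
  n <- nrow(X_train)
  d <- sqrt(colSums((t(X_train) - x_val)^2))
  util <- function(S) {
    if (length(S) == 0) return(0)
    ordS <- S[order(d[S], S)]
    sum(y_train[ordS[seq_len(min(k, length(S)))]] == y_val) / k
  }
  vapply(seq_len(n), function(j) {
    others <- setdiff(seq_len(n), j)
    phi <- 0
    for (m in 0:(n - 1)) {
      w <- factorial(m) * factorial(n - m - 1) / factorial(n)
      subs <- if (m == 0) list(integer(0)) else utils::combn(others, m, simplify = FALSE)
      for (S in subs) phi <- phi + w * (util(c(S, j)) - util(S))
    }
    phi
  }, numeric(1))
}

# Brute-force frozen-structure leave-one-out for a single boosted tree:
# re-derive leaf values without sample j and measure the target loss
# change directly.
single_tree_loo <- function(X, y, X_target, y_target, eta, lambda, seed) {
  m <- screenval:::fit_gbm(X, y, nrounds = 1, eta = eta, lambda = lambda,
                           seed = seed)
  lt <- screenval:::gbm_leaf_indices(m, X)[, 1]
  lg <- screenval:::gbm_leaf_indices(m, X_target)[, 1]
  loss_without <- function(drop) {
    w <- rep(1, nrow(X)); if (drop > 0) w[drop] <- 0
    g <- (0.5 - y) * w        # p0 = 0.5 under constant initialization
    h <- 0.25 * w
    leaves <- sort(unique(lt))
    vals <- vapply(leaves, function(L) {
      -eta * sum(g[lt == L]) / (sum(h[lt == L]) + lambda)
    }, numeric(1))
    f <- vals[match(lg, leaves)]
    f[is.na(f)] <- 0
    p <- stats::plogis(f)
    -mean(y_target * log(p) + (1 - y_target) * log(1 - p))
  }
  full <- loss_without(0)
  vapply(seq_len(nrow(X)), function(j) loss_without(j) - full, numeric(1))
}

# Separable binary-feature screen with planted label flips, the
# standard instance for self-importance recovery checks.
make_planted_flip_set <- function(n, d, n_flips, seed) {
  withr::with_seed(seed, {
    cl <- stats::rbinom(n, 1, 0.3)
    X <- matrix(stats::rbinom(n * d, 1, 0.1), n)
    X[cl == 1, 1:8] <- matrix(stats::rbinom(sum(cl == 1) * 8, 1, 0.9), ncol = 8)
    y <- cl
    flip <- sample(which(y == 0), n_flips)
    y[flip] <- 1
  })
  list(X = X, y = y, flip = flip)
}
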