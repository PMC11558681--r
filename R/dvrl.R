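# DVRL: data valuation by reinforcement learning. A value-estimator
# network maps each training sample to a selection probability; each
# iteration draws selection masks by those probabilities, fits a
# boosted-tree predictor on every selected subset, measures
# area-under-ROC on the validation set, and updates the estimator by a
# score-function (REINFORCE) gradient. Three stabilizers make the
# estimator learnable at desk scale:
#   * marginal information: |y - baseline prediction| from a predictor
#     trained once on the full training set enters the estimator just
#     before its combining layer, giving label-noise a short path to
#     the output;
#   * several selection rollouts per iteration, with the rollout-mean
#     reward as baseline (variance-reduced score-function estimator);
#   * an exploration penalty that pushes the mean selection probability
#     back inside [1-threshold, threshold], preventing the degenerate
#     select-everything optimum.
# Estimator: (x, y) -> dense(hidden_dim) -> dense(hidden_dim)
#            -> concat(marginal) -> dense(comb_dim) -> sigmoid.
# Leaky rectified-linear activations with a small positive bias
# initialization keep the narrow combining layer from dying.

dvrl_init <- function(d_in, hidden_dim, comb_dim, seed) {
  ini <- function(a, b) matrix(stats::rnorm(a * b, 0, sqrt(2 / a)), a)
  withr::with_seed(seed, list(
    W1 = ini(d_in, hidden_dim), b1 = rep(0.05, hidden_dim),
    W2 = ini(hidden_dim, hidden_dim), b2 = rep(0.05, hidden_dim),
    W3 = ini(hidden_dim + 1, comb_dim), b3 = rep(0.05, comb_dim),
    W4 = ini(comb_dim, 1), b4 = 0
  ))
}

dvrl_act <- function(x) pmax(x, 0.01 * x)
dvrl_dact <- function(x) ifelse(x > 0, 1, 0.01)

dvrl_forward <- function(pr, Z, marginal) {
  z1 <- sweep(Z %*% pr$W1, 2, pr$b1, "+"); a1 <- dvrl_act(z1)
  z2 <- sweep(a1 %*% pr$W2, 2, pr$b2, "+"); a2 <- dvrl_act(z2)
  a2m <- cbind(a2, marginal)
  z3 <- sweep(a2m %*% pr$W3, 2, pr$b3, "+"); a3 <- dvrl_act(z3)
  z4 <- as.vector(a3 %*% pr$W4 + pr$b4)
  list(z1 = z1, a1 = a1, z2 = z2, a2 = a2, a2m = a2m, z3 = z3, a3 = a3,
       p = sigmoid(z4))
}

dvrl_backward <- function(pr, ca, dz4, Z) {
  g <- list()
  g$W4 <- crossprod(ca$a3, matrix(dz4, ncol = 1)); g$b4 <- sum(dz4)
  d3 <- (matrix(dz4, ncol = 1) %*% t(pr$W4)) * dvrl_dact(ca$z3)
  g$W3 <- crossprod(ca$a2m, d3); g$b3 <- colSums(d3)
  d2m <- d3 %*% t(pr$W3)
  d2 <- d2m[, seq_len(ncol(ca$a2)), drop = FALSE] * dvrl_dact(ca$z2)
  g$W2 <- crossprod(ca$a1, d2); g$b2 <- colSums(d2)
  d1 <- (d2 %*% t(pr$W2)) * dvrl_dact(ca$z1)
  g$W1 <- crossprod(Z, d1); g$b1 <- colSums(d1)
  g
}

#' DVRL importance scores
#'
#' Trains the reinforcement-learning value estimator and returns its
#' final selection probabilities as importance scores in `[0, 1]`;
#' harmful or noisy samples receive low probabilities. Defaults here
#' are reduced-scale for desk-sized runs; the full-scale setting
#' (1000 iterations, batch 5000) is configurable.
#'
#' @param X,y Training features and binary labels.
#' @param X_val,y_val Validation features/labels; the reward is the
#'   predictor's ROC-AUC here, so both classes must be present.
#' @param iterations Outer reinforcement iterations (default 200;
#'   full-scale 1000).
#' @param batch_size Training samples considered per iteration
#'   (default 256, capped at n; full-scale 5000).
#' @param n_rollouts Selection masks drawn per iteration; the rollout
#'   mean serves as the reward baseline (default 6).
#' @param hidden_dim Width of the two hidden estimator layers
#'   (default 100).
#' @param comb_dim Width of the combining layer that receives the
#'   marginal information (default 10).
#' @param lr Estimator learning rate (default 0.01, Adam).
#' @param predictor_nrounds,predictor_max_depth Boosted-tree predictor
#'   per rollout (defaults 50 rounds, depth 6).
#' @param exploration_weight,exploration_threshold Penalty pushing the
#'   mean selection probability inside
#'   `[1 - threshold, threshold]` (defaults 5 and 0.9).
#' @param prob_clip Clipping bounds on selection probabilities so
#'   sampling never degenerates (default `c(1e-3, 1 - 1e-3)`).
#' @param seed Integer seed; fixed seed and single-threaded execution
#'   give an identical score vector on rerun.
#' @return An importance table with scores in `[0, 1]`.
#' @export
dvrl_scores <- function(X, y, X_val, y_val, iterations = 200,
                        batch_size = 256, n_rollouts = 6, hidden_dim = 100,
                        comb_dim = 10, lr = 0.01, predictor_nrounds = 50,
                        predictor_max_depth = 6, exploration_weight = 5,
                        exploration_threshold = 0.9,
                        prob_clip = c(1e-3, 1 - 1e-3), seed = 1) {
  assert_binary_labels(y)
  if (length(unique(y_val)) < 2) {
    stop("degenerate reward: validation labels are constant", call. = FALSE)
  }
  n <- nrow(X)
  pred_seed <- derive_seed(seed, 33L)
  base_model <- fit_gbm(X, y, nrounds = predictor_nrounds,
                        max_depth = predictor_max_depth, seed = pred_seed)
  marginal <- abs(y - gbm_predict(base_model, X))
  Z <- cbind(X, y)
  params <- dvrl_init(ncol(Z), hidden_dim, comb_dim, derive_seed(seed, 31L))
  m_st <- lapply(params, function(x) x * 0)
  v_st <- lapply(params, function(x) x * 0)
  t_st <- 0
  clip <- function(p) pmin(pmax(p, prob_clip[1]), prob_clip[2])
  rewards <- numeric(0)

  withr::with_seed(derive_seed(seed, 32L), {
    for (it in seq_len(iterations)) {
      idx <- if (batch_size < n) sample.int(n, batch_size) else seq_len(n)
      nb <- length(idx)
      ca <- dvrl_forward(params, Z[idx, , drop = FALSE], marginal[idx])
      p <- clip(ca$p)
      rs <- numeric(n_rollouts)
      dls <- matrix(0, n_rollouts, nb)
      for (m in seq_len(n_rollouts)) {
        s <- stats::rbinom(nb, 1, p)
        sel <- idx[s == 1]
        rs[m] <- if (length(unique(y[sel])) < 2) NA_real_ else {
          mod <- fit_gbm(X[sel, , drop = FALSE], y[sel],
                         nrounds = predictor_nrounds,
                         max_depth = predictor_max_depth, seed = pred_seed)
          auc_score(gbm_predict(mod, X_val), y_val)
        }
        dls[m, ] <- s / p - (1 - s) / (1 - p)
      }
      ok <- !is.na(rs)
      if (sum(ok) < 2) next
      adv <- rs[ok] - mean(rs[ok])
      rewards <- c(rewards, mean(rs[ok]))
      dz <- -colMeans(adv * dls[ok, , drop = FALSE]) * ca$p * (1 - ca$p) / nb
      mp <- mean(p)
      if (mp > exploration_threshold) {
        dz <- dz + exploration_weight * ca$p * (1 - ca$p) / nb
      }
      if (mp < 1 - exploration_threshold) {
        dz <- dz - exploration_weight * ca$p * (1 - ca$p) / nb
      }
      grads <- dvrl_backward(params, ca, dz, Z[idx, , drop = FALSE])
      t_st <- t_st + 1
      for (nm in names(params)) {
        m_st[[nm]] <- 0.9 * m_st[[nm]] + 0.1 * grads[[nm]]
        v_st[[nm]] <- 0.999 * v_st[[nm]] + 0.001 * grads[[nm]]^2
        params[[nm]] <- params[[nm]] - lr * (m_st[[nm]] / (1 - 0.9^t_st)) /
          (sqrt(v_st[[nm]] / (1 - 0.999^t_st)) + 1e-8)
      }
    }
  })

  final <- clip(dvrl_forward(params, Z, marginal)$p)
  new_importance(final, engine = "dvrl", mode = "test", seed = seed,
                 config = list(iterations = iterations, batch_size = batch_size,
                               n_rollouts = n_rollouts, hidden_dim = hidden_dim,
                               comb_dim = comb_dim, lr = lr,
                               predictor_nrounds = predictor_nrounds,
                               predictor_max_depth = predictor_max_depth),
                 flags = list(rewards = rewards))
}
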