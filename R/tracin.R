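# TracIn: influence of training samples traced through gradient
# checkpoints of a feed-forward network. The network (dense 512-unit
# input layer + three 512-unit hidden layers, ELU, dropout 0.5 on the
# hidden layers, L2 1e-4, sigmoid output, binary cross-entropy, Adam at
# 1e-3) is trained past the last checkpoint epoch; parameters are
# snapshot at epochs {30, 60, 90}. Gradients are taken with respect to
# the last two layers' weights only:
#   self:  score_j = sum_ckpt ||grad_j||^2
#   test:  score_j = sum_ckpt eta * <grad_j, mean_val grad_v>
#   pos:   test restricted to active validation samples
#
# Per-sample gradients are never materialized: for the factored
# gradients grad_W = a (x) delta, inner products decompose as
# <grad_j, grad_v> = (delta_j . delta_v)(a_j . a_v + 1), the +1
# absorbing the bias component.

# Per-sample gradient factors for the last two layers at one checkpoint
# (evaluation mode, no dropout): returns activations and deltas.
tracin_factors <- function(params, X, y, activation = "elu") {
  act <- act_fun(activation)
  L <- length(params)
  cache <- mlp_forward(params, X, activation, train = FALSE)
  d_out <- cache$p - y                              # dL/dz at sigmoid output
  a_out <- cache$a[[L]]                             # input to output layer
  d_hid <- (matrix(d_out, ncol = 1) %*% t(params[[L]]$W)) *
    act$df(cache$z[[L - 1]])                        # dL/dz at last hidden
  a_hid <- cache$a[[L - 1]]                         # input to last hidden
  list(d_out = d_out, a_out = a_out, d_hid = d_hid, a_hid = a_hid)
}

tracin_self_one <- function(fa) {
  fa$d_out^2 * (rowSums(fa$a_out^2) + 1) +
    rowSums(fa$d_hid^2) * (rowSums(fa$a_hid^2) + 1)
}

tracin_test_one <- function(fa_train, fa_val) {
  m_out <- outer(fa_train$d_out, fa_val$d_out) *
    (fa_train$a_out %*% t(fa_val$a_out) + 1)
  m_hid <- (fa_train$d_hid %*% t(fa_val$d_hid)) *
    (fa_train$a_hid %*% t(fa_val$a_hid) + 1)
  rowMeans(m_out + m_hid)
}

#' TracIn importance scores
#'
#' Trains the checkpointed feed-forward network and scores every
#' training sample by its traced gradient influence. `mode = "self"`
#' sums squared last-two-layer gradient norms over checkpoints (high
#' for false positives, whose own-prediction gradients stay large);
#' `mode = "test"` sums learning-rate-weighted dot products with the
#' mean validation gradient; `mode = "pos"` restricts the validation
#' set to actives.
#'
#' @param X,y Training features and binary labels.
#' @param X_val,y_val Validation set, required for test/pos modes.
#' @param mode `"self"`, `"test"` or `"pos"`.
#' @param hidden_units Width of the four dense layers (default 512).
#' @param epochs Training epochs (default 90; must reach the last
#'   checkpoint).
#' @param checkpoints Checkpoint epochs (default `c(30, 60, 90)`).
#' @param lr Adam learning rate, also the checkpoint weight eta
#'   (default 1e-3).
#' @param dropout Hidden-layer dropout rate during training
#'   (default 0.5).
#' @param l2 L2 weight decay on every dense layer (default 1e-4).
#' @param batch_size Minibatch size (default 128).
#' @param seed Integer seed for initialization, shuffling and dropout.
#' @return An importance table.
#' @export
tracin_scores <- function(X, y, X_val = NULL, y_val = NULL,
                          mode = c("self", "test", "pos"),
                          hidden_units = 512, epochs = 90,
                          checkpoints = c(30, 60, 90), lr = 1e-3,
                          dropout = 0.5, l2 = 1e-4, batch_size = 128,
                          seed = 1) {
  mode <- match.arg(mode)
  assert_binary_labels(y)
  checkpoints <- sort(as.integer(checkpoints))
  if (max(checkpoints) > epochs) {
    stop("config error: checkpoint epoch exceeds total epochs", call. = FALSE)
  }
  if (mode != "self") {
    if (is.null(X_val) || nrow(X_val) == 0) stop("validation set required", call. = FALSE)
    if (mode == "pos") {
      keep <- which(y_val == 1)
      if (length(keep) == 0) stop("mode='pos' needs active validation samples", call. = FALSE)
      X_val <- X_val[keep, , drop = FALSE]
      y_val <- y_val[keep]
    }
  }
  hidden <- rep(hidden_units, 4)
  fit <- mlp_train(X, y, hidden = hidden, activation = "elu",
                   dropout = dropout, dropout_layers = 2:4, l2 = l2,
                   lr = lr, epochs = epochs, batch_size = batch_size,
                   seed = seed, checkpoint_epochs = checkpoints)
  scores <- numeric(nrow(X))
  for (ck in as.character(checkpoints)) {
    params <- fit$checkpoints[[ck]]
    fa <- tracin_factors(params, X, y)
    if (mode == "self") {
      scores <- scores + tracin_self_one(fa)
    } else {
      fv <- tracin_factors(params, X_val, y_val)
      scores <- scores + lr * tracin_test_one(fa, fv)
    }
  }
  new_importance(scores, engine = "tracin", mode = mode, seed = seed,
                 config = list(hidden_units = hidden_units, epochs = epochs,
                               checkpoints = checkpoints, lr = lr,
                               dropout = dropout, l2 = l2,
                               batch_size = batch_size))
}
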