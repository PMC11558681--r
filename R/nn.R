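# Minimal internal feed-forward network module (dense layers, ELU/ReLU,
# inverted dropout, L2 weight decay, Adam) used by the TracIn engine
# (which needs per-sample gradients and training checkpoints) and the
# DVRL value estimator (which needs a score-function gradient). Kept
# deliberately small: dense layers only, full-batch matrix ops via BLAS.

act_fun <- function(name) {
  switch(name,
    elu = list(
      f = function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1),
      df = function(x) ifelse(x > 0, 1, exp(pmin(x, 0)))
    ),
    relu = list(
      f = function(x) pmax(x, 0),
      df = function(x) as.numeric(x > 0)
    ),
    stop("unknown activation: ", name, call. = FALSE)
  )
}

mlp_init <- function(sizes, seed) {
  withr::with_seed(seed, {
    lapply(seq_len(length(sizes) - 1), function(l) {
      list(
        W = matrix(stats::rnorm(sizes[l] * sizes[l + 1], 0,
                                sqrt(2 / sizes[l])),
                   nrow = sizes[l]),
        b = rep(0, sizes[l + 1])
      )
    })
  })
}

# Forward pass; the last layer is linear + sigmoid. dropout_layers gives
# the hidden-layer indices whose OUTPUT is dropped during training
# (inverted dropout, so inference needs no rescaling).
mlp_forward <- function(params, X, activation = "elu", dropout = 0,
                        dropout_layers = integer(0), train = FALSE) {
  act <- act_fun(activation)
  L <- length(params)
  a <- list(X)
  z <- vector("list", L)
  masks <- vector("list", L)
  for (l in seq_len(L)) {
    z[[l]] <- sweep(a[[l]] %*% params[[l]]$W, 2, params[[l]]$b, "+")
    if (l < L) {
      h <- act$f(z[[l]])
      if (train && dropout > 0 && l %in% dropout_layers) {
        m <- matrix(stats::rbinom(length(h), 1, 1 - dropout) / (1 - dropout),
                    nrow = nrow(h))
        h <- h * m
        masks[[l]] <- m
      }
      a[[l + 1]] <- h
    } else {
      a[[l + 1]] <- sigmoid(z[[l]])
    }
  }
  list(a = a, z = z, masks = masks, p = as.vector(a[[L + 1]]))
}

# Backward pass from dL/dz at the output layer (a length-n vector for a
# single output unit). Returns per-layer weight/bias gradients; L2
# decay 2*l2*W is added to every weight gradient.
mlp_backward <- function(params, cache, dz_out, activation = "elu", l2 = 0) {
  act <- act_fun(activation)
  L <- length(params)
  grads <- vector("list", L)
  delta <- matrix(dz_out, ncol = 1)
  for (l in rev(seq_len(L))) {
    grads[[l]] <- list(
      W = crossprod(cache$a[[l]], delta) + 2 * l2 * params[[l]]$W,
      b = colSums(delta)
    )
    if (l > 1) {
      da <- delta %*% t(params[[l]]$W)
      if (!is.null(cache$masks[[l - 1]])) da <- da * cache$masks[[l - 1]]
      delta <- da * act$df(cache$z[[l - 1]])
    }
  }
  grads
}

adam_init <- function(params) {
  list(
    m = lapply(params, function(p) list(W = p$W * 0, b = p$b * 0)),
    v = lapply(params, function(p) list(W = p$W * 0, b = p$b * 0)),
    t = 0
  )
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (l in seq_along(params)) {
    for (nm in c("W", "b")) {
      g <- grads[[l]][[nm]]
      state$m[[l]][[nm]] <- beta1 * state$m[[l]][[nm]] + (1 - beta1) * g
      state$v[[l]][[nm]] <- beta2 * state$v[[l]][[nm]] + (1 - beta2) * g^2
      params[[l]][[nm]] <- params[[l]][[nm]] -
        lr * (state$m[[l]][[nm]] / bc1) / (sqrt(state$v[[l]][[nm]] / bc2) + eps)
    }
  }
  list(params = params, state = state)
}

# Minibatch training of a binary classifier MLP with optional parameter
# snapshots at given epochs. Returns final params and the checkpoints.
mlp_train <- function(X, y, hidden, activation = "elu", dropout = 0,
                      dropout_layers = integer(0), l2 = 0, lr = 1e-3,
                      epochs = 90, batch_size = 128, seed = 1,
                      checkpoint_epochs = integer(0)) {
  n <- nrow(X)
  sizes <- c(ncol(X), hidden, 1)
  params <- mlp_init(sizes, seed = derive_seed(seed, 21L))
  state <- adam_init(params)
  checkpoints <- list()
  withr::with_seed(derive_seed(seed, 22L), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, n)]
        cache <- mlp_forward(params, X[idx, , drop = FALSE], activation,
                             dropout, dropout_layers, train = TRUE)
        dz <- (cache$p - y[idx]) / length(idx)
        grads <- mlp_backward(params, cache, dz, activation, l2)
        upd <- adam_step(params, grads, state, lr)
        params <- upd$params
        state <- upd$state
      }
      if (ep %in% checkpoint_epochs) {
        checkpoints[[as.character(ep)]] <- params
      }
    }
  })
  list(params = params, checkpoints = checkpoints,
       config = list(hidden = hidden, activation = activation,
                     dropout = dropout, l2 = l2, lr = lr, epochs = epochs,
                     batch_size = batch_size, seed = seed))
}
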