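# KNN Shapley values: exact Shapley values of the K-nearest-neighbour
# utility, computed in closed form per validation point by the standard
# descending recursion over training points sorted by distance. The
# utility of a training subset S for a validation point t is
#   v(S) = (1/K) * sum_{k=1..min(K,|S|)} 1[y_{alpha_k(S)} = y_t],
# the fraction of correct votes among the up-to-K nearest members of S
# (v(empty) = 0). Because the training majority class drowns the
# computation, the majority class is randomly undersampled to a target
# minority:majority ratio first; removed samples score 0 and are
# flagged.

# Shapley values of all N kept training points for ONE validation point,
# given distances. Recursion (farthest to nearest):
#   s_{alpha_N} = 1[match_N] / N
#   s_{alpha_i} = s_{alpha_{i+1}} + (1[match_i] - 1[match_{i+1}]) * min(K,i)/(K*i)
knn_shapley_one <- function(dist, y_train, y_val_point, k) {
  n <- length(dist)
  ord <- order(dist, seq_len(n))
  match <- as.numeric(y_train[ord] == y_val_point)
  s <- numeric(n)
  s[n] <- match[n] / n
  if (n > 1) {
    for (i in (n - 1):1) {
      s[i] <- s[i + 1] + (match[i] - match[i + 1]) * min(k, i) / (k * i)
    }
  }
  out <- numeric(n)
  out[ord] <- s
  out
}

# Per-validation-point Shapley matrix (m validation rows x N kept train
# columns); used by the efficiency test and averaged for the scores.
knn_shapley_matrix <- function(X_train, y_train, X_val, y_val, k) {
  # squared Euclidean distances via the cross-product expansion
  tn <- rowSums(X_train^2)
  vn <- rowSums(X_val^2)
  d2 <- outer(vn, tn, "+") - 2 * X_val %*% t(X_train)
  d2[d2 < 0] <- 0
  t(vapply(seq_len(nrow(X_val)), function(t_i) {
    knn_shapley_one(sqrt(d2[t_i, ]), y_train, y_val[t_i], k)
  }, numeric(nrow(X_train))))
}

# Random undersampling of the majority class to a minority:majority
# ratio; returns kept indices in original order.
undersample_majority <- function(y, ratio, seed) {
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  minority <- if (n1 <= n0) 1 else 0
  n_min <- min(n1, n0)
  n_maj_target <- round(n_min / ratio)
  maj_idx <- which(y != minority)
  if (length(maj_idx) <= n_maj_target) return(sort(seq_along(y)))
  withr::with_seed(seed, kept_maj <- sample(maj_idx, n_maj_target))
  sort(c(which(y == minority), kept_maj))
}

#' KNN Shapley importance scores
#'
#' Computes, for each training compound, its exact Shapley value under
#' the K-nearest-neighbour utility, averaged over all validation
#' points. The training majority class is randomly undersampled to the
#' `undersample_ratio` first (seeded); compounds removed by
#' undersampling receive score 0 and are flagged in the `removed`
#' attribute. Distances are Euclidean on the feature vectors, ties
#' broken by ascending index.
#'
#' @param X_train,y_train Training features and binary labels.
#' @param X_val,y_val Validation features and labels (nonempty).
#' @param k Neighbourhood size (default 5).
#' @param undersample_ratio Target minority:majority ratio (default 0.2).
#' @param seed Integer seed for the undersampling draw.
#' @return An importance table; positive scores mark samples that help
#'   validation predictions (true positives), negative scores samples
#'   that hurt them (false positives).
#' @export
knn_shapley_scores <- function(X_train, y_train, X_val, y_val, k = 5,
                               undersample_ratio = 0.2, seed = 1) {
  if (nrow(X_val) == 0) stop("empty validation set", call. = FALSE)
  if (k < 1) stop("k must be at least 1", call. = FALSE)
  if (undersample_ratio <= 0 || undersample_ratio > 1) {
    stop("undersample_ratio outside (0, 1]", call. = FALSE)
  }
  assert_binary_labels(y_train, "y_train")
  kept <- undersample_majority(y_train, undersample_ratio,
                               seed = derive_seed(seed, 3L))
  if (k > length(kept)) stop("k exceeds the undersampled training size", call. = FALSE)
  sv <- knn_shapley_matrix(X_train[kept, , drop = FALSE], y_train[kept],
                           X_val, y_val, k)
  scores <- numeric(length(y_train))
  scores[kept] <- colMeans(sv)
  removed <- setdiff(seq_along(y_train), kept)
  new_importance(scores, engine = "knn_shapley", mode = "test", seed = seed,
                 config = list(k = k, undersample_ratio = undersample_ratio,
                               distance = "euclidean"),
                 flags = list(removed = removed))
}
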