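# Synthetic screen generator.
#
# Emulates the statistical structure of a primary+confirmatory HTS
# dataset without any chemistry on the critical path: compounds are
# binary feature vectors drawn around latent cluster prototypes, true
# actives live in designated "active" clusters, and planted false
# positives are structurally isolated points (uniform random bit
# vectors, far from every prototype) that nevertheless carry a primary
# active label and an active-like score. This reproduces the signal the
# valuation engines exploit: false positives are atypical and carry
# flipped labels, so they show high self-importance.

#' Generate a synthetic HTS screen
#'
#' Builds a screen table, a binary feature matrix and a ground-truth
#' table. Counts are exact: `round(n * active_rate)` primary actives, of
#' which `round(fp_rate * n_actives)` are planted false positives
#' (confirmatory label 0); all remaining primary actives are true
#' positives (confirmatory label 1); inactives carry no confirmatory
#' label. Activity scores are Gaussian around class-specific means
#' (actives high, inactives low), clipped to \[0, 100\]; false positives
#' draw from the same score distribution as true positives, so scores do
#' not give them away.
#'
#' @param n Number of compounds (>= 100 recommended).
#' @param active_rate Fraction of primary actives (default 0.02).
#' @param fp_rate Fraction of primary actives that are planted false
#'   positives (default 0.3).
#' @param n_clusters Number of latent structural clusters (default 8);
#'   the first `n_active_clusters` are active chemotypes.
#' @param n_active_clusters Clusters whose members are true actives
#'   (default 2).
#' @param d Feature dimension (default 1024; minimum 16).
#' @param bit_noise Per-bit flip probability around a prototype
#'   (default 0.05).
#' @param score_noise Gaussian score noise standard deviation on the
#'   0-100 scale (default 15 for inactives around mean 35; actives draw
#'   around mean 60 with 4/3 the spread, so class scores overlap and a
#'   top-score cut captures high scorers of both classes).
#' @param attach_smiles `"none"` (default) or `"fixture"` to attach
#'   structures sampled from the packaged fixture list, for end-to-end
#'   I/O tests only (structures are then unrelated to features).
#' @param seed Integer seed; the same seed reproduces the dataset
#'   bitwise.
#' @return A list of class `synthetic_screen` with elements `screen`
#'   (a screen table), `features` (an `n x d` binary matrix), `truth`
#'   (tibble with `compound_id`, `cluster`, `is_fp`), plus the latent
#'   `prototypes` matrix and `active_clusters` indices.
#' @export
simulate_screen <- function(n, active_rate = 0.02, fp_rate = 0.3,
                            n_clusters = 8, n_active_clusters = 2, d = 1024,
                            bit_noise = 0.05, score_noise = 15,
                            attach_smiles = c("none", "fixture"), seed = 1) {
  attach_smiles <- match.arg(attach_smiles)
  if (active_rate <= 0 || active_rate >= 0.5) stop("active_rate outside (0, 0.5)", call. = FALSE)
  if (fp_rate < 0 || fp_rate >= 1) stop("fp_rate outside [0, 1)", call. = FALSE)
  if (d < 16) stop("feature dimension must be at least 16", call. = FALSE)
  n_act <- round(n * active_rate)
  if (n_act < 2) stop("config error: n * active_rate must be at least 2", call. = FALSE)
  n_fp <- round(fp_rate * n_act)
  n_tp <- n_act - n_fp
  n_inact <- n - n_act
  if (n_active_clusters >= n_clusters) stop("need at least one background cluster", call. = FALSE)

  withr::with_seed(seed, {
    proto <- matrix(stats::rbinom(n_clusters * d, 1, 0.5), nrow = n_clusters)
    active_clusters <- seq_len(n_active_clusters)
    background_clusters <- setdiff(seq_len(n_clusters), active_clusters)

    cl_tp <- sample(active_clusters, n_tp, replace = TRUE)
    cl_in <- sample(background_clusters, n_inact, replace = TRUE)

    sample_around <- function(cl) {
      m <- proto[cl, , drop = FALSE]
      flips <- matrix(stats::rbinom(length(cl) * d, 1, bit_noise), nrow = length(cl))
      (m + flips) %% 2L
    }
    X_tp <- sample_around(cl_tp)
    X_in <- sample_around(cl_in)
    # isolated false positives: uniform random vectors, ~d/2 bits from
    # every prototype while cluster members sit ~d*bit_noise away
    X_fp <- matrix(stats::rbinom(n_fp * d, 1, 0.5), nrow = n_fp)

    X <- rbind(X_tp, X_fp, X_in)
    primary <- c(rep(1L, n_tp + n_fp), rep(0L, n_inact))
    confirmatory <- c(rep(1L, n_tp), rep(0L, n_fp), rep(NA_integer_, n_inact))
    cluster <- c(cl_tp, rep(NA_integer_, n_fp), cl_in)
    is_fp <- c(rep(FALSE, n_tp), rep(TRUE, n_fp), rep(FALSE, n_inact))

    score_mean <- ifelse(primary == 1L, 60, 35)
    score_sd <- ifelse(primary == 1L, score_noise * 4 / 3, score_noise)
    score <- pmin(pmax(score_mean + stats::rnorm(n, 0, score_sd), 0), 100)

    perm <- sample.int(n)
  })

  X <- X[perm, , drop = FALSE]
  storage.mode(X) <- "integer"
  primary <- primary[perm]
  confirmatory <- confirmatory[perm]
  cluster <- cluster[perm]
  is_fp <- is_fp[perm]
  score <- score[perm]
  ids <- sprintf("CPD%06d", seq_len(n))

  smiles <- rep(NA_character_, n)
  if (attach_smiles == "fixture") {
    fx <- utils::read.csv(system.file("extdata", "smiles_fixture.csv",
                                      package = "screenval"),
                          stringsAsFactors = FALSE)
    withr::with_seed(derive_seed(seed, 7L), {
      smiles <- sample(fx$smiles, n, replace = TRUE)
    })
  }

  screen <- new_screen_tbl(
    tibble::tibble(compound_id = ids, smiles = smiles, activity_score = score,
                   primary_label = primary, confirmatory_label = confirmatory),
    name = sprintf("synthetic_n%d_seed%d", n, seed)
  )
  rownames(X) <- ids
  attr(X, "representation") <- "fingerprint"

  structure(
    list(screen = screen, features = X,
         truth = tibble::tibble(compound_id = ids, cluster = cluster, is_fp = is_fp),
         prototypes = proto, active_clusters = active_clusters,
         config = list(n = n, active_rate = active_rate, fp_rate = fp_rate,
                       n_clusters = n_clusters, n_active_clusters = n_active_clusters,
                       d = d, bit_noise = bit_noise, score_noise = score_noise,
                       seed = seed)),
    class = "synthetic_screen"
  )
}

#' @export
print.synthetic_screen <- function(x, ...) {
  cat(sprintf("<synthetic_screen> n=%d, d=%d, actives=%d (%d planted FP), seed=%d\n",
              nrow(x$screen), ncol(x$features), sum(x$screen$primary_label),
              sum(x$truth$is_fp), x$config$seed))
  invisible(x)
}
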