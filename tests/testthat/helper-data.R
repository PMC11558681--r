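# Shared fixtures, all built in code at test time.

# Two separable Gaussian clusters with a fraction of flipped labels;
# the standard planted-noise instance for the valuation engines.
make_flip_data <- function(n, d, sep = 1.2, flip_frac = 0, seed = 1) {
  withr::with_seed(seed, {
    cl <- stats::rbinom(n, 1, 0.5)
    X <- matrix(stats::rnorm(n * d), n)
    X[cl == 1, ] <- X[cl == 1, ] + sep
    y <- cl
    flip <- integer(0)
    if (flip_frac > 0) {
      flip <- sample(n, round(flip_frac * n))
      y[flip] <- 1 - y[flip]
    }
  })
  list(X = X, y = y, flip = flip)
}

# A tiny screen table with known structures, used by I/O and
# featurization tests.
make_smiles_screen <- function() {
  screenval:::new_screen_tbl(tibble::tibble(
    compound_id = sprintf("C%02d", 1:6),
    smiles = c("CCO", "c1ccccc1", "CC(=O)Oc1ccccc1C(=O)O",
               "CCCCCC", "CCN", "OCC"),
    activity_score = c(80, 20, 65, 10, 55, 90),
    primary_label = c(1L, 0L, 1L, 0L, 1L, 1L),
    confirmatory_label = c(1L, NA, 0L, NA, NA, 1L)
  ))
}

write_screen_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  path
}
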