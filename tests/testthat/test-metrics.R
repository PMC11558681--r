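test_that("enrichment factor matches hand-computed closed forms", {
  # uniform ranking: 1 positive in top-10 of 100 with 10 positives
  expect_equal(enrichment_factor(c(5, 15, 25, 35, 45, 55, 65, 75, 85, 95), 100), 1)
  # maximal: all 10 in the top decile
  expect_equal(enrichment_factor(1:10, 100), 10)
  # hand case: N=50, n_pos=5, top-5 holds 2 -> (2/5)/(5/50) = 4
  expect_equal(enrichment_factor(c(1, 4, 20, 30, 40), 50), 4)
  expect_error(enrichment_factor(integer(0), 100), "no positives")
})

test_that("BEDROC hits its bounds and matches a direct-sum oracle", {
  # independent direct evaluation of the early-recognition formula
  bedroc_oracle <- function(ranks, n, alpha) {
    npos <- length(ranks)
    ra <- npos / n
    rie <- mean(exp(-alpha * ranks / n)) /
      ((1 / n) * (1 - exp(-alpha)) / (exp(alpha / n) - 1))
    rie * ra * sinh(alpha / 2) /
      (cosh(alpha / 2) - cosh(alpha / 2 - alpha * ra)) +
      1 / (1 - exp(alpha * (1 - ra)))
  }
  expect_gte(bedroc(1:10, 1000, 20), 0.99)
  expect_lte(bedroc(991:1000, 1000, 20), 0.01)
  expect_equal(bedroc(1:10, 1000, 20), bedroc_oracle(1:10, 1000, 20),
               tolerance = 1e-12)
  set.seed(1)
  for (i in 1:25) {
    ranks <- sort(sample(1000, 10))
    b <- bedroc(ranks, 1000, 20)
    expect_gte(b, 0); expect_lte(b, 1)
    expect_equal(b, bedroc_oracle(ranks, 1000, 20), tolerance = 1e-12)
  }
})

test_that("precision and relative precision follow their definitions", {
  p <- precision_at(1:10, 100, k = 10)
  expect_equal(p$precision, 1)
  expect_equal(p$relative_precision, 1 - 0.1)
  # ranking [+,-,+] cutoff 2 -> 0.5
  expect_equal(precision_at(c(1, 3), 3, k = 2)$precision, 0.5)
  # base-rate-matching selection has relative precision 0
  expect_equal(precision_at(c(1, 11), 20, k = 10)$relative_precision, 0)
  expect_error(precision_at(1, 10, k = 11), "cutoff")
})

test_that("average precision matches hand evaluation and ignores trailing negatives", {
  expect_equal(average_precision(1:5, 10), 1)
  expect_equal(average_precision(c(1, 3), 3), (1 + 2 / 3) / 2)
  expect_equal(average_precision(c(1, 3), 3), average_precision(c(1, 3), 50))
})

test_that("ranking metrics are invariant to monotone score transforms", {
  set.seed(2)
  scores <- runif(60)
  labels <- rbinom(60, 1, 0.2)
  if (sum(labels) %in% c(0, 60)) labels[1:3] <- c(1, 0, 1)
  a <- ranking_metrics(scores, labels)
  b <- ranking_metrics(exp(5 * scores) + 2, labels)   # strictly monotone
  expect_equal(a, b)
})

test_that("score ties resolve by stable index order", {
  scores <- c(1, 1, 1, 0)
  labels <- c(0, 1, 0, 1)
  expect_equal(screenval:::ranks_from_scores(scores, labels), c(2L, 4L))
})

test_that("paired comparison runs omnibus and adjusted pairwise tests", {
  set.seed(3)
  base <- rnorm(12)
  df <- tibble::tibble(
    replicate = rep(1:12, 3),
    method = rep(c("a", "b", "c"), each = 12),
    value = c(base, base + 0.8 + rnorm(12, 0, 0.2), base + rnorm(12, 0, 0.05))
  )
  mc <- method_comparison(df, reference = "a")
  g <- glance(mc)
  expect_lt(g$p_value, 0.05)
  td <- tidy(mc)
  expect_true(all(td$p_adjusted >= td$p_value))
  expect_lt(td$p_adjusted[td$method == "b"], 0.05)
})

test_that("Friedman omnibus agrees with the textbook formula by hand", {
  # 3 methods x 4 replicates, no ties
  m <- rbind(c(1, 2, 3), c(1, 3, 2), c(1, 2, 3), c(2, 1, 3)) * 1.0
  df <- tibble::tibble(
    replicate = rep(1:4, times = 3),
    method = rep(c("m1", "m2", "m3"), each = 4),
    value = c(m[, 1], m[, 2], m[, 3])
  )
  mc <- method_comparison(df, reference = "m1")
  # chi2 = 12/(n k (k+1)) * sum Rj^2 - 3 n (k+1); ranks per row = values here
  rj <- colSums(t(apply(m, 1, rank)))
  chi2 <- 12 / (4 * 3 * 4) * sum(rj^2) - 3 * 4 * 4
  expect_equal(unname(glance(mc)$statistic), chi2)
})

test_that("identical paired vectors are flagged degenerate with p = 1", {
  df <- tibble::tibble(replicate = rep(1:6, 2),
                       method = rep(c("a", "b"), each = 6),
                       value = rep(1:6, 2) * 1.0)
  mc <- method_comparison(df, reference = "a")
  td <- tidy(mc)
  expect_true(td$degenerate)
  expect_equal(td$p_adjusted, 1.0)
})

test_that("mismatched pairings raise an error", {
  df <- tibble::tibble(replicate = c(1, 2, 1), method = c("a", "a", "b"),
                       value = c(1, 2, 3))
  expect_error(method_comparison(df), "unpaired")
})
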