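test_that("random selection is the seeded shuffle prefix and steps stay disjoint", {
  syn <- simulate_screen(400, active_rate = 0.05, d = 32, seed = 1)
  tr <- run_campaign(syn$screen, syn$features, n_steps = 4,
                     strategy = "random", seed = 1)
  sel <- attr(tr, "selected")
  batch <- round(0.015 * 400)
  expect_true(all(lengths(sel) == batch))
  all_idx <- unlist(sel)
  expect_equal(anyDuplicated(all_idx), 0)       # pairwise disjoint
  # the step-1 batch is the prefix of the seeded shuffle of the remainder
  remainder <- setdiff(seq_len(400), sel[[1]])
  expected <- withr::with_seed(screenval:::derive_seed(1, 101L),
                               sample(remainder))[seq_len(batch)]
  expect_setequal(sel[[2]], expected)
})

test_that("screening the whole library retrieves every active", {
  syn <- simulate_screen(200, active_rate = 0.1, d = 32, seed = 2)
  n_steps <- ceiling(1 / 0.015)
  tr <- run_campaign(syn$screen, syn$features, n_steps = n_steps,
                     strategy = "random", seed = 2)
  expect_equal(tr$cum_fraction[nrow(tr)], 1.0)
  expect_true(attr(tr, "truncated"))            # final batch is short
  expect_true(all(diff(tr$cum_actives) >= 0))
})

test_that("a remainder smaller than the batch is returned whole", {
  X <- matrix(rnorm(40), 20)
  out <- select_batch(1:15, 16:20, X, rep(c(0, 1), c(10, 5)),
                      strategy = "greedy", batch = 10, seed = 1)
  expect_equal(out, 16:20)
})

test_that("selection is deterministic given identical inputs and seed", {
  syn <- simulate_screen(300, active_rate = 0.05, d = 32, seed = 3)
  y <- syn$screen$primary_label
  lab <- 1:60
  rem <- 61:300
  for (strat in c("random", "greedy", "importance")) {
    a <- select_batch(lab, rem, syn$features, y[lab], strategy = strat,
                      batch = 10, nrounds = 20, seed = 4)
    b <- select_batch(lab, rem, syn$features, y[lab], strategy = strat,
                      batch = 10, nrounds = 20, seed = 4)
    expect_identical(a, b)
  }
})

test_that("a single-class labeled pool falls back to a random step", {
  X <- matrix(rnorm(200), 100)
  out <- select_batch(1:20, 21:100, X, rep(0, 20), strategy = "greedy",
                      batch = 5, seed = 2)
  expect_equal(attr(out, "fallback"), "single-class labeled set: random step")
})

test_that("campaign traces are reproducible bitwise from the seed", {
  syn <- simulate_screen(400, active_rate = 0.05, d = 32, seed = 5)
  a <- run_campaign(syn$screen, syn$features, n_steps = 3, strategy = "greedy",
                    nrounds = 20, seed = 6)
  b <- run_campaign(syn$screen, syn$features, n_steps = 3, strategy = "greedy",
                    nrounds = 20, seed = 6)
  expect_identical(attr(a, "selected"), attr(b, "selected"))
  expect_identical(a$cum_actives, b$cum_actives)
})

test_that("model-driven strategies out-retrieve random on a separable library", {
  syn <- simulate_screen(1500, active_rate = 0.04, d = 128, seed = 7)
  res <- vapply(c("random", "greedy", "importance"), function(strat) {
    tr <- run_campaign(syn$screen, syn$features, n_steps = 3, strategy = strat,
                       nrounds = 50, seed = 7)
    tr$cum_actives[4]
  }, numeric(1))
  expect_gt(res[["greedy"]], res[["random"]])
  expect_gt(res[["importance"]], res[["random"]])
})

test_that("campaign configuration is validated", {
  syn <- simulate_screen(200, active_rate = 0.1, d = 32, seed = 8)
  expect_error(run_campaign(syn$screen, syn$features, n_steps = 2,
                            step_fraction = 0.6), "step_fraction")
  expect_error(run_campaign(syn$screen, syn$features, n_steps = 200,
                            step_fraction = 0.015), "exceeds 1")
})
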