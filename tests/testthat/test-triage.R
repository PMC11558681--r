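make_triage_screen <- function(scores_by_active, confirmatory, n_inactive = 20) {
  n_act <- length(scores_by_active)
  screenval:::new_screen_tbl(tibble::tibble(
    compound_id = sprintf("C%03d", seq_len(n_act + n_inactive)),
    smiles = NA_character_,
    activity_score = c(rep(80, n_act), rep(20, n_inactive)),
    primary_label = c(rep(1L, n_act), rep(0L, n_inactive)),
    confirmatory_label = c(confirmatory, rep(NA_integer_, n_inactive))
  ))
}

fake_importance <- function(screen, scores, engine = "mvsa", mode = "self") {
  idx <- seq_len(nrow(screen))
  out <- tibble::tibble(compound_id = screen$compound_id[idx], index = idx,
                        score = scores)
  class(out) <- c("importance_tbl", class(tibble::tibble()))
  attr(out, "engine") <- engine
  attr(out, "mode") <- mode
  attr(out, "seed") <- 1
  out
}

test_that("self-mode scores sort actives highest-first for the FP task", {
  sc <- make_triage_screen(c(0, 0, 0), confirmatory = c(1L, 0L, 1L),
                           n_inactive = 5)
  imp <- fake_importance(sc, c(3, 1, 2, rep(0, 5)))
  res <- rank_candidates(sc, imp, decile_fraction = 0.34)
  expect_equal(res$ranked$fp_rank, c(1L, 3L, 2L))   # scores [3,1,2]
  expect_equal(res$ranked$tp_rank, c(3L, 1L, 2L))
})

test_that("test-mode engines are oriented lowest-score-is-FP", {
  sc <- make_triage_screen(c(0, 0, 0), confirmatory = c(1L, 0L, 1L),
                           n_inactive = 5)
  imp <- fake_importance(sc, c(3, 1, 2, rep(0, 5)), engine = "knn_shapley",
                         mode = "test")
  res <- rank_candidates(sc, imp, decile_fraction = 0.34)
  expect_equal(res$ranked$fp_rank, c(3L, 1L, 2L))
})

test_that("nominee sets have the exact decile size and never overlap", {
  sc <- make_triage_screen(rep(0, 40), confirmatory = rep(c(0L, 1L), 20))
  imp <- fake_importance(sc, c(rnorm(40), rep(0, 20)))
  res <- rank_candidates(sc, imp, decile_fraction = 0.10)
  expect_length(res$fp_nominees, 4)
  expect_length(res$tp_nominees, 4)
  expect_length(intersect(res$fp_nominees, res$tp_nominees), 0)
})

test_that("the filter benchmark ranks alert-rich compounds as FP-like", {
  sc <- screenval:::new_screen_tbl(tibble::tibble(
    compound_id = c("alerts2", "clean", "alert1"),
    smiles = c("O=[N+]([O-])c1ccccc1C(=O)Cl", "c1ccccc1", "O=Cc1ccccc1"),
    activity_score = c(50, 50, 50),
    primary_label = 1L,
    confirmatory_label = c(0L, 1L, 1L)
  ))
  res <- rank_candidates(sc, importance = NULL, benchmark = "filters",
                         decile_fraction = 0.34)
  expect_equal(res$ranked$fp_rank[res$ranked$compound_id == "alerts2"], 1L)
  expect_equal(res$ranked$fp_rank[res$ranked$compound_id == "clean"], 3L)
})

test_that("the score benchmark treats high scores as TP-like", {
  sc <- make_triage_screen(rep(0, 3), confirmatory = c(1L, 0L, 1L))
  sc$activity_score[1:3] <- c(90, 40, 70)
  res <- rank_candidates(sc, importance = NULL, benchmark = "score",
                         decile_fraction = 0.34)
  expect_equal(res$ranked$tp_rank, c(1L, 3L, 2L))
})

test_that("triage metrics follow their hand-computed definitions", {
  # 10 labeled actives, 4 FPs; decile of size 1 holds an FP
  conf <- c(0L, rep(c(0L, 1L, 1L), 3))
  sc <- make_triage_screen(rep(0, 10), confirmatory = conf)
  imp <- fake_importance(sc, c(10:1, rep(0, 20)))  # active 1 ranked first
  res <- rank_candidates(sc, imp, decile_fraction = 0.10)
  ev <- evaluate_triage(res)
  fp <- ev[ev$task == "false_positive", ]
  expect_equal(fp$value[fp$metric == "precision"], 1.0)
  expect_equal(fp$value[fp$metric == "relative_precision"], 0.6)
})

test_that("a perfect FP ranking attains relative precision 1 - base rate", {
  conf <- c(rep(0L, 4), rep(1L, 6))
  sc <- make_triage_screen(rep(0, 10), confirmatory = conf)
  imp <- fake_importance(sc, c(rep(5, 4), rep(1, 6), rep(0, 20)) + c(4:1, 6:1, rep(0, 20)) / 10)
  res <- rank_candidates(sc, imp, decile_fraction = 0.4)
  ev <- evaluate_triage(res, k = 0.4)
  fp <- ev[ev$task == "false_positive", ]
  expect_equal(fp$value[fp$metric == "precision"], 1.0)
  expect_equal(fp$value[fp$metric == "relative_precision"], 0.6)
})

test_that("missing importance coverage and unknown orientations error", {
  sc <- make_triage_screen(rep(0, 4), confirmatory = rep(c(0L, 1L), 2))
  imp <- fake_importance(sc, rnorm(24), engine = "mystery", mode = "self")
  expect_error(rank_candidates(sc, imp), "orientation")
  expect_error(rank_candidates(sc, fake_importance(sc, rnorm(24)),
                               decile_fraction = 0.7), "decile_fraction")
})

test_that("FP nominee structural similarity is computable", {
  syn <- simulate_screen(300, active_rate = 0.1, fp_rate = 0.3, d = 64, seed = 3)
  imp <- fake_importance(syn$screen, rnorm(300))
  res <- rank_candidates(syn$screen, imp, decile_fraction = 0.2)
  sim <- fp_nominee_similarity(res, syn$features)
  expect_true(is.finite(sim))
  expect_gte(sim, 0); expect_lte(sim, 1)
})
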