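test_that("class and false-positive counts are exact", {
  syn <- simulate_screen(1000, active_rate = 0.05, fp_rate = 0.3, d = 64, seed = 1)
  expect_equal(sum(syn$screen$primary_label), 50)
  expect_equal(sum(syn$screen$confirmatory_label == 0, na.rm = TRUE), 15)
  expect_equal(sum(syn$screen$confirmatory_label == 1, na.rm = TRUE), 35)
  expect_true(all(is.na(syn$screen$confirmatory_label[syn$screen$primary_label == 0])))
  expect_equal(sum(syn$truth$is_fp), 15)
})

test_that("the same seed reproduces the dataset bitwise", {
  a <- simulate_screen(500, d = 64, active_rate = 0.04, seed = 9)
  b <- simulate_screen(500, d = 64, active_rate = 0.04, seed = 9)
  expect_identical(a$features, b$features)
  expect_identical(as.data.frame(a$screen), as.data.frame(b$screen))
  c <- simulate_screen(500, d = 64, active_rate = 0.04, seed = 10)
  expect_false(identical(a$features, c$features))
})

test_that("planted false positives are structurally isolated", {
  isolated <- vapply(1:10, function(seed) {
    syn <- simulate_screen(800, active_rate = 0.05, fp_rate = 0.3, d = 128,
                           seed = seed)
    proto <- syn$prototypes[syn$active_clusters, , drop = FALSE]
    nearest <- function(rows) {
      vapply(seq_len(nrow(rows)), function(i) {
        min(rowSums(sweep(proto, 2, rows[i, ], "!=")))
      }, numeric(1))
    }
    tp <- syn$features[syn$screen$primary_label == 1 & !syn$truth$is_fp, , drop = FALSE]
    fp <- syn$features[syn$truth$is_fp, , drop = FALSE]
    mean(nearest(fp)) > mean(nearest(tp))
  }, logical(1))
  expect_true(all(isolated))
})

test_that("scores correlate with labels but overlap between classes", {
  syn <- simulate_screen(2000, active_rate = 0.05, d = 32, seed = 4)
  s <- syn$screen
  expect_gt(mean(s$activity_score[s$primary_label == 1]),
            mean(s$activity_score[s$primary_label == 0]))
  expect_true(all(s$activity_score >= 0 & s$activity_score <= 100))
  # overlap: some inactives outscore some actives
  expect_gt(max(s$activity_score[s$primary_label == 0]),
            min(s$activity_score[s$primary_label == 1]))
  # false positives draw from the active score distribution
  fp_scores <- s$activity_score[!is.na(s$confirmatory_label) & s$confirmatory_label == 0]
  tp_scores <- s$activity_score[!is.na(s$confirmatory_label) & s$confirmatory_label == 1]
  expect_gt(stats::wilcox.test(fp_scores, tp_scores)$p.value, 0.01)
})

test_that("generated screens are learnable above the base rate", {
  syn <- simulate_screen(1500, active_rate = 0.05, d = 128, seed = 6)
  sp <- screen_splits(syn$screen, seed = 6)
  y <- syn$screen$primary_label
  m <- screenval:::fit_gbm(syn$features[sp$train_idx, ], y[sp$train_idx],
                           nrounds = 50, seed = 6)
  p <- screenval:::gbm_predict(m, syn$features[sp$val_idx, ])
  ap <- average_precision(screenval:::ranks_from_scores(p, y[sp$val_idx]),
                          length(sp$val_idx))
  expect_gt(ap, mean(y[sp$val_idx]))
})

test_that("degenerate configurations are rejected", {
  expect_error(simulate_screen(30, active_rate = 0.02), "at least 2")
  expect_error(simulate_screen(100, active_rate = 0.7), "active_rate")
  expect_error(simulate_screen(100, d = 8), "dimension")
})

test_that("fixture structures attach and survive a disk round trip", {
  syn <- simulate_screen(120, active_rate = 0.1, d = 32,
                         attach_smiles = "fixture", seed = 2)
  expect_false(anyNA(syn$screen$smiles))
  path <- tempfile(fileext = ".csv")
  write_screen(syn$screen, path)
  back <- read_screen(path, columns = c(smiles = "smiles", score = "activity_score",
                                        primary = "primary_label",
                                        confirmatory = "confirmatory_label",
                                        id = "compound_id"))
  expect_equal(nrow(back), 120)
  expect_equal(back$primary_label, syn$screen$primary_label)
})
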