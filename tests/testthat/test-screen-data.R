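test_that("a well-formed CSV loads as an identity pass-through", {
  path <- tempfile(fileext = ".csv")
  write_screen_csv(data.frame(
    smiles = c("CCO", "c1ccccc1"), score = c(80, 20),
    primary = c(1, 0), confirmatory = c(1, NA)
  ), path)
  ds <- read_screen(path)
  expect_equal(nrow(ds), 2)
  expect_equal(sum(drop_report(ds)$n), 0)
  expect_equal(ds$activity_score, c(80, 20))
  expect_equal(ds$confirmatory_label, c(1L, NA_integer_))
})

test_that("a missing confirmatory column defaults to all-missing labels", {
  path <- tempfile(fileext = ".csv")
  write_screen_csv(data.frame(smiles = c("CCO", "CCN"), score = c(70, 30),
                              primary = c(1, 0)), path)
  ds <- read_screen(path)
  expect_true(all(is.na(ds$confirmatory_label)))
})

test_that("unparsable structures are dropped and counted", {
  path <- tempfile(fileext = ".csv")
  write_screen_csv(data.frame(
    smiles = c("CCO", "c1ccccc1", "not_a_smiles(((", "CCN", "CCCC"),
    score = c(90, 10, 50, 60, 5),
    primary = c(1, 0, 1, 1, 0)
  ), path)
  ds <- read_screen(path)
  expect_equal(nrow(ds), 4)  # hand count of valid rows
  rep <- drop_report(ds)
  expect_equal(rep$n[rep$reason == "unparsable_structure"], 1L)
})

test_that("schema and empty-dataset errors are raised", {
  path <- tempfile(fileext = ".csv")
  write_screen_csv(data.frame(smiles = "CCO", primary = 1), path)
  expect_error(read_screen(path), "schema error")
  path2 <- tempfile(fileext = ".csv")
  write_screen_csv(data.frame(smiles = "zzz((", score = 1, primary = 1), path2)
  expect_error(read_screen(path2), "empty dataset")
})

test_that("out-of-range scores are min-max rescaled to 0..100", {
  path <- tempfile(fileext = ".csv")
  write_screen_csv(data.frame(smiles = c("CCO", "CCN", "CCCC"),
                              score = c(-2, 0, 6), primary = c(1, 0, 0)), path)
  ds <- read_screen(path)
  expect_equal(range(ds$activity_score), c(0, 100))
  expect_equal(ds$activity_score[2], 25)  # (0 - (-2)) / 8 * 100
})

test_that("standardization canonicalizes, deduplicates and is idempotent", {
  ds <- screenval:::new_screen_tbl(tibble::tibble(
    compound_id = sprintf("C%d", 1:5),
    # three spellings of ethanol + two distinct molecules
    smiles = c("CCO", "OCC", "C(O)C", "c1ccccc1", "CC(=O)Oc1ccccc1C(=O)O"),
    activity_score = c(50, 60, 70, 20, 90),
    primary_label = c(0L, 1L, 0L, 0L, 1L),
    confirmatory_label = c(NA, 0L, NA, NA, 1L)
  ))
  std <- standardize_screen(ds)
  expect_equal(nrow(std), 3)  # oracle canonicalization of the 5 strings
  rep <- drop_report(std)
  expect_equal(rep$n[rep$reason == "merged_duplicate_structure"], 2L)
  # first occurrence kept, labels aggregated by max (active wins)
  eth <- std[std$compound_id == "C1", ]
  expect_equal(eth$smiles, "CCO")
  expect_equal(eth$primary_label, 1L)
  expect_equal(eth$confirmatory_label, 0L)
  # idempotence
  std2 <- standardize_screen(std)
  expect_equal(as.data.frame(std2), as.data.frame(std))
})

test_that("two spellings of benzene map to one canonical string", {
  out <- canonical_smiles(c("C1=CC=CC=C1", "c1ccccc1"))
  expect_equal(out[1], out[2])
})

test_that("write/read round trip reproduces records field-for-field", {
  ds <- make_smiles_screen()
  path <- tempfile(fileext = ".csv")
  write_screen(ds, path)
  back <- read_screen(path, columns = c(smiles = "smiles", score = "activity_score",
                                        primary = "primary_label",
                                        confirmatory = "confirmatory_label",
                                        id = "compound_id"))
  expect_equal(back$compound_id, ds$compound_id)
  expect_equal(back$smiles, ds$smiles)
  expect_equal(back$activity_score, ds$activity_score)
  expect_equal(back$primary_label, ds$primary_label)
  expect_equal(back$confirmatory_label, ds$confirmatory_label)
})

test_that("validation split takes the top-score records exactly", {
  n <- 100
  ds <- screenval:::new_screen_tbl(tibble::tibble(
    compound_id = sprintf("C%03d", 1:n),
    smiles = NA_character_,
    activity_score = as.numeric(sample(1:n)),  # 1..100 distinct, shuffled
    primary_label = rep(c(1L, 0L), 50),
    confirmatory_label = NA_integer_
  ))
  sp <- screen_splits(ds, val_fraction = 0.10, seed = 7)
  expect_equal(length(sp$val_idx), 10)
  expect_setequal(ds$activity_score[sp$val_idx], 91:100)
  # partition: disjoint and exhaustive
  expect_length(intersect(sp$train_idx, sp$val_idx), 0)
  expect_setequal(c(sp$train_idx, sp$val_idx), seq_len(n))
})

test_that("stratified initialization preserves the class ratio exactly", {
  labels <- c(rep(1L, 200), rep(0L, 1800))
  picked <- screenval:::stratified_sample(labels, 30, seed = 3)
  expect_length(picked, 30)
  expect_equal(sum(labels[picked]), 3)  # 30 * 200/2000
})

test_that("tied boundary scores resolve deterministically across calls", {
  ds <- screenval:::new_screen_tbl(tibble::tibble(
    compound_id = sprintf("C%02d", 1:30),
    smiles = NA_character_,
    activity_score = rep(c(10, 50, 90), each = 10),  # ties at the cut
    primary_label = rep(c(0L, 1L), 15),
    confirmatory_label = NA_integer_
  ))
  sp1 <- screen_splits(ds, val_fraction = 0.2, seed = 5)
  sp2 <- screen_splits(ds, val_fraction = 0.2, seed = 5)
  expect_identical(sp1$val_idx, sp2$val_idx)
  expect_identical(sp1$init_idx, sp2$init_idx)
  # ascending-index tie-break: the first score-90 records win
  expect_equal(sp1$val_idx, 21:26)
})

test_that("invalid split fractions and missing actives error", {
  ds <- make_smiles_screen()
  ds30 <- dplyr::bind_rows(replicate(5, ds, simplify = FALSE)) |>
    dplyr::mutate(compound_id = sprintf("X%02d", dplyr::row_number()))
  ds30 <- screenval:::new_screen_tbl(ds30)
  expect_error(screen_splits(ds30, val_fraction = 1.2), "val_fraction")
  expect_error(screen_splits(ds30, init_fraction = 0), "init_fraction")
  inact <- dplyr::mutate(ds30, primary_label = 0L, confirmatory_label = NA_integer_)
  expect_error(screen_splits(screenval:::new_screen_tbl(inact)), "active")
})

test_that("standardization is permutation-equivariant", {
  ds <- make_smiles_screen()[1:5, ]   # distinct molecules only
  ds <- screenval:::new_screen_tbl(ds)
  perm <- c(4, 2, 1, 5, 3)
  dsp <- screenval:::new_screen_tbl(ds[perm, ])
  a <- standardize_screen(ds)
  b <- standardize_screen(dsp)
  expect_equal(b$compound_id, a$compound_id[perm])   # order follows input
  expect_equal(b$smiles, a$smiles[perm])
})
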