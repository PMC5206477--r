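test_that("expr_dataset enforces its structural invariants", {
  X <- matrix(1:6, 2, 3)
  expect_error(expr_dataset(X, 1:3), "row count")
  expect_error(expr_dataset(X, c(1, NA)), "finite")
  ds <- expr_dataset(X, c(1, 2))
  expect_identical(dim(ds), c(2L, 3L))
  expect_identical(ds$gene_ids, c("g1", "g2", "g3"))
  sub <- ds[1, c(1, 3)]
  expect_identical(sub$X, ds$X[1, c(1, 3), drop = FALSE])
  expect_identical(sub$y, ds$y[1])
})

test_that("series matrix parsing transposes probes to gene columns", {
  path <- write_series_matrix_fixture()
  ds <- read_series_matrix(path, dose = c(0.5, 1, 2))
  expect_identical(dim(ds$X), c(3L, 4L))
  expect_identical(ds$gene_ids, c("P1", "P2", "P3", "P4"))
  expect_identical(ds$sample_ids, c("S1", "S2", "S3"))
  expect_equal(ds$X["S2", "P3"], 8)
  expect_false(anyNA(ds$X))
})

test_that("series matrix 'null' cells become missing markers", {
  path <- write_series_matrix_fixture(
    cells = list(list(row = 2, col = 3, value = "null")))
  ds <- read_series_matrix(path, dose = c(0.5, 1, 2))
  expect_identical(sum(is.na(ds$X)), 1L)
  expect_true(is.na(ds$X["S2", "P2"]))
})

test_that("series matrix structural errors are reported", {
  path <- write_series_matrix_fixture(extra_row = "\"P5\"\t1\t2\t3\t4")
  expect_error(read_series_matrix(path, dose = 1:3), "4 values")
  path2 <- tempfile()
  writeLines(c("!series_matrix_table_begin", "a\tb"), path2)
  expect_error(read_series_matrix(path2, dose = 1), "table_begin/table_end")
  path3 <- write_series_matrix_fixture()
  expect_error(read_series_matrix(path3), "no response")
  # dose via a characteristics key
  ds <- read_series_matrix(path3, dose_key = "dose")
  expect_equal(ds$y, c(1, 2.5, 4))
})

test_that("preprocessing log2-transforms, drops and imputes as documented", {
  X <- matrix(c(1, 3, 7), 1, 3)
  ds <- expr_dataset(X, 5)
  expect_equal(as.numeric(preprocess_dataset(ds, already_log2 = FALSE,
                                             max_missing_fraction = 1)$X),
               c(1, 2, 3))
  # 10-sample gene with 3 missing dropped at threshold 0.2; a gene with
  # 1 missing median-imputed
  set.seed(1)
  X2 <- matrix(rnorm(30), 10, 3)
  X2[1:3, 1] <- NA
  X2[4, 2] <- NA
  X2[-4, 2] <- c(1, 2, 3, 4, 5.5, 6, 7, 8, 10)  # observed median 5.5
  ds2 <- expr_dataset(X2, rnorm(10))
  out <- preprocess_dataset(ds2, already_log2 = TRUE,
                            max_missing_fraction = 0.2)
  expect_identical(ncol(out$X), 2L)
  expect_false("g1" %in% out$gene_ids)
  expect_equal(out$X[4, "g2"], 5.5)
  expect_false(anyNA(out$X))
  # fully missing gene always dropped, even at threshold 1
  X3 <- cbind(rep(NA_real_, 5), rnorm(5))
  out3 <- preprocess_dataset(expr_dataset(X3, rnorm(5)),
                             already_log2 = TRUE,
                             max_missing_fraction = 1)
  expect_identical(ncol(out3$X), 1L)
  expect_error(preprocess_dataset(expr_dataset(X3[, 1, drop = FALSE],
                                               rnorm(5)),
                                  already_log2 = TRUE),
               "every gene")
})

test_that("preprocessing is idempotent on clean log2 data", {
  ds <- toy_dataset(12, 3, seed = 7)
  once <- preprocess_dataset(ds, already_log2 = TRUE)
  twice <- preprocess_dataset(once, already_log2 = TRUE)
  expect_identical(once$X, twice$X)
  expect_identical(once$y, twice$y)
})

test_that("train/test split sizes follow round-half-away-from-zero", {
  ds10 <- toy_dataset(10, 2)
  sp <- split_train_test(ds10, 0.7, seed = 3)
  expect_identical(nrow(sp$train$X), 7L)
  expect_identical(nrow(sp$test$X), 3L)
  ds69 <- toy_dataset(69, 2)
  sp69 <- split_train_test(ds69, 0.7, seed = 3)
  expect_identical(nrow(sp69$train$X), 48L)
  expect_identical(nrow(sp69$test$X), 21L)
  # same seed, same partition
  sp2 <- split_train_test(ds10, 0.7, seed = 3)
  expect_identical(sp$train$sample_ids, sp2$train$sample_ids)
})

test_that("split partitions are exhaustive and disjoint across seeds", {
  ds <- toy_dataset(11, 2)
  for (seed in 1:1000) {
    sp <- split_train_test(ds, 0.7, seed = seed)
    ids <- c(sp$train$sample_ids, sp$test$sample_ids)
    expect_length(intersect(sp$train$sample_ids, sp$test$sample_ids), 0)
    expect_setequal(ids, ds$sample_ids)
  }
})

test_that("TSV round trip reproduces X and y bit-exactly", {
  ds <- toy_dataset(15, 6, seed = 42)
  ds$X[3, 2] <- NA  # missing survives the dialect
  path <- tempfile(fileext = ".tsv")
  write_expr_tsv(ds, path)
  back <- read_expr_tsv(path)
  expect_identical(unname(back$X), unname(ds$X))
  expect_identical(back$y, ds$y)
  expect_identical(back$gene_ids, ds$gene_ids)
  expect_identical(back$sample_ids, ds$sample_ids)
})
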