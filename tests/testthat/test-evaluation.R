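test_that("metrics match hand-computed values", {
  m <- compute_metrics(c(4, 7, 9), c(4, 7, 9))
  expect_equal(m$rmse, 0)
  expect_equal(m$mad, 0)
  expect_equal(m$r2, 1)
  m2 <- compute_metrics(c(1, 2, 3), c(1, 3, 2))
  expect_equal(m2$rmse, sqrt(2 / 3))
  expect_equal(m2$mad, 2 / 3)
  expect_equal(m2$r2, 0)
  # predicting the observed mean gives r2 exactly 0
  y <- c(2, 4, 9, 1)
  m3 <- compute_metrics(y, rep(mean(y), 4))
  expect_equal(m3$r2, 0)
  # constant observed vector: r2 flagged missing, rmse/mad valid
  m4 <- compute_metrics(c(3, 3, 3), c(2, 3, 4))
  expect_true(is.na(m4$r2))
  expect_equal(m4$rmse, sqrt(2 / 3))
  expect_equal(m4$mad, 2 / 3)
})

test_that("metrics agree with the arithmetic oracle on random vectors", {
  set.seed(51)
  for (i in 1:300) {
    n <- sample(2:40, 1)
    y <- rnorm(n, sd = runif(1, 0.1, 10))
    yhat <- y + rnorm(n, sd = runif(1, 0, 5))
    mine <- compute_metrics(y, yhat)
    ref <- oracle_metrics(y, yhat)
    expect_equal(mine$rmse, ref$rmse, tolerance = 1e-10)
    expect_equal(mine$mad, ref$mad, tolerance = 1e-10)
    expect_equal(mine$r2, ref$r2, tolerance = 1e-10)
    expect_equal(mine$rmse^2 * mine$n, mine$sse, tolerance = 1e-10)
  }
})

test_that("grid tuning is a deterministic argmin with documented ties", {
  set.seed(52)
  X <- matrix(rnorm(80), 40, 2)
  y <- as.numeric(X %*% c(1, -1)) + rnorm(40, sd = 0.1)
  # singleton grid returned untouched
  cfg <- tune_esvr(X, y, kernel = "linear", cost = 1, epsilon = 0.1,
                   folds = 5, seed = 1)
  expect_equal(cfg$cost, 1)
  expect_equal(cfg$epsilon, 0.1)
  # seeded runs agree
  a <- tune_esvr(X, y, kernel = "linear", cost = c(0.1, 1, 10),
                 epsilon = c(0.05, 0.2), folds = 5, seed = 4)
  b <- tune_esvr(X, y, kernel = "linear", cost = c(0.1, 1, 10),
                 epsilon = c(0.05, 0.2), folds = 5, seed = 4)
  expect_identical(a[c("cost", "epsilon", "cv_mse")],
                   b[c("cost", "epsilon", "cv_mse")])
  # winner attains the minimum CV MSE of the table
  expect_equal(a$cv_mse, min(a$cv_table$cv_mse))
  # tree grid: singleton identity and determinism
  ctrl <- tune_rtree(X, y, min_node_size = 5, cp = 0.01, max_depth = 3,
                     folds = 5, seed = 1)
  expect_identical(ctrl$min_node_size, 5L)
  expect_identical(ctrl$max_depth, 3L)
  t1 <- tune_rtree(X, y, folds = 5, seed = 9)
  t2 <- tune_rtree(X, y, folds = 5, seed = 9)
  expect_identical(unclass(t1)[], unclass(t2)[])
})

test_that("tuning lowers the fold count with a warning on tiny n", {
  set.seed(53)
  X <- matrix(rnorm(12), 6, 2)
  y <- rnorm(6)
  expect_warning(
    tune_rtree(X, y, min_node_size = 2, cp = 0.01, max_depth = 2,
               folds = 10, seed = 1),
    "fewer samples")
})

test_that("repeated holdout is deterministic and prefix-stable", {
  ds <- toy_dataset(30, 3, seed = 3)
  r1 <- repeated_holdout(ds, methods = "rt", n_splits = 3, seed = 7,
                         tune = "none")
  r2 <- repeated_holdout(ds, methods = "rt", n_splits = 3, seed = 7,
                         tune = "none")
  expect_identical(r1$per_split, r2$per_split)
  expect_identical(nrow(r1$per_split), 3L)
  # growing n_splits preserves the earlier splits' values
  r4 <- repeated_holdout(ds, methods = "rt", n_splits = 5, seed = 7,
                         tune = "none")
  expect_identical(r4$per_split[1:3, ], r1$per_split)
})

test_that("holdout summary equals column statistics of per-split table", {
  ds <- toy_dataset(40, 3, seed = 5)
  res <- repeated_holdout(ds, methods = c("rt", "gbm"), n_splits = 4,
                          seed = 2, tune = "none", gbm_stages = 20)
  for (m in c("rt", "gbm")) {
    d <- res$per_split[res$per_split$method == m, ]
    s <- res$summary[res$summary$method == m, ]
    expect_equal(s$mean_rmse, mean(d$rmse), tolerance = 1e-12)
    expect_equal(s$sd_rmse, sd(d$rmse), tolerance = 1e-12)
    expect_equal(s$mean_r2, mean(d$r2), tolerance = 1e-12)
  }
  expect_error(repeated_holdout(ds, methods = "boosted-svm"), "unknown")
})

test_that("linear SVR beats a single tree on linear dose-gene data", {
  # the pattern seen on near-linear expression datasets: a linear
  # kernel SVR explains more test variance than one CART tree
  ds <- synthetic_dataset(gse2409_like_config(), n = 69, seed = 11)
  res <- repeated_holdout(ds, methods = c("svr-linear", "rt"),
                          n_splits = 12, seed = 21, folds = 5)
  s <- res$summary
  expect_gt(s$mean_r2[s$method == "svr-linear"],
            s$mean_r2[s$method == "rt"])
  expect_identical(unique(table(res$per_split$method)), 12L)
})

test_that("the permutation extension separates signal from shuffled dose", {
  ds <- toy_dataset(30, 3, seed = 8, noise_sd = 0.2)
  pt <- r2_permutation_test(ds, method = "rt", n_splits = 4,
                            n_perm = 9, seed = 3, tune = "none")
  expect_gt(pt$observed, max(pt$null))
  expect_equal(pt$p_value, 1 / 10)
  expect_length(pt$null, 9)
})
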