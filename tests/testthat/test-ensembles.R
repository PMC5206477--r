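test_that("bagging with the identity resample equals the base learner", {
  set.seed(41)
  X <- matrix(rnorm(60), 30, 2)
  y <- X[, 1]^2 + rnorm(30, sd = 0.2)
  bag <- bagging(X, y, base = "rtree", B = 1L, seed = 9,
                 .resample = function(n, b) seq_len(n))
  single <- rtree(X, y)
  expect_equal(predict(bag, X), predict(single, X), tolerance = 1e-12)
})

test_that("bagging prediction is the member mean and stays in range", {
  members <- lapply(c(1, 2, 3), function(v)
    structure(list(value = v), class = "constant_predictor"))
  bag <- structure(list(members = members, B = 3L, base = "custom",
                        predict_member = function(m, x)
                          rep(m$value, nrow(x))),
                   class = "bagging")
  X <- matrix(0, 4, 1)
  expect_equal(predict(bag, X), rep(2, 4))
  # two members 0 and 10 -> 5
  bag2 <- bag
  bag2$members <- members[c(1, 3)]
  bag2$members[[1]]$value <- 0
  bag2$members[[2]]$value <- 10
  bag2$B <- 2L
  expect_equal(predict(bag2, X), rep(5, 4))
  # mean bound for a real ensemble
  set.seed(42)
  Xr <- matrix(rnorm(80), 40, 2)
  yr <- Xr[, 1] + rnorm(40, sd = 0.3)
  bag3 <- bagging(Xr, yr, base = "esvr", B = 5L, seed = 2, cost = 1,
                  epsilon = 0.1, kernel = "linear")
  Xt <- matrix(rnorm(20), 10, 2)
  per_member <- sapply(bag3$members, function(m) predict(m, Xt))
  p <- predict(bag3, Xt)
  expect_true(all(p >= apply(per_member, 1, min) - 1e-12))
  expect_true(all(p <= apply(per_member, 1, max) + 1e-12))
  expect_equal(p, rowMeans(per_member), tolerance = 1e-12)
})

test_that("bagging is deterministic given the top-level seed", {
  set.seed(43)
  X <- matrix(rnorm(60), 30, 2)
  y <- rnorm(30)
  b1 <- bagging(X, y, base = "rtree", B = 8L, seed = 77)
  b2 <- bagging(X, y, base = "rtree", B = 8L, seed = 77)
  Xt <- matrix(rnorm(10), 5, 2)
  expect_identical(predict(b1, Xt), predict(b2, Xt))
  b3 <- bagging(X, y, base = "rtree", B = 8L, seed = 78)
  expect_false(identical(predict(b1, Xt), predict(b3, Xt)))
})

test_that("degenerate bootstrap draws become constant members", {
  X <- matrix(1:6, 6, 1)
  y <- c(5, 5, 5, 5, 5, 9)
  # force a resample hitting only the constant block
  bag <- bagging(X, y, base = "rtree", B = 1L, seed = 1,
                 .resample = function(n, b) rep(1L, n))
  expect_s3_class(bag$members[[1]], "constant_predictor")
  expect_equal(predict(bag, X), rep(5, 6))
})

test_that("bagged trees beat a single tree on noisy nonlinear data", {
  # variance-reduction property, averaged over seeded replicates
  deltas <- vapply(1:10, function(s) {
    set.seed(500 + s)
    n <- 100
    X <- matrix(runif(n * 2, -2, 2), n, 2)
    f <- X[, 1]^2 + X[, 2]
    y <- f + rnorm(n)
    Xt <- matrix(runif(400, -2, 2), 200, 2)
    yt <- Xt[, 1]^2 + Xt[, 2] + rnorm(200)
    single <- rtree(X, y)
    bag <- bagging(X, y, base = "rtree", B = 25L, seed = s)
    sqrt(mean((yt - predict(single, Xt))^2)) -
      sqrt(mean((yt - predict(bag, Xt))^2))
  }, numeric(1))
  expect_gt(mean(deltas), 0)
})

test_that("boosting stages reduce training loss as specified", {
  set.seed(44)
  X <- matrix(rnorm(50), 50, 1)
  y <- as.numeric(X[, 1] > 0) * 3 + rnorm(50, sd = 0.1)
  # M = 0 predicts the mean everywhere
  m0 <- rt_boost(X, y, M = 0L)
  expect_equal(predict(m0, X), rep(mean(y), 50))
  # stumps with shrinkage: strictly decreasing early losses
  m <- rt_boost(X, y, M = 25L, nu = 0.1, max_depth = 1L,
                min_node_size = 5L)
  expect_true(all(diff(m$stage_losses[1:20]) < 0))
  expect_true(all(diff(m$stage_losses) <= 1e-12))
  # nu = 1, deep tree, one stage memorises the data (y constant within
  # x-duplicates so the minimum node size is not binding)
  yd2 <- rep(rnorm(10), each = 2)
  Xd2 <- matrix(rep(1:10, each = 2), 20, 1)
  m2 <- rt_boost(Xd2, yd2, M = 1L, nu = 1, max_depth = 30L,
                 min_node_size = 2L, cp = 0)
  expect_equal(m2$stage_losses[1], 0, tolerance = 1e-20)
})

test_that("boosting prediction equals stagewise evaluation", {
  set.seed(45)
  X <- matrix(rnorm(60), 30, 2)
  y <- X[, 1] + rnorm(30, sd = 0.3)
  m <- rt_boost(X, y, M = 15L, nu = 0.3)
  Xt <- matrix(rnorm(12), 6, 2)
  manual <- rep(m$f0, 6)
  for (tr in m$stages) manual <- manual + m$nu * predict(tr, Xt)
  expect_equal(predict(m, Xt), manual, tolerance = 1e-12)
  # single stage with nu = 1 is f0 + tree
  m1 <- rt_boost(X, y, M = 1L, nu = 1)
  expect_equal(predict(m1, Xt),
               m1$f0 + predict(m1$stages[[1]], Xt), tolerance = 1e-12)
  # staged matrix output matches suffix evaluations
  staged <- predict(m, Xt, n_stages = c(0L, 7L, 15L))
  expect_equal(staged[, "0"], rep(m$f0, 6))
  expect_equal(staged[, "15"], predict(m, Xt), tolerance = 1e-12)
  expect_equal(staged[, "7"], predict(m, Xt, n_stages = 7L),
               tolerance = 1e-12)
})

test_that("model JSON serialisation is self-consistent", {
  set.seed(46)
  X <- matrix(rnorm(40), 20, 2)
  y <- X[, 1] + rnorm(20, sd = 0.2)
  tr <- rtree(X, y)
  js <- jsonlite::fromJSON(model_to_json(tr), simplifyVector = FALSE)
  expect_identical(js$type, "rtree")
  expect_false(js$root$leaf)
  m <- esvr(X, y, cost = 2, epsilon = 0.1, kernel = "linear")
  js2 <- jsonlite::fromJSON(model_to_json(m), simplifyVector = FALSE)
  expect_identical(js2$type, "esvr")
  expect_length(js2$dual_coefs, length(m$dual_coefs))
  bag <- bagging(X, y, base = "rtree", B = 3L, seed = 1)
  js3 <- jsonlite::fromJSON(model_to_json(bag), simplifyVector = FALSE)
  expect_length(js3$members, 3L)
})
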