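#' Bootstrap-aggregated regression
#'
#' Generic bagging over any fit/predict learner in the package: member
#' `b` is trained on `n` indices drawn i.i.d. uniformly with
#' replacement, seeded as `seed + b` so the whole ensemble is
#' reproducible from the top-level seed, and predictions are the
#' unweighted mean over members. The same base configuration is shared
#' by every member.
#'
#' @param x,y training data.
#' @param base `"rtree"` or `"esvr"`, or a list `(fit, predict)` of
#'   functions for a custom learner (`fit(x, y)` returning a model,
#'   `predict(model, x)` returning a numeric vector).
#' @param B ensemble size (default 50 bootstrap repetitions).
#' @param seed integer seed for the bootstrap draws.
#' @param ... base-learner configuration passed to every member
#'   (e.g. `control =` for trees, `cost =`/`epsilon =` for SVR).
#' @param .resample test hook: a function `(n, b)` returning the member
#'   row indices; defaults to the seeded bootstrap.
#' @return An object of class `"bagging"` with `members`, `B`,
#'   `base_config`, and the per-member `seeds`.
#' @export
bagging <- function(x, y, base = "rtree", B = 50L, seed = 1L, ...,
                    .resample = NULL) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- length(y)
  B <- as.integer(B)
  if (B < 1L) stop("B must be >= 1")
  learner <- bagging_learner(base, ...)
  seeds <- as.integer(seed) + seq_len(B)
  if (is.null(.resample))
    .resample <- function(n, b) with_seed(seeds[b],
                                          sample.int(n, n, replace = TRUE))
  members <- vector("list", B)
  for (b in seq_len(B)) {
    idx <- .resample(n, b)
    yb <- y[idx]
    if (stats::var(yb) == 0) {
      # degenerate bootstrap: constant-response member
      members[[b]] <- structure(list(value = yb[1]),
                                class = "constant_predictor")
    } else {
      members[[b]] <- learner$fit(x[idx, , drop = FALSE], yb)
    }
  }
  structure(list(members = members, B = B,
                 base = if (is.character(base)) base else "custom",
                 base_config = list(...), seeds = seeds,
                 predict_member = learner$predict),
            class = "bagging")
}

bagging_learner <- function(base, ...) {
  if (is.list(base) && !is.null(base$fit) && !is.null(base$predict))
    return(base)
  cfg <- list(...)
  switch(base,
         rtree = list(
           fit = function(x, y) do.call(rtree, c(list(x, y), cfg)),
           predict = function(m, x) predict(m, x)),
         esvr = list(
           fit = function(x, y) do.call(esvr, c(list(x, y), cfg)),
           predict = function(m, x) predict(m, x)),
         stop("unknown base learner '", base, "'"))
}

#' @export
predict.constant_predictor <- function(object, newdata, ...)
  rep(object$value, nrow(as.matrix(newdata)))

#' Predict from a bagged ensemble
#'
#' Row-wise arithmetic mean of member predictions.
#'
#' @param object a [bagging()] model.
#' @param newdata feature matrix.
#' @param ... ignored.
#' @return Numeric vector of averaged predictions.
#' @export
predict.bagging <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  acc <- numeric(nrow(newdata))
  for (m in object$members) {
    acc <- acc + if (inherits(m, "constant_predictor"))
      rep(m$value, nrow(newdata)) else object$predict_member(m, newdata)
  }
  acc / object$B
}

#' @export
print.bagging <- function(x, ...) {
  cat("Bagged ensemble of ", x$B, " ", x$base, " members\n", sep = "")
  invisible(x)
}

#' Gradient boosting of regression trees (squared loss)
#'
#' Stagewise additive modelling: start from the constant fit `f0 =
#' mean(y)`; at stage m fit a depth-limited regression tree to the
#' current residuals `y - f_{m-1}(x)` (the negative gradient of squared
#' loss) and update `f_m = f_{m-1} + nu * tree`. With `nu <= 1` the
#' training loss is non-increasing in m. Deterministic: no subsampling.
#'
#' @param x,y training data.
#' @param M number of boosting stages (`M = 0` gives the constant fit).
#' @param nu shrinkage (learning rate) in (0, 1].
#' @param max_depth,min_node_size,cp stage-tree size controls (shallow
#'   trees: default depth 3).
#' @return An object of class `"rt_boost"` with `f0`, the list of stage
#'   trees, `nu`, `M` and `stage_losses` (mean squared training loss
#'   after each stage).
#' @export
rt_boost <- function(x, y, M = 100L, nu = 0.1, max_depth = 3L,
                     min_node_size = 5L, cp = 0) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  M <- as.integer(M)
  if (M < 0L) stop("M must be >= 0")
  if (nu <= 0 || nu > 1) stop("nu must lie in (0, 1]")
  ctrl <- rtree_control(min_node_size = min_node_size, cp = cp,
                        max_depth = max_depth)
  f0 <- mean(y)
  f <- rep(f0, length(y))
  stages <- vector("list", M)
  stage_losses <- numeric(M)
  for (m in seq_len(M)) {
    r <- y - f
    tr <- rtree(x, r, control = ctrl)
    f <- f + nu * predict(tr, x)
    stages[[m]] <- tr
    stage_losses[m] <- mean((y - f)^2)
  }
  structure(list(f0 = f0, stages = stages, nu = nu, M = M,
                 stage_losses = stage_losses,
                 control = ctrl),
            class = "rt_boost")
}

#' Predict from a boosted tree model
#'
#' Evaluates the additive expansion `f0 + nu * sum_m tree_m(x)`. With
#' `n_stages` the expansion can be truncated, which is how the
#' cross-validated choice of M evaluates every candidate from a single
#' fit.
#'
#' @param object an [rt_boost()] model.
#' @param newdata feature matrix.
#' @param n_stages evaluate only the first `n_stages` trees (default all).
#' @param ... ignored.
#' @return Numeric vector of predictions, or a matrix with one column
#'   per requested stage count when `n_stages` has length > 1.
#' @export
predict.rt_boost <- function(object, newdata, n_stages = object$M, ...) {
  newdata <- as.matrix(newdata)
  n_stages <- as.integer(n_stages)
  if (any(n_stages < 0L | n_stages > object$M))
    stop("n_stages out of range")
  maxm <- max(n_stages, 0L)
  f <- rep(object$f0, nrow(newdata))
  if (length(n_stages) == 1L) {
    for (m in seq_len(n_stages))
      f <- f + object$nu * predict(object$stages[[m]], newdata)
    return(f)
  }
  out <- matrix(NA_real_, nrow(newdata), length(n_stages),
                dimnames = list(NULL, n_stages))
  hit <- match(0L, n_stages)
  if (!is.na(hit)) out[, hit] <- f
  for (m in seq_len(maxm)) {
    f <- f + object$nu * predict(object$stages[[m]], newdata)
    hit <- match(m, n_stages)
    if (!is.na(hit)) out[, hit] <- f
  }
  out
}

#' @export
print.rt_boost <- function(x, ...) {
  cat("Gradient-boosted regression trees: M = ", x$M, ", nu = ", x$nu,
      ", stage depth <= ", x$control$max_depth, "\n", sep = "")
  if (x$M > 0)
    cat("  final training MSE: ", format(x$stage_losses[x$M]), "\n",
        sep = "")
  invisible(x)
}
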