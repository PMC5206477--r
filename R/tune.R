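#' Cross-validated grid tuning for the SVR and tree learners
#'
#' Exhaustive grid search minimising the mean k-fold cross-validated
#' squared prediction error on the training data, with the fold
#' assignment drawn once under `seed` and shared by every candidate so
#' the comparison is paired. Default grids: `C` in `10^(-2..2)` (5
#' points), `epsilon` in `{0.05, 0.10, 0.20}`, and for the polynomial
#' kernel `gamma` in `10^(-3..2)` (6 points); for trees
#' `min_node_size` in `{2, 5, 10}`, `cp` in `{0.001, 0.01, 0.05}`,
#' `max_depth` in `{2, 3, 5, 10}`. Ties are broken toward the smaller
#' `C`, then smaller `epsilon` (then smaller `gamma`); tree grids break
#' toward the earlier grid point in the documented order. When `n` is
#' smaller than `folds` the fold count is lowered to `n` with a warning
#' (leave-one-out).
#'
#' @param x,y training data (or `x` an [expr_dataset()]).
#' @param kernel SVR kernel to tune, `"linear"` or `"polynomial"`.
#' @param cost,epsilon,gamma candidate grids (SVR).
#' @param min_node_size,cp,max_depth candidate grids (trees).
#' @param folds cross-validation folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @return `tune_esvr`: a list with the winning `cost`, `epsilon`
#'   (+ `gamma`, `degree`, `coef0` for polynomial), the `kernel`, the
#'   winning `cv_mse` and the full `cv_table`. `tune_rtree`: an
#'   [rtree_control()] with `cv_mse` and `cv_table` attributes.
#' @export
tune_esvr <- function(x, y = NULL, kernel = c("linear", "polynomial"),
                      cost = 10^(-2:2), epsilon = c(0.05, 0.10, 0.20),
                      gamma = 10^(-3:2), folds = 10L, seed = 1L) {
  kernel <- match.arg(kernel)
  if (inherits(x, "expr_dataset")) { y <- x$y; x <- x$X }
  x <- as.matrix(x); y <- as.numeric(y)
  grid <- if (kernel == "linear")
    expand.grid(epsilon = epsilon, cost = cost)[, c("cost", "epsilon")]
  else
    expand.grid(gamma = gamma, epsilon = epsilon,
                cost = cost)[, c("cost", "epsilon", "gamma")]
  fit_one <- function(xtr, ytr, cfg)
    esvr(xtr, ytr, cost = cfg$cost, epsilon = cfg$epsilon,
         kernel = kernel,
         gamma = if (kernel == "polynomial") cfg$gamma else NULL)
  res <- cv_grid(x, y, grid, fit_one, folds, seed)
  best <- res$grid[res$best, , drop = FALSE]
  out <- list(kernel = kernel, cost = best$cost, epsilon = best$epsilon,
              cv_mse = res$mse[res$best], cv_table = cbind(res$grid,
                                                           cv_mse = res$mse))
  if (kernel == "polynomial") {
    out$gamma <- best$gamma
    out$degree <- 2L
    out$coef0 <- 1
  }
  out
}

#' @rdname tune_esvr
#' @export
tune_rtree <- function(x, y = NULL, min_node_size = c(2L, 5L, 10L),
                       cp = c(0.001, 0.01, 0.05),
                       max_depth = c(2L, 3L, 5L, 10L),
                       folds = 10L, seed = 1L) {
  if (inherits(x, "expr_dataset")) { y <- x$y; x <- x$X }
  x <- as.matrix(x); y <- as.numeric(y)
  grid <- expand.grid(max_depth = max_depth, cp = cp,
                      min_node_size = min_node_size)[,
                        c("min_node_size", "cp", "max_depth")]
  fit_one <- function(xtr, ytr, cfg)
    rtree(xtr, ytr, rtree_control(min_node_size = cfg$min_node_size,
                                  cp = cfg$cp, max_depth = cfg$max_depth))
  res <- cv_grid(x, y, grid, fit_one, folds, seed)
  best <- res$grid[res$best, , drop = FALSE]
  ctrl <- rtree_control(min_node_size = best$min_node_size, cp = best$cp,
                        max_depth = best$max_depth)
  attr(ctrl, "cv_mse") <- res$mse[res$best]
  attr(ctrl, "cv_table") <- cbind(res$grid, cv_mse = res$mse)
  ctrl
}

# shared k-fold CV over a config grid; ties resolved to the earliest
# grid row (grids are ordered so that earlier = smaller C/epsilon/...)
cv_grid <- function(x, y, grid, fit_one, folds, seed) {
  n <- length(y)
  folds <- as.integer(folds)
  if (n < folds) {
    warning("fewer samples (", n, ") than folds; lowering folds to n")
    folds <- n
  }
  foldid <- make_folds(n, folds, seed)
  mse <- numeric(nrow(grid))
  for (gidx in seq_len(nrow(grid))) {
    cfg <- grid[gidx, , drop = FALSE]
    err <- 0
    for (f in seq_len(folds)) {
      tr <- foldid != f
      model <- fit_one(x[tr, , drop = FALSE], y[tr], cfg)
      pred <- predict(model, x[!tr, , drop = FALSE])
      err <- err + sum((y[!tr] - pred)^2)
    }
    mse[gidx] <- err / n
  }
  list(grid = grid, mse = mse, best = which.min(mse))
}

# cross-validated choice of the boosting stage count from a single
# full-length fit per fold, scoring every candidate M on the staged path
tune_boost_stages <- function(x, y, M_grid = seq(50L, 500L, by = 50L),
                              nu = 0.1, max_depth = 3L, min_node_size = 5L,
                              folds = 10L, seed = 1L) {
  n <- length(y)
  folds <- as.integer(min(folds, n))
  foldid <- make_folds(n, folds, seed)
  M_max <- max(M_grid)
  err <- numeric(length(M_grid))
  for (f in seq_len(folds)) {
    tr <- foldid != f
    fit <- rt_boost(x[tr, , drop = FALSE], y[tr], M = M_max, nu = nu,
                    max_depth = max_depth, min_node_size = min_node_size)
    pred <- predict(fit, x[!tr, , drop = FALSE], n_stages = M_grid)
    err <- err + colSums((y[!tr] - pred)^2)
  }
  M_grid[which.min(err)]
}
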