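#' Repeated 70/30 holdout benchmark of the dose-prediction methods
#'
#' The evaluation protocol used throughout the package: each split
#' partitions the dataset into 70% training / 30% test, tunes the tree
#' and SVR hyperparameters on the training part by 10-fold
#' cross-validation, fits every requested method on the training part
#' with those tuned settings (a method's single and ensemble variants
#' share the same configuration within a split), computes RMSE, MAD and
#' R-squared on the test part, and finally averages over splits.
#' Split k draws its partition from `seed + k`, so results for the
#' first `k` splits do not change when `n_splits` grows.
#'
#' @param ds an [expr_dataset()] (typically after feature selection).
#' @param methods subset of `c("svr-linear", "svr-polynomial",
#'   "svr-bagging", "rt", "rt-bagging", "gbm")`.
#' @param n_splits number of random splits (default 100).
#' @param seed master integer seed.
#' @param train_fraction training share (default 0.7).
#' @param bags bagging repetitions for the `*-bagging` methods
#'   (default 50).
#' @param tune `"per-split"` (default) retunes on every training part;
#'   `"global"` tunes once on the full dataset and reuses the
#'   configuration; `"none"` uses package defaults.
#' @param gbm_stages fixed boosting stage count, or `"cv"` to pick it by
#'   10-fold cross-validation over 50..500 per split.
#' @param folds tuning folds (default 10).
#' @return An object of class `"eval_result"`: `per_split` (long table
#'   split x method with `rmse`, `mad`, `r2`), `summary` (mean and sd
#'   per method), `failures` (methods that errored on a split, recorded
#'   and skipped), `n_splits`, `seed`.
#' @export
repeated_holdout <- function(ds, methods = c("svr-linear", "rt"),
                             n_splits = 100L, seed = 1L,
                             train_fraction = 0.7, bags = 50L,
                             tune = c("per-split", "global", "none"),
                             gbm_stages = 100L, folds = 10L) {
  stopifnot(inherits(ds, "expr_dataset"))
  tune <- match.arg(tune)
  known <- c("svr-linear", "svr-polynomial", "svr-bagging", "rt",
             "rt-bagging", "gbm")
  bad <- setdiff(methods, known)
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "))
  n_splits <- as.integer(n_splits)

  need_rt <- any(methods %in% c("rt", "rt-bagging"))
  need_svr_lin <- any(methods %in% c("svr-linear", "svr-bagging"))
  need_svr_pol <- "svr-polynomial" %in% methods

  global_cfg <- NULL
  if (tune == "global")
    global_cfg <- tune_configs(ds$X, ds$y, need_rt, need_svr_lin,
                               need_svr_pol, folds, seed)

  rows <- vector("list", n_splits * length(methods))
  failures <- list()
  ri <- 0L
  for (k in seq_len(n_splits)) {
    sp <- split_train_test(ds, train_fraction, seed = seed + k)
    xtr <- sp$train$X; ytr <- sp$train$y
    xte <- sp$test$X; yte <- sp$test$y
    cfg <- switch(tune,
                  "per-split" = tune_configs(xtr, ytr, need_rt,
                                             need_svr_lin, need_svr_pol,
                                             folds, seed + k),
                  "global" = global_cfg,
                  "none" = list())
    for (m in methods) {
      ri <- ri + 1L
      met <- tryCatch({
        pred <- fit_predict_method(m, xtr, ytr, xte, cfg, bags,
                                   gbm_stages, folds,
                                   seed = seed + k)
        compute_metrics(yte, pred)
      }, error = function(e) {
        failures[[length(failures) + 1L]] <<-
          list(split = k, method = m, message = conditionMessage(e))
        NULL
      })
      rows[[ri]] <- data.frame(
        split = k, method = m,
        rmse = if (is.null(met)) NA_real_ else met$rmse,
        mad = if (is.null(met)) NA_real_ else met$mad,
        r2 = if (is.null(met)) NA_real_ else met$r2,
        stringsAsFactors = FALSE)
    }
  }
  per_split <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(per_split, per_split$method),
    function(d) data.frame(
      method = d$method[1L],
      mean_rmse = mean(d$rmse, na.rm = TRUE),
      sd_rmse = stats::sd(d$rmse, na.rm = TRUE),
      mean_mad = mean(d$mad, na.rm = TRUE),
      sd_mad = stats::sd(d$mad, na.rm = TRUE),
      mean_r2 = mean(d$r2, na.rm = TRUE),
      sd_r2 = stats::sd(d$r2, na.rm = TRUE),
      n_ok = sum(!is.na(d$rmse)),
      stringsAsFactors = FALSE)))
  rownames(summary) <- NULL
  summary <- summary[match(methods, summary$method), , drop = FALSE]
  structure(list(per_split = per_split, summary = summary,
                 failures = failures, n_splits = n_splits,
                 seed = as.integer(seed), methods = methods,
                 tune = tune),
            class = "eval_result")
}

tune_configs <- function(x, y, need_rt, need_svr_lin, need_svr_pol,
                         folds, seed) {
  cfg <- list()
  if (need_rt)
    cfg$rt <- tune_rtree(x, y, folds = folds, seed = seed)
  if (need_svr_lin)
    cfg$svr_linear <- tune_esvr(x, y, kernel = "linear", folds = folds,
                                seed = seed)
  if (need_svr_pol)
    cfg$svr_poly <- tune_esvr(x, y, kernel = "polynomial", folds = folds,
                              seed = seed)
  cfg
}

fit_predict_method <- function(method, xtr, ytr, xte, cfg, bags,
                               gbm_stages, folds, seed) {
  switch(method,
    "svr-linear" = {
      cc <- cfg$svr_linear %||% list(cost = 1, epsilon = 0.1)
      predict(esvr(xtr, ytr, cost = cc$cost, epsilon = cc$epsilon,
                   kernel = "linear"), xte)
    },
    "svr-polynomial" = {
      cc <- cfg$svr_poly %||% list(cost = 1, epsilon = 0.1, gamma = NULL)
      predict(esvr(xtr, ytr, cost = cc$cost, epsilon = cc$epsilon,
                   kernel = "polynomial", gamma = cc$gamma), xte)
    },
    "svr-bagging" = {
      cc <- cfg$svr_linear %||% list(cost = 1, epsilon = 0.1)
      predict(bagging(xtr, ytr, base = "esvr", B = bags,
                      seed = seed + 100000L,
                      cost = cc$cost, epsilon = cc$epsilon,
                      kernel = "linear"), xte)
    },
    "rt" = {
      ctrl <- cfg$rt %||% rtree_control()
      predict(rtree(xtr, ytr, control = ctrl), xte)
    },
    "rt-bagging" = {
      ctrl <- cfg$rt %||% rtree_control()
      predict(bagging(xtr, ytr, base = "rtree", B = bags,
                      seed = seed + 200000L, control = ctrl), xte)
    },
    "gbm" = {
      M <- if (identical(gbm_stages, "cv"))
        tune_boost_stages(xtr, ytr, folds = folds, seed = seed)
      else as.integer(gbm_stages)
      predict(rt_boost(xtr, ytr, M = M), xte)
    })
}

#' @export
print.eval_result <- function(x, ...) {
  cat("Repeated holdout: ", x$n_splits, " splits (seed ", x$seed,
      ", tuning: ", x$tune, ")\n", sep = "")
  print(x$summary, row.names = FALSE, digits = 4)
  if (length(x$failures))
    cat("  ", length(x$failures), " method/split failures recorded\n",
        sep = "")
  invisible(x)
}

#' @export
summary.eval_result <- function(object, ...) object$summary

#' Box plot of per-split RMSE by method
#'
#' The distribution view used to compare single and ensemble learners:
#' one box per method over the per-split test RMSE values.
#'
#' @param x an [repeated_holdout()] result.
#' @param metric one of `"rmse"`, `"mad"`, `"r2"`.
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.eval_result <- function(x, metric = "rmse", ...) {
  d <- x$per_split
  graphics::boxplot(d[[metric]] ~ factor(d$method, levels = x$methods),
                    xlab = "method", ylab = toupper(metric), ...)
  invisible(x)
}
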