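#' Configuration for the training-set-size sweep
#'
#' The Monte-Carlo experiment that compares a single regression tree,
#' bagged trees and boosted trees as the training-set size grows: for
#' each size in `train_sizes` and each of `reps` replicates, a fresh
#' training draw of that size and a fresh test draw of `test_size`
#' samples are generated from `data_config`, the three learners are
#' fitted and their test RMSE and MAD recorded in raw dose units.
#'
#' The replicate seed is `master_seed + 100000 * n + r`, so results for
#' a given size are unchanged by adding other sizes to the grid
#' (`reps` must stay below 100000 for the streams not to collide).
#'
#' @param data_config a [synthetic_config()]; default
#'   [gse2409_like_config()].
#' @param train_sizes strictly increasing integer grid, all `>= 5`
#'   (default 15 to 60 by 5, bracketing the real-data sample sizes).
#' @param reps replicates per size (default 500).
#' @param test_size evaluation draw per replicate (default 1000; a
#'   large fixed test set keeps evaluation noise small relative to the
#'   training variability under study).
#' @param rt_control tree configuration shared by the single tree and
#'   the bagging members.
#' @param bags bagging ensemble size (default 50).
#' @param boost_stages,boost_nu,boost_depth boosting settings, fixed
#'   across replicates (default M = 100, nu = 0.1, depth 3).
#' @param master_seed integer master seed.
#' @return A list of class `"sweep_config"`.
#' @export
sweep_config <- function(data_config = gse2409_like_config(),
                         train_sizes = seq(15L, 60L, by = 5L),
                         reps = 500L, test_size = 1000L,
                         rt_control = rtree_control(),
                         bags = 50L, boost_stages = 100L,
                         boost_nu = 0.1, boost_depth = 3L,
                         master_seed = 1L) {
  train_sizes <- as.integer(train_sizes)
  if (is.unsorted(train_sizes, strictly = TRUE))
    stop("train_sizes must be strictly increasing")
  if (any(train_sizes < 5L)) stop("train sizes must be >= 5")
  reps <- as.integer(reps)
  if (reps < 1L || reps >= 100000L) stop("reps must lie in [1, 99999]")
  structure(list(data_config = data_config, train_sizes = train_sizes,
                 reps = reps, test_size = as.integer(test_size),
                 rt_control = rt_control, bags = as.integer(bags),
                 boost_stages = as.integer(boost_stages),
                 boost_nu = boost_nu, boost_depth = as.integer(boost_depth),
                 master_seed = as.integer(master_seed)),
            class = "sweep_config")
}

sweep_rep_seed <- function(master_seed, n, r) {
  as.integer(master_seed + 100000L * as.integer(n) + as.integer(r))
}

#' Run the training-set-size sweep
#'
#' Executes the Monte-Carlo experiment described in [sweep_config()].
#' Each replicate generates standardised dose-gene data, fits the
#' single tree, the bagged ensemble and the boosted ensemble on the
#' training draw, predicts the test draw, back-transforms predictions
#' and observed doses to raw units with the configured scaler, and
#' records RMSE and MAD. A replicate where a fit fails is recorded as
#' missing and the sweep continues; more than 5% failures at any size
#' aborts.
#'
#' @param cfg a [sweep_config()].
#' @param units `"raw"` (default) reports errors in raw dose units;
#'   `"z"` stays on the standardised scale (errors differ exactly by
#'   the factor `sd` of the scaler).
#' @param keep_raw retain the per-replicate records (needed by
#'   [detect_cutoff()]'s bootstrap intervals; default TRUE).
#' @return An object of class `"sweep_result"`: `table` (size x method
#'   mean/sd of RMSE and MAD), `raw` (per-replicate records), `cfg`.
#' @export
run_sweep <- function(cfg, units = c("raw", "z"), keep_raw = TRUE) {
  stopifnot(inherits(cfg, "sweep_config"))
  units <- match.arg(units)
  S <- build_correlation_matrix(cfg$data_config$spec)
  scaler <- cfg$data_config$scaler
  methods <- c("rt", "rt-bagging", "rt-boost")
  raw <- vector("list", length(cfg$train_sizes))
  boost_ctrl <- list(M = cfg$boost_stages, nu = cfg$boost_nu,
                     depth = cfg$boost_depth)
  for (si in seq_along(cfg$train_sizes)) {
    n <- cfg$train_sizes[si]
    rec <- array(NA_real_,
                 dim = c(cfg$reps, length(methods), 2L),
                 dimnames = list(NULL, methods, c("rmse", "mad")))
    for (r in seq_len(cfg$reps)) {
      sd_rep <- sweep_rep_seed(cfg$master_seed, n, r)
      M <- generate_mvn(S, n + cfg$test_size, seed = sd_rep)
      ztr <- M[seq_len(n), 1L]
      xtr <- M[seq_len(n), -1L, drop = FALSE]
      zte <- M[n + seq_len(cfg$test_size), 1L]
      xte <- M[n + seq_len(cfg$test_size), -1L, drop = FALSE]
      yte <- if (units == "raw") to_raw_dose(zte, scaler) else zte
      ok <- tryCatch({
        tr <- rtree(xtr, ztr, control = cfg$rt_control)
        bg <- bagging(xtr, ztr, base = "rtree", B = cfg$bags,
                      seed = sd_rep + 10000000L,
                      control = cfg$rt_control)
        bo <- rt_boost(xtr, ztr, M = boost_ctrl$M, nu = boost_ctrl$nu,
                       max_depth = boost_ctrl$depth,
                       min_node_size = cfg$rt_control$min_node_size)
        preds <- list(predict(tr, xte), predict(bg, xte),
                      predict(bo, xte))
        for (mi in seq_along(preds)) {
          ph <- if (units == "raw") to_raw_dose(preds[[mi]], scaler)
                else preds[[mi]]
          rec[r, mi, "rmse"] <- sqrt(mean((yte - ph)^2))
          rec[r, mi, "mad"] <- mean(abs(yte - ph))
        }
        TRUE
      }, error = function(e) FALSE)
      if (!ok) next
    }
    fail <- mean(is.na(rec[, 1L, "rmse"]))
    if (fail > 0.05)
      stop("more than 5% of replicates failed at size ", n)
    raw[[si]] <- rec
  }
  tab <- do.call(rbind, lapply(seq_along(cfg$train_sizes), function(si) {
    rec <- raw[[si]]
    do.call(rbind, lapply(methods, function(m) data.frame(
      train_size = cfg$train_sizes[si], method = m,
      mean_rmse = mean(rec[, m, "rmse"], na.rm = TRUE),
      sd_rmse = stats::sd(rec[, m, "rmse"], na.rm = TRUE),
      mean_mad = mean(rec[, m, "mad"], na.rm = TRUE),
      sd_mad = stats::sd(rec[, m, "mad"], na.rm = TRUE),
      n_ok = sum(!is.na(rec[, m, "rmse"])),
      stringsAsFactors = FALSE)))
  }))
  rownames(tab) <- NULL
  structure(list(table = tab,
                 raw = if (keep_raw) raw else NULL,
                 train_sizes = cfg$train_sizes,
                 methods = methods, units = units, cfg = cfg),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("Training-size sweep (", x$cfg$reps, " reps/size, ", x$units,
      " units):\n", sep = "")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Learning-curve plot of the sweep
#'
#' Mean RMSE (and optionally MAD) against training size for the single,
#' bagged and boosted trees.
#'
#' @param x a [run_sweep()] result.
#' @param metric `"rmse"` or `"mad"`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.sweep_result <- function(x, metric = c("rmse", "mad"), ...) {
  metric <- match.arg(metric)
  col <- paste0("mean_", metric)
  wide <- sapply(x$methods, function(m)
    x$table[[col]][x$table$method == m])
  graphics::matplot(x$train_sizes, wide, type = "b", pch = 19,
                    lty = 1:3, col = c("blue", "magenta", "brown"),
                    xlab = "training size n",
                    ylab = paste("mean test", toupper(metric)), ...)
  graphics::legend("topright", legend = x$methods, lty = 1:3, pch = 19,
                   col = c("blue", "magenta", "brown"), bty = "n")
  invisible(x)
}

#' Detect the sample size from which an ensemble outperforms a baseline
#'
#' Finds the smallest grid size `n*` such that the mean RMSE of
#' `better` is below the mean RMSE of `baseline` minus `margin` at `n*`
#' and at every larger grid size (the sustained-crossing rule, which
#' stops noise from declaring an early cutoff). Per-size mean
#' differences (baseline - better, positive favouring `better`) are
#' reported with percentile-bootstrap confidence intervals over the
#' paired per-replicate differences when raw records are available.
#'
#' @param res a [run_sweep()] result, or a data frame with columns
#'   `train_size`, `method`, `mean_rmse` (constructed tables; no CIs).
#' @param better,baseline method names (defaults `"rt-bagging"` vs
#'   `"rt"`).
#' @param margin required superiority margin in RMSE units (default 0).
#' @param conf bootstrap confidence level (default 0.95).
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed seed for the bootstrap.
#' @return A list of class `"cutoff_report"`: `cutoff_n` (integer or
#'   `NA` when the crossing never sustains), `margin`, `better`,
#'   `baseline`, and `differences` (per-size mean difference with CI
#'   bounds where available).
#' @export
detect_cutoff <- function(res, better = "rt-bagging", baseline = "rt",
                          margin = 0, conf = 0.95, n_boot = 1000L,
                          seed = 1L) {
  tab <- if (inherits(res, "sweep_result")) res$table else res
  sizes <- sort(unique(tab$train_size))
  get_mean <- function(m, n)
    tab$mean_rmse[tab$method == m & tab$train_size == n]
  if (!all(c(better, baseline) %in% tab$method))
    stop("both methods must be present in the sweep table")
  diffs <- vapply(sizes, function(n)
    get_mean(baseline, n) - get_mean(better, n), numeric(1))
  beats <- diffs > margin
  cutoff_n <- NA_integer_
  for (i in seq_along(sizes)) {
    if (all(beats[i:length(sizes)])) { cutoff_n <- sizes[i]; break }
  }
  lo <- up <- rep(NA_real_, length(sizes))
  if (inherits(res, "sweep_result") && !is.null(res$raw)) {
    alpha <- (1 - conf) / 2
    for (i in seq_along(sizes)) {
      si <- match(sizes[i], res$train_sizes)
      d <- res$raw[[si]][, baseline, "rmse"] - res$raw[[si]][, better, "rmse"]
      d <- d[!is.na(d)]
      bm <- with_seed(seed + i, {
        idx <- matrix(sample.int(length(d), length(d) * n_boot,
                                 replace = TRUE), ncol = n_boot)
        colMeans(matrix(d[idx], ncol = n_boot))
      })
      qs <- stats::quantile(bm, c(alpha, 1 - alpha), names = FALSE)
      lo[i] <- qs[1L]; up[i] <- qs[2L]
    }
  }
  structure(list(cutoff_n = cutoff_n, margin = margin, better = better,
                 baseline = baseline,
                 differences = data.frame(train_size = sizes,
                                          mean_diff = diffs,
                                          ci_lower = lo, ci_upper = up),
                 conf = conf),
            class = "cutoff_report")
}

#' @export
print.cutoff_report <- function(x, ...) {
  if (is.na(x$cutoff_n))
    cat("No sustained cutoff: '", x$better, "' never stays ahead of '",
        x$baseline, "' by more than ", x$margin, "\n", sep = "")
  else
    cat("Cutoff at n = ", x$cutoff_n, ": '", x$better,
        "' outperforms '", x$baseline, "' from this training size on\n",
        sep = "")
  print(x$differences, row.names = FALSE, digits = 4)
  invisible(x)
}
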