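#' Prediction-error metrics for dose regression
#'
#' Root mean squared error, mean absolute deviation and coefficient of
#' determination for a vector of predictions:
#' `RMSE = sqrt(sum((yhat - y)^2) / n)`, `MAD = sum(|yhat - y|) / n`,
#' `R2 = 1 - SSE/SST` with `SST` taken about the mean of the observed
#' evaluation vector. On a test set `R2` can be negative (the model is
#' worse than predicting the test mean); when the observed vector is
#' constant `SST = 0` and `R2` is returned as `NA` while RMSE and MAD
#' remain valid.
#'
#' @param y observed values (length >= 2).
#' @param yhat predicted values, same length.
#' @return A list of class `"dose_metrics"`: `rmse`, `mad`, `r2`, `n`,
#'   and the intermediate sums `sse`, `sst`, `ssr` (`= sst - sse`).
#' @export
compute_metrics <- function(y, yhat) {
  y <- as.numeric(y)
  yhat <- as.numeric(yhat)
  n <- length(y)
  if (n < 2L || length(yhat) != n)
    stop("y and yhat must have equal length >= 2")
  sse <- sum((y - yhat)^2)
  sst <- sum((y - mean(y))^2)
  structure(list(rmse = sqrt(sse / n),
                 mad = sum(abs(yhat - y)) / n,
                 r2 = if (sst > 0) 1 - sse / sst else NA_real_,
                 n = n, sse = sse, sst = sst, ssr = sst - sse),
            class = "dose_metrics")
}

#' @export
print.dose_metrics <- function(x, ...) {
  cat(sprintf("RMSE %.4g  MAD %.4g  R2 %s  (n = %d)\n",
              x$rmse, x$mad,
              if (is.na(x$r2)) "NA" else sprintf("%.4g", x$r2), x$n))
  invisible(x)
}
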