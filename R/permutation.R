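#' Permutation test of predictive signal (extension)
#'
#' An optional extension to the holdout harness, not part of the core
#' benchmarking protocol: tests whether a method's mean test R-squared
#' over repeated 70/30 splits exceeds what the same pipeline attains on
#' dose values randomly shuffled across samples (which destroys any
#' dose-gene association while preserving both marginals). The p-value
#' is the usual permutation estimate `(1 + #{null >= observed}) /
#' (1 + n_perm)`.
#'
#' With tuning enabled and many permutations this is expensive; the
#' defaults keep the null pipeline identical to the observed one.
#'
#' @param ds an [expr_dataset()].
#' @param method one method name accepted by [repeated_holdout()].
#' @param n_splits holdout splits per (observed or permuted) run.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed driving splits and shuffles.
#' @param ... further arguments passed to [repeated_holdout()] (e.g.
#'   `tune`, `bags`, `gbm_stages`).
#' @return A list of class `"r2_permutation_test"`: `observed` mean R2,
#'   `null` vector of permuted mean R2 values, `p_value`.
#' @export
r2_permutation_test <- function(ds, method = "svr-linear",
                                n_splits = 20L, n_perm = 999L,
                                seed = 1L, ...) {
  stopifnot(inherits(ds, "expr_dataset"))
  mean_r2 <- function(d, run_seed) {
    res <- repeated_holdout(d, methods = method, n_splits = n_splits,
                            seed = run_seed, ...)
    res$summary$mean_r2[1L]
  }
  observed <- mean_r2(ds, seed)
  null <- vapply(seq_len(n_perm), function(b) {
    perm <- with_seed(seed + 10000L + b, sample.int(length(ds$y)))
    dsp <- expr_dataset(ds$X, ds$y[perm], sample_ids = ds$sample_ids,
                        gene_ids = ds$gene_ids, meta = ds$meta)
    mean_r2(dsp, seed)
  }, numeric(1))
  structure(list(observed = observed, null = null,
                 p_value = (1 + sum(null >= observed)) / (1 + n_perm),
                 method = method, n_splits = n_splits,
                 n_perm = n_perm),
            class = "r2_permutation_test")
}

#' @export
print.r2_permutation_test <- function(x, ...) {
  cat("Permutation test (", x$method, ", ", x$n_perm,
      " shuffles): observed mean R2 ", format(x$observed, digits = 4),
      ", p = ", format(x$p_value, digits = 4), "\n", sep = "")
  invisible(x)
}
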