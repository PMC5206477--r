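#' Marginal correlation screening
#'
#' Sure-independence screening statistic: the absolute Pearson
#' correlation of each gene with the screening target (the dose, or a
#' residual in later iterations). Returns the `d` top-ranked genes in
#' decreasing order. Zero-variance genes receive statistic 0 and can
#' never outrank a correlated gene. The statistic is invariant to
#' affine rescaling of any gene column.
#'
#' @param X numeric matrix (n x p).
#' @param r screening target of length n; must not be constant.
#' @param d number of genes to keep, `1 <= d <= p`.
#' @return A data frame with columns `index`, `gene`, `stat`, ordered
#'   by decreasing statistic, `d` rows.
#' @export
marginal_screen <- function(X, r, d) {
  X <- as.matrix(X)
  r <- as.numeric(r)
  d <- as.integer(d)
  if (d < 1L || d > ncol(X)) stop("d must lie in [1, ncol(X)]")
  if (stats::var(r) == 0) stop("degenerate screening target: r is constant")
  rc <- r - mean(r)
  Xc <- sweep(X, 2L, colMeans(X))
  num <- abs(as.numeric(crossprod(Xc, rc)))
  den <- sqrt(colSums(Xc^2) * sum(rc^2))
  stat <- ifelse(den > 0, num / den, 0)
  stat <- pmin(stat, 1)
  ord <- order(stat, decreasing = TRUE)[seq_len(d)]
  data.frame(index = ord,
             gene = (colnames(X) %||% paste0("g", seq_len(ncol(X))))[ord],
             stat = stat[ord], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Cross-validated lasso on a screened sub-design
#'
#' Coordinate-descent lasso path (via glmnet) over a decreasing penalty
#' grid, with the penalty chosen by k-fold cross-validated squared
#' error; fold assignment is seeded, so the result is deterministic.
#' Columns are standardised internally to unit variance by default.
#' Returns the genes with a nonzero coefficient at the chosen penalty.
#'
#' @param X_sub numeric matrix of screened columns.
#' @param r target vector.
#' @param lambda optional decreasing positive penalty grid; by default
#'   the solver's own log-spaced path.
#' @param cv_folds number of cross-validation folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @param standardize standardise columns to unit variance (default TRUE).
#' @return A list with `active` (column indices of `X_sub` with nonzero
#'   coefficient), `coefficients` (including intercept), and `lambda`
#'   (the selected penalty).
#' @export
lasso_fit <- function(X_sub, r, lambda = NULL, cv_folds = 10L, seed = 1L,
                      standardize = TRUE) {
  X_sub <- as.matrix(X_sub)
  n <- nrow(X_sub)
  if (n < cv_folds) stop("fewer samples than folds")
  if (!is.null(lambda)) {
    if (any(lambda <= 0) || is.unsorted(rev(lambda)))
      stop("lambda grid must be strictly positive and decreasing")
  }
  if (ncol(X_sub) == 1L) {
    # glmnet needs >= 2 columns; a single screened gene is kept iff its
    # univariate slope survives the soft-threshold at the CV-best lambda
    # of a duplicated-column surrogate
    X_sub <- cbind(X_sub, X_sub)
    fit <- lasso_fit(X_sub, r, lambda = lambda, cv_folds = cv_folds,
                     seed = seed, standardize = standardize)
    act <- if (length(fit$active)) 1L else integer(0)
    co <- fit$coefficients
    co <- c(co[1L], co[2L] + co[3L])
    return(list(active = act, coefficients = co, lambda = fit$lambda))
  }
  foldid <- make_folds(n, cv_folds, seed)
  cv <- glmnet::cv.glmnet(X_sub, r, alpha = 1, lambda = lambda,
                          foldid = foldid, standardize = standardize,
                          thresh = 1e-10)
  co <- as.numeric(stats::coef(cv, s = "lambda.min"))
  active <- which(co[-1L] != 0)
  list(active = active, coefficients = co,
       lambda = cv$lambda.min, cv = cv)
}

#' Iterative sure independence screening
#'
#' Ultrahigh-dimensional gene selection for a continuous dose: iteration
#' 1 screens all genes against the dose by marginal correlation
#' ([marginal_screen()]) and applies a cross-validated lasso
#' ([lasso_fit()]) to the screened set; each later iteration screens the
#' not-yet-selected genes against the residual of an OLS fit on the
#' current selection (catching genes that are marginally weak but
#' jointly relevant), lasso-selects on the union, and updates the
#' selection. Iteration stops when the selected set is unchanged or
#' `max_iter` is reached. The selected set is truncated to at most
#' `n - 2` genes, with a warning recorded in the trace.
#'
#' @param x numeric matrix (n x p) or an [expr_dataset()].
#' @param y dose vector (ignored when `x` is an `expr_dataset`).
#' @param d screening size; default is the classical `floor(n / log(n))`.
#' @param max_iter maximum ISIS iterations (default 5).
#' @param lambda optional lasso penalty grid (decreasing, positive).
#' @param cv_folds folds for the lasso cross-validation (default 10).
#' @param seed integer seed driving all fold randomness.
#' @return An object of class `"isis"` with `selected` (ordered gene
#'   ids), `selected_index`, `trace` (per-iteration screened set, lasso
#'   active set, residual norm, warnings) and `marginal_stats` (per-gene
#'   absolute correlation with the dose).
#' @export
isis <- function(x, y = NULL, d = NULL, max_iter = 5L, lambda = NULL,
                 cv_folds = 10L, seed = 1L) {
  if (inherits(x, "expr_dataset")) {
    y <- x$y
    x <- x$X
  }
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- length(y)
  p <- ncol(x)
  if (n < 10L) stop("need at least 10 samples for ISIS")
  if (is.null(d)) d <- max(1L, floor(n / log(n)))
  d <- as.integer(min(d, p))
  gene_ids <- colnames(x) %||% paste0("g", seq_len(p))

  marg <- marginal_screen(x, y, d = p)
  marginal_stats <- stats::setNames(numeric(p), gene_ids)
  marginal_stats[marg$index] <- marg$stat

  selected <- integer(0)
  trace <- list()
  for (it in seq_len(max_iter)) {
    if (it == 1L) {
      target <- y
      pool <- seq_len(p)
    } else {
      fit <- stats::lm.fit(cbind(1, x[, selected, drop = FALSE]), y)
      target <- fit$residuals
      pool <- setdiff(seq_len(p), selected)
    }
    if (stats::var(target) == 0 || !length(pool)) {
      trace[[it]] <- list(iteration = it, screened = integer(0),
                          active = selected,
                          residual_norm = sqrt(sum(target^2)),
                          note = "residual degenerate; stopped")
      break
    }
    scr <- marginal_screen(x[, pool, drop = FALSE], target,
                           d = min(d, length(pool)))
    screened <- pool[scr$index]
    cand <- union(selected, screened)
    las <- lasso_fit(x[, cand, drop = FALSE], y, lambda = lambda,
                     cv_folds = cv_folds, seed = seed + it)
    new_selected <- sort(cand[las$active])
    note <- NULL
    if (length(new_selected) > n - 2L) {
      keep <- order(marginal_stats[new_selected],
                    decreasing = TRUE)[seq_len(n - 2L)]
      new_selected <- sort(new_selected[keep])
      note <- sprintf("selection truncated to n - 2 = %d genes", n - 2L)
      warning(note)
    }
    trace[[it]] <- list(iteration = it, screened = screened,
                        active = new_selected,
                        residual_norm = sqrt(sum(target^2)),
                        lambda = las$lambda, note = note)
    if (it > 1L && identical(new_selected, selected)) {
      selected <- new_selected
      break
    }
    selected <- new_selected
  }
  structure(list(selected = gene_ids[selected],
                 selected_index = selected,
                 trace = trace,
                 marginal_stats = marginal_stats,
                 d = d, n = n, p = p),
            class = "isis")
}

#' @export
print.isis <- function(x, ...) {
  cat("Iterative SIS selection: ", length(x$selected), " of ", x$p,
      " genes after ", length(x$trace), " iteration(s) (d = ", x$d,
      ")\n", sep = "")
  if (length(x$selected))
    cat("  selected: ", paste(x$selected, collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

# VIF of each column of X: 1 / (1 - R^2_j) of regressing j on the rest
vif_values <- function(X) {
  p <- ncol(X)
  if (p < 2L) return(rep(1, p))
  vapply(seq_len(p), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Multicollinearity and significance post-filter
#'
#' Reduces a selected gene set the way a regression modeller would
#' before interpreting coefficients: first iteratively drop the gene
#' with the largest variance-inflation factor while any VIF exceeds
#' `vif_threshold` (perfectly collinear pairs lose their later-indexed
#' member first), then fit an OLS of the dose on the survivors and drop,
#' in a single pass, every gene whose coefficient p-value is at or above
#' `p_threshold`.
#'
#' @param X_sel numeric matrix of the selected genes (n x q, `q < n - 1`).
#' @param y dose vector.
#' @param vif_threshold VIF above which a gene is considered collinear
#'   (default 10).
#' @param p_threshold coefficient significance cut (default 0.10).
#' @return A list of class `"post_filter"`: `selected` (surviving gene
#'   ids), `selected_index` (columns of `X_sel`), `p_values` (their OLS
#'   p-values from the significance-stage fit), and `dropped_vif` /
#'   `dropped_p` bookkeeping.
#' @export
post_filter <- function(X_sel, y, vif_threshold = 10, p_threshold = 0.10) {
  X_sel <- as.matrix(X_sel)
  y <- as.numeric(y)
  if (vif_threshold <= 1) stop("vif_threshold must exceed 1")
  if (p_threshold <= 0 || p_threshold >= 1)
    stop("p_threshold must lie in (0, 1)")
  if (ncol(X_sel) >= length(y) - 1L)
    stop("need fewer selected genes than n - 1 for the OLS stage")
  gene_ids <- colnames(X_sel) %||% paste0("g", seq_len(ncol(X_sel)))
  keep <- seq_len(ncol(X_sel))
  dropped_vif <- integer(0)
  while (length(keep) > 1L) {
    v <- vif_values(X_sel[, keep, drop = FALSE])
    if (max(v) <= vif_threshold) break
    worst <- which(v == max(v))
    worst <- worst[length(worst)]        # later-indexed gene goes first
    dropped_vif <- c(dropped_vif, keep[worst])
    keep <- keep[-worst]
  }
  fit <- stats::lm(y ~ ., data = as.data.frame(X_sel[, keep, drop = FALSE]))
  pv <- summary(fit)$coefficients[-1L, 4L]
  surv <- keep[pv < p_threshold]
  list_out <- list(selected = gene_ids[surv], selected_index = surv,
                   p_values = stats::setNames(pv[pv < p_threshold],
                                              gene_ids[surv]),
                   all_p_values = stats::setNames(pv, gene_ids[keep]),
                   dropped_vif = gene_ids[dropped_vif],
                   dropped_p = gene_ids[setdiff(keep, surv)],
                   vif_threshold = vif_threshold,
                   p_threshold = p_threshold)
  structure(list_out, class = "post_filter")
}

#' @export
print.post_filter <- function(x, ...) {
  cat("Post-filter: ", length(x$selected), " genes survive (",
      length(x$dropped_vif), " dropped by VIF > ", x$vif_threshold,
      ", ", length(x$dropped_p), " by p >= ", x$p_threshold, ")\n",
      sep = "")
  invisible(x)
}
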