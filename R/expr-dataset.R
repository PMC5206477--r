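#' Expression dataset with a continuous dose response
#'
#' Container for a samples x genes expression matrix together with a
#' continuous per-sample response (a clinical dose or concentration, in
#' dataset-specific units). This is the object every other function in the
#' package consumes: feature selection, the learners, the holdout harness
#' and the synthetic generator all speak `expr_dataset`.
#'
#' @param X numeric matrix, samples in rows, genes in columns. Missing
#'   values are allowed before [preprocess_dataset()] has been run.
#' @param y numeric response vector, one finite value per sample.
#' @param sample_ids,gene_ids character identifiers; default to the
#'   dimnames of `X` or `S1..Sn` / `g1..gp`.
#' @param meta free-form named list of annotations (organism, response
#'   name, provenance).
#'
#' @return An object of class `"expr_dataset"`: a list with elements
#'   `X`, `y`, `sample_ids`, `gene_ids`, `meta`.
#' @seealso [read_series_matrix()], [read_expr_tsv()], [preprocess_dataset()],
#'   [split_train_test()]
#' @export
expr_dataset <- function(X, y, sample_ids = NULL, gene_ids = NULL,
                         meta = list()) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(sample_ids)) sample_ids <- rownames(X)
  if (is.null(gene_ids)) gene_ids <- colnames(X)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(X)))
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(ncol(X)))
  sample_ids <- as.character(sample_ids)
  gene_ids <- as.character(gene_ids)
  y <- as.numeric(y)
  if (nrow(X) != length(y))
    stop("row count of X (", nrow(X), ") must equal length of y (",
         length(y), ")")
  if (nrow(X) != length(sample_ids))
    stop("length of sample_ids must equal the number of rows of X")
  if (ncol(X) != length(gene_ids))
    stop("length of gene_ids must equal the number of columns of X")
  if (anyDuplicated(sample_ids))
    stop("sample_ids must be unique")
  if (!all(is.finite(y)))
    stop("y must be finite (no NA/NaN/Inf dose values)")
  dimnames(X) <- list(sample_ids, gene_ids)
  structure(list(X = X, y = y, sample_ids = sample_ids,
                 gene_ids = gene_ids, meta = meta),
            class = "expr_dataset")
}

#' @export
print.expr_dataset <- function(x, ...) {
  cat("Expression dataset: ", nrow(x$X), " samples x ", ncol(x$X),
      " genes\n", sep = "")
  cat("  response range: [", format(min(x$y)), ", ", format(max(x$y)),
      "]\n", sep = "")
  nmiss <- sum(is.na(x$X))
  if (nmiss > 0) cat("  missing expression values: ", nmiss, "\n", sep = "")
  if (length(x$meta))
    cat("  meta: ", paste(names(x$meta), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.expr_dataset <- function(x) dim(x$X)

#' Subset an expression dataset
#'
#' `ds[i, j]` selects samples `i` and genes `j` (indices, logicals or ids),
#' keeping `X`, `y` and the identifiers in step.
#'
#' @param x an [expr_dataset()].
#' @param i,j sample / gene selectors.
#' @param ... ignored.
#' @return An `expr_dataset`.
#' @export
`[.expr_dataset` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$X))
  if (missing(j)) j <- seq_len(ncol(x$X))
  Xs <- x$X[i, j, drop = FALSE]
  expr_dataset(Xs, x$y[i], sample_ids = rownames(Xs),
               gene_ids = colnames(Xs), meta = x$meta)
}

# round half away from zero; base round() is half-to-even
round_half_up <- function(x) floor(x + 0.5)

#' Split a dataset into training and test parts
#'
#' Uniform random partition without replacement, driven entirely by
#' `seed`: the same seed always yields the same partition. The training
#' size is `round(train_fraction * n)` with half rounded away from zero,
#' matching a 70/30 protocol (e.g. n = 69 gives 48 train / 21 test).
#'
#' @param ds an [expr_dataset()].
#' @param train_fraction fraction of samples assigned to training, in (0,1).
#' @param seed integer seed.
#' @return A list of class `"split_pair"` with elements `train`, `test`
#'   (both `expr_dataset`), `seed` and `train_fraction`.
#' @export
split_train_test <- function(ds, train_fraction = 0.7, seed) {
  stopifnot(inherits(ds, "expr_dataset"))
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie strictly between 0 and 1")
  n <- nrow(ds$X)
  if (n < 4) stop("need at least 4 samples to split")
  n_train <- round_half_up(train_fraction * n)
  if (n_train < 1 || n_train > n - 1)
    stop("split leaves an empty training or test set")
  idx <- with_seed(seed, sample.int(n, n_train))
  structure(list(train = ds[sort(idx), ],
                 test = ds[sort(setdiff(seq_len(n), idx)), ],
                 seed = as.integer(seed),
                 train_fraction = train_fraction),
            class = "split_pair")
}

#' @export
print.split_pair <- function(x, ...) {
  cat("Train/test split (seed ", x$seed, "): ",
      nrow(x$train$X), " train / ", nrow(x$test$X), " test samples\n",
      sep = "")
  invisible(x)
}

#' Preprocess an expression dataset
#'
#' Standard microarray pre-treatment: an optional log2 intensity
#' transform, removal of genes with excessive missingness, and median
#' imputation of the residual missing cells. The transform is
#' `log2(max(v, 0) + 1)` -- the pseudo-count keeps it total on
#' background-corrected intensities that can be zero or slightly
#' negative, and it is monotone in `v`. A gene is dropped when its
#' missing fraction exceeds `max_missing_fraction`; a fully missing gene
#' is always dropped. Surviving missing cells are replaced by that
#' gene's median over observed samples. The result contains no missing
#' values, and the whole operation is idempotent when `already_log2 =
#' TRUE` and no value is missing.
#'
#' @param ds an [expr_dataset()].
#' @param already_log2 logical; if `TRUE` the intensity transform is skipped.
#' @param max_missing_fraction drop genes whose missing fraction exceeds
#'   this value (default 0.2).
#' @return A preprocessed `expr_dataset`.
#' @export
preprocess_dataset <- function(ds, already_log2 = FALSE,
                               max_missing_fraction = 0.2) {
  stopifnot(inherits(ds, "expr_dataset"))
  if (max_missing_fraction < 0 || max_missing_fraction > 1)
    stop("max_missing_fraction must lie in [0, 1]")
  X <- ds$X
  if (!already_log2) X <- log2(pmax(X, 0) + 1)
  frac <- colMeans(is.na(X))
  keep <- frac <= max_missing_fraction & frac < 1
  if (!any(keep)) stop("preprocessing dropped every gene (empty dataset)")
  X <- X[, keep, drop = FALSE]
  miss <- which(colSums(is.na(X)) > 0L)
  for (j in miss) {
    nas <- is.na(X[, j])
    X[nas, j] <- stats::median(X[!nas, j])
  }
  expr_dataset(X, ds$y, sample_ids = ds$sample_ids,
               gene_ids = colnames(X), meta = ds$meta)
}
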