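# Run expr with a private RNG state seeded by `seed`, restoring the
# caller's state afterwards so library code never disturbs user RNG.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# deterministic fold assignment: n items into k folds, sizes differing
# by at most one, order shuffled under `seed`
make_folds <- function(n, k, seed) {
  k <- as.integer(k)
  if (k < 2L) stop("need at least 2 folds")
  if (k > n) stop("fewer samples than folds")
  with_seed(seed, sample(rep_len(seq_len(k), n)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
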