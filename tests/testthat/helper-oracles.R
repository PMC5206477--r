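# Independent oracles and fixture builders shared across test files.
# Oracles are deliberately naive re-derivations (brute force / closed
# form), never calls into the code paths they check.

# exhaustive best-split search: every feature, every midpoint between
# consecutive distinct values, SSE computed from scratch
oracle_best_split <- function(X, y, min_node_size) {
  best <- NULL
  best_sse <- Inf
  for (j in seq_len(ncol(X))) {
    xs <- sort(unique(X[, j]))
    if (length(xs) < 2L) next
    for (s in (xs[-length(xs)] + xs[-1L]) / 2) {
      left <- X[, j] <= s
      if (sum(left) < min_node_size || sum(!left) < min_node_size) next
      sse <- sum((y[left] - mean(y[left]))^2) +
        sum((y[!left] - mean(y[!left]))^2)
      if (sse < best_sse) {
        best_sse <- sse
        best <- list(j = j, s = s, sse = sse)
      }
    }
  }
  best
}

# naive recursive greedy tree, returning only its training SSE
oracle_greedy_sse <- function(X, y, min_node_size, cp_gate, max_depth,
                              depth = 0L) {
  sse_node <- sum((y - mean(y))^2)
  if (depth >= max_depth || length(y) < 2L * min_node_size)
    return(sse_node)
  sp <- oracle_best_split(X, y, min_node_size)
  if (is.null(sp)) return(sse_node)
  improve <- sse_node - sp$sse
  if (!(improve > 0) || improve < cp_gate) return(sse_node)
  left <- X[, sp$j] <= sp$s
  oracle_greedy_sse(X[left, , drop = FALSE], y[left], min_node_size,
                    cp_gate, max_depth, depth + 1L) +
    oracle_greedy_sse(X[!left, , drop = FALSE], y[!left], min_node_size,
                      cp_gate, max_depth, depth + 1L)
}

# one-line arithmetic metric oracle
oracle_metrics <- function(y, yhat) {
  list(rmse = sqrt(sum((yhat - y)^2) / length(y)),
       mad = sum(abs(yhat - y)) / length(y),
       r2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2))
}

# primal epsilon-SVR objective from an arbitrary dual coefficient vector
oracle_svr_primal <- function(beta, K, y, f, epsilon, box) {
  0.5 * sum(beta * (K %*% beta)) +
    box * sum(pmax(abs(y - f) - epsilon, 0))
}

# small series-matrix fixture written to a temp file
write_series_matrix_fixture <- function(cells = NULL, extra_row = NULL) {
  tab <- rbind(
    c("\"P1\"", "1", "2", "3"),
    c("\"P2\"", "4", "5", "6"),
    c("\"P3\"", "7", "8", "9"),
    c("\"P4\"", "10", "11", "12"))
  if (!is.null(cells))
    for (cc in cells) tab[cc$row, cc$col] <- cc$value
  lines <- c(
    "!Series_title\t\"fixture\"",
    "!Sample_characteristics_ch1\t\"dose: 1\"\t\"dose: 2.5\"\t\"dose: 4\"",
    "!series_matrix_table_begin",
    paste(c("\"ID_REF\"", "\"S1\"", "\"S2\"", "\"S3\""), collapse = "\t"),
    apply(tab, 1, paste, collapse = "\t"))
  if (!is.null(extra_row)) lines <- c(lines, extra_row)
  lines <- c(lines, "!series_matrix_table_end")
  path <- tempfile(fileext = ".txt")
  writeLines(lines, path)
  path
}

toy_dataset <- function(n = 20L, p = 4L, seed = 1L, noise_sd = 0.5) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(paste0("S", 1:n), paste0("g", 1:p)))
  y <- X[, 1] - 0.5 * X[, 2] + rnorm(n, sd = noise_sd)
  expr_dataset(X, y)
}
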