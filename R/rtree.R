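#' Best single split of a node by sum of squared errors
#'
#' Exact greedy CART split search: for every feature j and every
#' candidate split point s (midpoints between consecutive distinct
#' sorted values), computes the total within-child sum of squared errors
#' of the partition `{x_j <= s, x_j > s}` and returns the minimiser.
#' Children must each contain at least `min_node_size` observations.
#' Ties are broken toward the smallest feature index, then the smallest
#' split point.
#'
#' @param X numeric matrix (node rows x features).
#' @param y numeric response for the node rows.
#' @param min_node_size minimum observations per child.
#' @return A list `(j, s, sse, sse_left, sse_right)` describing the best
#'   split, or `NULL` when no admissible split exists (the "no-split"
#'   marker: node too small, all features constant, or y constant across
#'   every admissible cut with no SSE reduction possible -- the caller's
#'   complexity gate rejects zero-improvement splits).
#' @export
find_best_split <- function(X, y, min_node_size = 5L) {
  n <- length(y)
  if (n < 2L * min_node_size) return(NULL)
  best <- NULL
  best_sse <- Inf
  for (j in seq_len(ncol(X))) {
    xj <- X[, j]
    o <- order(xj, method = "radix")
    xs <- xj[o]
    ys <- y[o]
    cs <- cumsum(ys)
    cs2 <- cumsum(ys * ys)
    tot <- cs[n]
    tot2 <- cs2[n]
    k <- seq_len(n - 1L)
    ok <- k >= min_node_size & (n - k) >= min_node_size &
      xs[k] < xs[k + 1L]
    if (!any(ok)) next
    k <- k[ok]
    sse_l <- cs2[k] - cs[k]^2 / k
    sse_r <- (tot2 - cs2[k]) - (tot - cs[k])^2 / (n - k)
    sse <- sse_l + sse_r
    m <- which.min(sse)           # first minimum -> smallest s
    if (sse[m] < best_sse) {
      kk <- k[m]
      best_sse <- sse[m]
      best <- list(j = j, s = (xs[kk] + xs[kk + 1L]) / 2,
                   sse = sse[m], sse_left = sse_l[m], sse_right = sse_r[m])
    }
  }
  best
}

#' Control parameters for regression trees
#'
#' @param min_node_size minimum observations in a node (each child of an
#'   accepted split has at least this many rows).
#' @param cp complexity parameter in `[0,1]`: a split is accepted only
#'   if it reduces the tree's training SSE by at least `cp` times the
#'   root's total sum of squares (the CART convention).
#' @param max_depth maximum number of split levels below the root
#'   (interaction depth); 1 gives stumps.
#' @return A list of class `"rtree_control"`.
#' @export
rtree_control <- function(min_node_size = 5L, cp = 0.01, max_depth = 10L) {
  min_node_size <- as.integer(min_node_size)
  max_depth <- as.integer(max_depth)
  if (min_node_size < 2L) stop("min_node_size must be >= 2")
  if (cp < 0 || cp > 1) stop("cp must lie in [0, 1]")
  if (max_depth < 1L) stop("max_depth must be >= 1")
  structure(list(min_node_size = min_node_size, cp = cp,
                 max_depth = max_depth), class = "rtree_control")
}

#' Fit a CART-style regression tree
#'
#' Recursive greedy binary partitioning: each node is split by
#' [find_best_split()] and the split is accepted when both children
#' respect `min_node_size`, the node is above `max_depth`, and the SSE
#' reduction is positive and at least `cp` times the root sum of
#' squares. Leaves predict the mean response of the training rows routed
#' to them; rows with `x_j == s` are routed left.
#'
#' @param x numeric feature matrix (n x p).
#' @param y numeric response of length n.
#' @param control an [rtree_control()].
#' @return An object of class `"rtree"`: a flat node table (`nodes`)
#'   with split feature `j`, split point `s`, child ids, node mean `cm`,
#'   node size `n_node` and within-node SSE `sse_node`, plus the control
#'   used and feature names.
#' @export
rtree <- function(x, y, control = rtree_control()) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- length(y)
  if (n == 0L || nrow(x) != n) stop("x and y sizes disagree or empty")
  sst_root <- sum((y - mean(y))^2)
  gate <- control$cp * sst_root

  # grow with an explicit stack over row-index sets; nodes stored flat
  cap <- 64L
  nd_j <- rep(NA_integer_, cap); nd_s <- rep(NA_real_, cap)
  nd_left <- rep(NA_integer_, cap); nd_right <- rep(NA_integer_, cap)
  nd_cm <- rep(NA_real_, cap); nd_n <- rep(NA_integer_, cap)
  nd_sse <- rep(NA_real_, cap); nd_depth <- rep(NA_integer_, cap)
  nnodes <- 0L
  new_node <- function(rows, depth) {
    nnodes <<- nnodes + 1L
    if (nnodes > length(nd_j)) {
      grow <- function(v) c(v, rep(v[NA_integer_][1L], length(v)))
      nd_j <<- grow(nd_j); nd_s <<- grow(nd_s)
      nd_left <<- grow(nd_left); nd_right <<- grow(nd_right)
      nd_cm <<- grow(nd_cm); nd_n <<- grow(nd_n)
      nd_sse <<- grow(nd_sse); nd_depth <<- grow(nd_depth)
    }
    yy <- y[rows]
    m <- mean(yy)
    nd_cm[nnodes] <<- m
    nd_n[nnodes] <<- length(rows)
    nd_sse[nnodes] <<- sum((yy - m)^2)
    nd_depth[nnodes] <<- depth
    nnodes
  }
  root_rows <- seq_len(n)
  root <- new_node(root_rows, 0L)
  stack <- list(list(id = root, rows = root_rows))
  while (length(stack)) {
    cur <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (nd_depth[cur$id] >= control$max_depth) next
    rows <- cur$rows
    sp <- find_best_split(x[rows, , drop = FALSE], y[rows],
                          control$min_node_size)
    if (is.null(sp)) next
    improve <- nd_sse[cur$id] - sp$sse
    if (!(improve > 0) || improve < gate) next
    go_left <- x[rows, sp$j] <= sp$s
    l <- new_node(rows[go_left], nd_depth[cur$id] + 1L)
    r <- new_node(rows[!go_left], nd_depth[cur$id] + 1L)
    nd_j[cur$id] <- sp$j
    nd_s[cur$id] <- sp$s
    nd_left[cur$id] <- l
    nd_right[cur$id] <- r
    stack[[length(stack) + 1L]] <- list(id = l, rows = rows[go_left])
    stack[[length(stack) + 1L]] <- list(id = r, rows = rows[!go_left])
  }
  idx <- seq_len(nnodes)
  nodes <- data.frame(j = nd_j[idx], s = nd_s[idx], left = nd_left[idx],
                      right = nd_right[idx], cm = nd_cm[idx],
                      n_node = nd_n[idx], sse_node = nd_sse[idx],
                      depth = nd_depth[idx])
  structure(list(nodes = nodes,
                 control = control,
                 feature_names = colnames(x),
                 n = n, sst_root = sst_root),
            class = "rtree")
}

#' Predict from a regression tree
#'
#' Routes each row down the tree (`x_j <= s` goes left) and returns the
#' leaf mean, i.e. the fitted piecewise-constant regression function --
#' the sum over leaves of the region constant times the region
#' indicator.
#'
#' @param object an [rtree()].
#' @param newdata numeric matrix with the training feature count.
#' @param ... ignored.
#' @return Numeric vector of predictions.
#' @export
predict.rtree <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  nd <- object$nodes
  node <- rep(1L, nrow(newdata))
  repeat {
    j <- nd$j[node]
    active <- which(!is.na(j))
    if (!length(active)) break
    a_nodes <- node[active]
    go_left <- newdata[cbind(active, nd$j[a_nodes])] <= nd$s[a_nodes]
    node[active] <- ifelse(go_left, nd$left[a_nodes], nd$right[a_nodes])
  }
  nd$cm[node]
}

#' @export
print.rtree <- function(x, ...) {
  nleaf <- sum(is.na(x$nodes$j))
  cat("Regression tree: ", nrow(x$nodes), " nodes (", nleaf,
      " leaves), depth ", max(x$nodes$depth), "\n", sep = "")
  cat("  n = ", x$n, ", training SSE = ",
      format(sum(x$nodes$sse_node[is.na(x$nodes$j)])), "\n", sep = "")
  invisible(x)
}

#' @export
residuals.rtree <- function(object, x, y, ...) y - predict(object, x)

# training SSE of a fitted tree (sum over leaves)
rtree_training_sse <- function(tree) {
  sum(tree$nodes$sse_node[is.na(tree$nodes$j)])
}
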