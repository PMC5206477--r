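#' Epsilon-insensitive support vector regression
#'
#' Fits the flattest function compatible with an epsilon-tube around the
#' training responses: minimise `||w||^2 / 2 + (C/N) * sum_i
#' L_eps(y_i, f(x_i))`, where `L_eps` is zero for residuals inside the
#' tube of half-width `epsilon` and linear outside. Note the `C/N`
#' scaling of the loss: the per-sample box bound on the dual variables
#' is `C/N`, so `C` values are comparable across training sizes but not
#' directly interchangeable with implementations that use a per-sample
#' bound of `C`.
#'
#' The convex dual (box constraints `0 <= alpha_i, alpha_i* <= C/N`,
#' equality `sum(alpha_i - alpha_i*) = 0`) is solved by sequential
#' minimal optimisation with maximal-violating-pair working-set
#' selection; the bias `b` is the mean Karush-Kuhn-Tucker implied bias
#' over in-tube-boundary (unbounded) support vectors, falling back to
#' the midpoint of the feasible interval when all multipliers are at a
#' bound.
#'
#' @param x numeric feature matrix (n x p).
#' @param y numeric response of length n.
#' @param cost regularisation constant `C > 0` multiplying the averaged loss.
#' @param epsilon half-width of the insensitivity tube, `>= 0`.
#' @param kernel `"linear"` (`<x, x'>`) or `"polynomial"`
#'   (`(gamma <x, x'> + coef0)^degree`).
#' @param degree,gamma,coef0 polynomial-kernel parameters; ignored by
#'   the linear kernel. `gamma` defaults to `1/ncol(x)`.
#' @param tol KKT violation tolerance for the SMO stopping rule.
#' @param max_iter hard cap on SMO pair updates.
#' @return An object of class `"esvr"` with the dual coefficients
#'   `alpha_i - alpha_i*` for all training points (`dual_coefs`), the
#'   retained support rows, the bias `b`, the explicit weight vector `w`
#'   (linear kernel only), the dual and primal objective values and the
#'   configuration.
#' @export
esvr <- function(x, y, cost = 1, epsilon = 0.1,
                 kernel = c("linear", "polynomial"),
                 degree = 2L, gamma = NULL, coef0 = 1,
                 tol = 1e-8, max_iter = 200000L) {
  kernel <- match.arg(kernel)
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- length(y)
  if (n < 2L) stop("need at least 2 training points")
  if (nrow(x) != n) stop("x and y sizes disagree")
  if (epsilon < 0) stop("epsilon must be >= 0")
  if (cost <= 0) stop("cost must be > 0")
  if (is.null(gamma)) gamma <- 1 / ncol(x)
  if (kernel == "polynomial" && (degree < 2L || gamma <= 0))
    stop("polynomial kernel needs degree >= 2 and gamma > 0")

  K <- svr_kernel_matrix(x, x, kernel, degree, gamma, coef0)
  # PSD guard: polynomial/linear Gram matrices are PSD in exact
  # arithmetic; reject anything a small jitter cannot rescue
  ok <- tryCatch({
    chol(K + diag(1e-8 * max(1, mean(diag(K))), n)); TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("kernel matrix is not positive semidefinite")

  Cn <- cost / n
  sol <- smo_solve(K, y, epsilon, Cn, tol, max_iter)
  beta <- sol$beta                       # alpha - alpha*
  f_no_b <- as.numeric(K %*% beta)
  b <- svr_bias(beta, y, f_no_b, epsilon, Cn)

  sv <- which(abs(beta) > 1e-12)
  w <- if (kernel == "linear") as.numeric(crossprod(x, beta)) else NULL
  fitted <- f_no_b + b
  primal <- 0.5 * sum(beta * f_no_b) +
    Cn * sum(pmax(abs(y - fitted) - epsilon, 0))
  dual <- -0.5 * sum(beta * f_no_b) - epsilon * sum(abs(beta)) +
    sum(y * beta)

  structure(list(dual_coefs = beta[sv], support_index = sv,
                 support_X = x[sv, , drop = FALSE],
                 b = b, w = w, N = n,
                 config = list(cost = cost, epsilon = epsilon,
                               kernel = kernel, degree = degree,
                               gamma = gamma, coef0 = coef0),
                 alpha = sol$alpha, alpha_star = sol$alpha_star,
                 box = Cn, iterations = sol$iter,
                 dual_objective = dual, primal_objective = primal,
                 fitted = fitted),
            class = "esvr")
}

svr_kernel_matrix <- function(x1, x2, kernel, degree, gamma, coef0) {
  G <- tcrossprod(x1, x2)
  switch(kernel,
         linear = G,
         polynomial = (gamma * G + coef0)^degree)
}

# SMO on the 2n-variable dual: theta = (alpha, alpha*), z = (+1, -1),
# min 1/2 theta' Q theta + p' theta, z' theta = 0, 0 <= theta <= Cn,
# with Q = [[K,-K],[-K,K]] and p = (eps - y, eps + y).
smo_solve <- function(K, y, epsilon, Cn, tol, max_iter) {
  n <- length(y)
  z <- c(rep(1, n), rep(-1, n))
  p <- c(epsilon - y, epsilon + y)
  theta <- numeric(2L * n)
  g <- p                      # gradient Q theta + p (theta = 0 initially)
  orig <- c(seq_len(n), seq_len(n))
  iter <- 0L
  repeat {
    # maximal violating pair on -z*g
    up <- (z > 0 & theta < Cn - 1e-15) | (z < 0 & theta > 1e-15)
    lo <- (z > 0 & theta > 1e-15) | (z < 0 & theta < Cn - 1e-15)
    f_val <- -z * g
    i <- which(up)[which.max(f_val[up])]
    j <- which(lo)[which.min(f_val[lo])]
    if (!length(i) || !length(j) || f_val[i] - f_val[j] <= tol) break
    iter <- iter + 1L
    if (iter > max_iter) {
      warning("SMO reached max_iter before meeting tolerance")
      break
    }
    Ki <- K[, orig[i]] ; Kj <- K[, orig[j]]
    # curvature along the feasible direction u (u_i = z_i, u_j = -z_j)
    a <- K[orig[i], orig[i]] + K[orig[j], orig[j]] -
      2 * K[orig[i], orig[j]]
    if (a <= 1e-14) a <- 1e-14
    # move theta_i by z_i*d and theta_j by -z_j*d keeps z'theta fixed
    d <- (f_val[i] - f_val[j]) / a
    # box clipping
    d_max_i <- if (z[i] > 0) Cn - theta[i] else theta[i]
    d_max_j <- if (z[j] > 0) theta[j] else Cn - theta[j]
    d <- min(d, d_max_i, d_max_j)
    if (d <= 0) next
    theta[i] <- theta[i] + z[i] * d
    theta[j] <- theta[j] - z[j] * d
    # gradient update: g += Q[,i] z_i d - Q[,j] z_j d = z (Ki - Kj) d
    g <- g + z * (c(Ki, Ki) - c(Kj, Kj)) * d
  }
  alpha <- theta[seq_len(n)]
  alpha_star <- theta[n + seq_len(n)]
  # enforce complementarity alpha_i * alpha_i* = 0 exactly (the pair
  # only drifts together by numerical slack)
  both <- pmin(alpha, alpha_star)
  alpha <- alpha - both
  alpha_star <- alpha_star - both
  list(beta = alpha - alpha_star, alpha = alpha,
       alpha_star = alpha_star, iter = iter)
}

# KKT bias: unbounded alpha  => y - f = eps; unbounded alpha* => y - f = -eps
svr_bias <- function(beta, y, f_no_b, epsilon, Cn) {
  eps_num <- 1e-10 * max(Cn, 1)
  alpha_pos <- beta > eps_num & beta < Cn - eps_num
  star_pos <- beta < -eps_num & beta > -(Cn - eps_num)
  b_vals <- c(y[alpha_pos] - epsilon - f_no_b[alpha_pos],
              y[star_pos] + epsilon - f_no_b[star_pos])
  if (length(b_vals)) return(mean(b_vals))
  # all multipliers at a bound: midpoint of the feasible b-interval
  lower <- suppressWarnings(max(c(
    (y - epsilon - f_no_b)[beta < Cn - eps_num],        # alpha can grow
    (y + epsilon - f_no_b)[beta < -eps_num])))          # alpha* active
  upper <- suppressWarnings(min(c(
    (y + epsilon - f_no_b)[beta > -(Cn - eps_num)],     # alpha* can grow
    (y - epsilon - f_no_b)[beta > eps_num])))           # alpha active
  if (!is.finite(lower) && !is.finite(upper)) return(mean(y - f_no_b))
  if (!is.finite(lower)) return(upper)
  if (!is.finite(upper)) return(lower)
  (lower + upper) / 2
}

#' Predict from a fitted epsilon-SVR model
#'
#' Evaluates `f(x) = sum_i (alpha_i - alpha_i*) K(x_i, x) + b` over the
#' support vectors; for the linear kernel this equals `<w, x> + b`.
#'
#' @param object an [esvr()] fit.
#' @param newdata numeric matrix with the training feature count.
#' @param ... ignored.
#' @return Numeric vector of predictions.
#' @export
predict.esvr <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$support_X) &&
      nrow(object$support_X) > 0L)
    stop("newdata has ", ncol(newdata), " features; model was trained on ",
         ncol(object$support_X))
  if (nrow(object$support_X) == 0L)
    return(rep(object$b, nrow(newdata)))
  cfg <- object$config
  Kx <- svr_kernel_matrix(newdata, object$support_X, cfg$kernel,
                          cfg$degree, cfg$gamma, cfg$coef0)
  as.numeric(Kx %*% object$dual_coefs) + object$b
}

#' @export
print.esvr <- function(x, ...) {
  cat("epsilon-SVR (", x$config$kernel, " kernel): ",
      length(x$dual_coefs), " support vectors of N = ", x$N, "\n",
      sep = "")
  cat("  C = ", x$config$cost, ", epsilon = ", x$config$epsilon,
      ", b = ", format(x$b), "\n", sep = "")
  invisible(x)
}

#' @export
coef.esvr <- function(object, ...) {
  if (is.null(object$w))
    stop("explicit weights exist only for the linear kernel")
  c(b = object$b, stats::setNames(object$w,
    colnames(object$support_X) %||% paste0("x", seq_along(object$w))))
}

# training epsilon-insensitive loss (averaged, without the C factor)
esvr_insensitive_loss <- function(object, x, y) {
  r <- abs(y - predict(object, x))
  mean(pmax(r - object$config$epsilon, 0))
}
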