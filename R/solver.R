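# Classical accelerated extra proximal-gradient optimizer with pluggable
# proximal operators, plus ISTA/FISTA reference solvers used as oracles in
# the test suite.  One iteration interleaves two momentum extrapolations,
# two gradient steps and two proximal steps (a predictor-corrector scheme);
# the unrolled network mirrors this structure exactly with the proximal
# steps replaced by learned residual updates.

#' Componentwise soft shrinkage (soft thresholding)
#'
#' `max(|z| - theta, 0) * sign(z)`, the proximal operator of `theta * |.|_1`;
#' the value at z = 0 is 0.  `theta` may be a scalar or an array conformable
#' with `z`.
#'
#' @param z numeric vector/matrix/array
#' @param theta threshold(s), recycled against `z`
#' @return shrunken array of the same shape as `z`
#' @examples
#' soft_shrink(c(3, -0.5, 0), 1)   # 2, 0, 0
#' @export
soft_shrink <- function(z, theta) {
  pmax(abs(z) - theta, 0) * sign(z)
}

#' Proximal rule for g(x) = lam * ||W x||_1 with orthonormal W
#'
#' For orthonormal `W` (t(W) %*% W = I) the proximal map has the closed form
#' `t(W) %*% soft_shrink(W %*% b, scale * lam)`.  A non-orthonormal `W` is
#' accepted with a warning (the prox is then inexact).
#'
#' @param W square (or tall) matrix with orthonormal columns applied to the
#'   vectorised image; use `diag(n)` for plain l1
#' @param lam nonnegative regularization weight
#' @return a `prox_rule`: list with `g_value(x)` and `prox(b, scale)`
#' @export
l1_transform_prox <- function(W, lam) {
  if (lam < 0) stop("`lam` must be nonnegative")
  if (max(abs(crossprod(W) - diag(ncol(W)))) > 1e-8)
    warning("W is not orthonormal; the proximal map is inexact")
  structure(list(
    g_value = function(x) lam * sum(abs(W %*% x)),
    prox = function(b, scale) {
      if (scale == 0 || lam == 0) return(b)
      drop(crossprod(W, soft_shrink(W %*% b, scale * lam)))
    }
  ), class = "prox_rule")
}

#' The identity proximal rule (g = 0)
#' @return a `prox_rule` whose prox is the identity and whose value is 0
#' @export
identity_prox <- function() {
  structure(list(
    g_value = function(x) 0,
    prox = function(b, scale) b
  ), class = "prox_rule")
}

#' Constant (or per-iteration) step schedule
#'
#' @param alpha,beta positive step sizes for the two gradient steps
#' @param gamma nonnegative momentum coefficient
#' @param K if given, scalars are recycled to length-K vectors
#' @return a `step_schedule` list with vectors `alpha`, `beta`, `gamma`
#' @export
step_schedule <- function(alpha, beta = alpha, gamma = 0, K = NULL) {
  if (any(alpha <= 0) || any(beta <= 0)) stop("step sizes must be positive")
  if (any(gamma < 0)) stop("momentum must be nonnegative")
  if (!is.null(K)) {
    alpha <- rep_len(alpha, K); beta <- rep_len(beta, K); gamma <- rep_len(gamma, K)
  }
  structure(list(alpha = alpha, beta = beta, gamma = gamma),
            class = "step_schedule")
}

.sched_at <- function(sched, k) {
  i <- function(v) v[min(k, length(v))]
  list(alpha = i(sched$alpha), beta = i(sched$beta), gamma = i(sched$gamma))
}

.check_finite <- function(x, where) {
  if (!all(is.finite(x)))
    stop(sprintf("divergence detected (non-finite iterate) in %s", where))
  x
}

#' One accelerated extra proximal-gradient iteration
#'
#' Executes, in order: momentum extrapolation, gradient step of size alpha,
#' prox; second momentum extrapolation, gradient step of size beta, prox.
#' State carries the current iterate and the previous half iterate.
#'
#' @param state list with `x_current`, `x_half_prev`, `k` (iteration index,
#'   1-based); create with `solver_state(x0)`
#' @param op a `sensing_operator`
#' @param y measurements
#' @param sched a `step_schedule`
#' @param prox a `prox_rule`
#' @return updated state with `x_current` = next iterate and `x_half_prev` =
#'   the new half iterate
#' @export
extra_prox_step <- function(state, op, y, sched, prox) {
  s <- .sched_at(sched, state$k)
  xk <- state$x_current; xh <- state$x_half_prev
  xt <- xk + s$gamma * (xk - xh)
  bh <- .check_finite(xt - s$alpha * fidelity_gradient(op, xt, y),
                      "gradient step (alpha)")
  xhalf <- .check_finite(prox$prox(bh, s$alpha), "prox step (alpha)")
  xhat <- xhalf + s$gamma * (xhalf - xk)
  bn <- .check_finite(xhat - s$beta * fidelity_gradient(op, xhat, y),
                      "gradient step (beta)")
  xnext <- .check_finite(prox$prox(bn, s$beta), "prox step (beta)")
  list(x_current = xnext, x_half_prev = xhalf, k = state$k + 1L)
}

#' Initial solver state (x0 = x_{-1/2})
#' @param x0 initial iterate
#' @export
solver_state <- function(x0) {
  list(x_current = x0, x_half_prev = x0, k = 1L)
}

#' Run the accelerated extra proximal-gradient algorithm
#'
#' @param op a `sensing_operator`
#' @param y measurements
#' @param sched a `step_schedule`
#' @param prox a `prox_rule`
#' @param K number of iterations (>= 1)
#' @param x0 initial iterate; default is the adjoint reconstruction
#'   `op_adjoint(op, y)` (zero-filled reconstruction in the MRI case)
#' @return list with `x` (final iterate), `objective` (length-K trace of
#'   f + g evaluated at the full iterates), `K`
#' @export
epg_solve <- function(op, y, sched, prox, K, x0 = NULL) {
  if (K < 1) stop("K must be >= 1")
  if (is.null(x0)) {
    x0 <- op_adjoint(op, y)
    if (is.complex(x0)) x0 <- Re(x0)
  }
  st <- solver_state(x0)
  obj <- numeric(K)
  norm0 <- sqrt(sum(x0^2)) + 1
  for (k in seq_len(K)) {
    st <- extra_prox_step(st, op, y, sched, prox)
    if (sqrt(sum(st$x_current^2)) > 1e6 * norm0)
      stop("divergence detected: iterate norm exceeded 1e6 x initial norm")
    obj[k] <- fidelity_value(op, st$x_current, y) + prox$g_value(st$x_current)
  }
  list(x = st$x_current, objective = obj, K = K)
}

#' FISTA reference solver for g(x) = lam * ||W x||_1
#'
#' Standard accelerated proximal-gradient with the t_k momentum sequence,
#' fixed step `step` (default 1, valid when the rows of A are orthonormal so
#' the Lipschitz constant of grad f is 1).  Intended as a high-accuracy
#' oracle in tests rather than a production solver.
#'
#' @param op a `sensing_operator`
#' @param y measurements
#' @param lam l1 weight
#' @param W orthonormal analysis transform (default identity)
#' @param iters iteration count
#' @param step gradient step size
#' @param x0 initial iterate (default adjoint reconstruction)
#' @return list with `x` and `objective` trace
#' @export
fista_reference <- function(op, y, lam, W = NULL, iters = 1000, step = 1,
                            x0 = NULL) {
  if (is.null(x0)) {
    x0 <- op_adjoint(op, y)
    if (is.complex(x0)) x0 <- Re(x0)
  }
  n <- length(x0)
  if (is.null(W)) W <- diag(n)
  prox <- l1_transform_prox(W, lam)
  x <- x0; z <- x0; t <- 1
  obj <- numeric(iters)
  for (k in seq_len(iters)) {
    xnew <- prox$prox(z - step * fidelity_gradient(op, z, y), step)
    tnew <- (1 + sqrt(1 + 4 * t^2)) / 2
    z <- xnew + ((t - 1) / tnew) * (xnew - x)
    x <- xnew; t <- tnew
    obj[k] <- fidelity_value(op, x, y) + prox$g_value(x)
  }
  list(x = x, objective = obj)
}

#' ISTA reference solver (unaccelerated proximal gradient)
#' @inheritParams fista_reference
#' @export
ista_reference <- function(op, y, lam, W = NULL, iters = 1000, step = 1,
                           x0 = NULL) {
  if (is.null(x0)) {
    x0 <- op_adjoint(op, y)
    if (is.complex(x0)) x0 <- Re(x0)
  }
  n <- length(x0)
  if (is.null(W)) W <- diag(n)
  prox <- l1_transform_prox(W, lam)
  x <- x0
  obj <- numeric(iters)
  for (k in seq_len(iters)) {
    x <- prox$prox(x - step * fidelity_gradient(op, x, y), step)
    obj[k] <- fidelity_value(op, x, y) + prox$g_value(x)
  }
  list(x = x, objective = obj)
}

#' Orthonormal DCT-II matrix
#'
#' Utility transform for handcrafted l1-in-transform regularizers and for
#' tests of the proximal rule on a non-trivial orthonormal basis.
#'
#' @param n size
#' @return n x n orthonormal matrix
#' @export
dct_matrix <- function(n) {
  k <- seq_len(n) - 1
  l <- seq_len(n) - 1
  C <- sqrt(2 / n) * cos(pi * outer(k, 2 * l + 1) / (2 * n))
  C[1, ] <- C[1, ] / sqrt(2)
  C
}
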