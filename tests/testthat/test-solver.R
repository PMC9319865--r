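# Classical accelerated extra proximal-gradient algorithm, its proximal
# rules, and the reference solvers used as oracles.

test_that("soft shrinkage closed form, oddness, and 1-Lipschitz bound", {
  expect_equal(soft_shrink(3.0, 1.0), 2.0)
  expect_equal(soft_shrink(-0.5, 1.0), 0.0)
  expect_equal(soft_shrink(0.0, 2.0), 0.0)
  set.seed(21)
  for (rep in 1:5) {
    z <- rnorm(50); th <- runif(1, 0, 2)
    expect_equal(soft_shrink(-z, th), -soft_shrink(z, th))
    z2 <- rnorm(50)
    expect_lte(max(abs(soft_shrink(z, th) - soft_shrink(z2, th))),
               max(abs(z - z2)) + 1e-12)
  }
})

test_that("l1 transform prox: identity cases and subgradient optimality", {
  n <- 16
  pr <- l1_transform_prox(diag(n), lam = 1)
  b <- c(3, -0.5, rep(0.2, n - 2))
  expect_equal(pr$prox(b, 0), b)                      # prox(b, 0) = b
  expect_equal(pr$prox(b, 1)[1:2], c(2, 0))
  pr0 <- l1_transform_prox(diag(n), lam = 0)
  expect_equal(pr0$prox(b, 0.7), b)
  # DCT transform: check 0 in (x - b) + scale*lam*d||Wx||_1
  W <- dct_matrix(n)
  lam <- 0.3; scale <- 0.8
  prd <- l1_transform_prox(W, lam)
  set.seed(22)
  b <- rnorm(n)
  x <- prd$prox(b, scale)
  wx <- drop(W %*% x)
  resid <- drop(W %*% (x - b))                        # orthonormal W
  for (i in seq_len(n)) {
    if (abs(wx[i]) > 1e-10) {
      expect_equal(resid[i], -scale * lam * sign(wx[i]), tolerance = 1e-8)
    } else {
      expect_lte(abs(resid[i]), scale * lam + 1e-8)
    }
  }
  expect_warning(l1_transform_prox(matrix(c(1, 0, 1, 1), 2), 1), "orthonormal")
})

test_that("one step with gamma=0 and identity prox is the plain extra-gradient update", {
  op <- make_gaussian_operator(16, 0.5, seed = 4)
  set.seed(23)
  x <- rnorm(16); y <- rnorm(op$m)
  a <- 0.7
  st <- extra_prox_step(solver_state(x), op, y, step_schedule(a, a, 0),
                        identity_prox())
  xh <- x - a * fidelity_gradient(op, x, y)
  xn <- xh - a * fidelity_gradient(op, xh, y)
  expect_equal(st$x_half_prev, xh, tolerance = 1e-14)
  expect_equal(st$x_current, xn, tolerance = 1e-14)
  # degenerate zero-step, zero-momentum iteration is a fixed point
  st0 <- extra_prox_step(solver_state(x), op, y,
                         step_schedule(1e-30, 1e-30, 0), identity_prox())
  expect_equal(st0$x_current, x, tolerance = 1e-12)
})

test_that("solver recovers a noiseless full-ratio measurement exactly", {
  op <- make_gaussian_operator(36, 1.0, seed = 5)
  set.seed(24)
  xstar <- runif(36)
  y <- op_forward(op, xstar)
  res <- epg_solve(op, y, step_schedule(1, 1, 0.3), identity_prox(), K = 100)
  expect_lt(max(abs(res$x - xstar)), 1e-6)
  expect_error(epg_solve(op, y, step_schedule(1, 1, 0), identity_prox(), K = 0),
               "K")
})

test_that("on a LASSO toy the solver matches FISTA and coordinate descent", {
  # 8 x 16 compressed sensing toy with l1 regularization
  op <- make_gaussian_operator(16, 0.5, seed = 6)
  set.seed(25)
  xstar <- numeric(16); xstar[c(3, 9, 14)] <- c(1.2, -0.8, 0.5)
  y <- op_forward(op, xstar) + 0.01 * rnorm(op$m)
  lam <- 0.05
  pr <- l1_transform_prox(diag(16), lam)
  obj <- function(x) fidelity_value(op, x, y) + lam * sum(abs(x))

  fis <- fista_reference(op, y, lam, iters = 20000)
  # independent oracle: cyclic coordinate descent on the LASSO objective
  A <- op$A
  xcd <- numeric(16)
  for (sweep in 1:2000) {
    for (j in 1:16) {
      r <- y - A %*% xcd + A[, j] * xcd[j]
      rho <- sum(A[, j] * r)
      xcd[j] <- soft_shrink(rho, lam) / sum(A[, j]^2)
    }
  }
  expect_equal(obj(fis$x), obj(xcd), tolerance = 1e-6)

  res <- epg_solve(op, y, step_schedule(1, 1, 0.3), pr, K = 500)
  expect_lt(abs(res$objective[500] - obj(fis$x)), 1e-6)
  # trace is nonincreasing after burn-in for this tuned schedule
  tr <- res$objective[10:500]
  expect_true(all(diff(tr) <= 1e-12))
  # acceleration guard: not worse than ISTA at equal iteration count
  ist <- ista_reference(op, y, lam, iters = 500)
  expect_lte(res$objective[500], ist$objective[500] + 1e-10)
})

test_that("FISTA reference solves the smooth full-rank case to high accuracy", {
  op <- make_gaussian_operator(12, 1.0, seed = 7)
  set.seed(26)
  xstar <- rnorm(12)
  y <- op_forward(op, xstar)
  fis <- fista_reference(op, y, lam = 0, iters = 300)
  expect_lt(max(abs(fis$x - xstar)), 1e-8)
})

test_that("divergent step sizes raise a divergence error", {
  op <- make_gaussian_operator(16, 0.5, seed = 8)
  set.seed(27)
  y <- rnorm(op$m)
  expect_error(
    epg_solve(op, y, step_schedule(500, 500, 0.9), identity_prox(), K = 200),
    "divergence")
})
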