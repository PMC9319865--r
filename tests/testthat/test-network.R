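# The unrolled network: parameter accounting, encoder/decoder structure,
# residual updates, phase semantics, and agreement with the classical solver.

test_that("analytic parameter count matches brute-force tensor enumeration", {
  for (case in list(list(K = 1, Nf = 32, nl = FALSE, per = 37475),
                    list(K = 9, Nf = 32, nl = FALSE, per = 37475),
                    list(K = 1, Nf = 32, nl = TRUE, per = 41571),
                    list(K = 7, Nf = 32, nl = TRUE, per = 41571),
                    list(K = 3, Nf = 8, nl = FALSE, per = NA),
                    list(K = 2, Nf = 4, nl = TRUE, per = NA))) {
    cfg <- epgn_config(case$K, case$Nf, case$nl)
    cnt <- count_parameters(cfg)
    enum <- enumerate_parameters(epgn_network(cfg, seed = 1))
    expect_equal(enum$per_phase, rep(cnt$per_phase, case$K))
    expect_equal(enum$total, cnt$total)
    if (!is.na(case$per)) expect_equal(cnt$per_phase, case$per)
  }
  expect_equal(count_parameters(epgn_config(9, 32))$total, 337275)
  expect_equal(count_parameters(epgn_config(7, 32, TRUE))$total, 290997)
})

test_that("encoder receptive field is exactly 7x7; encoder+decoder at most 13x13", {
  net <- epgn_network(epgn_config(1, 8), seed = 31)
  pp <- net$phases[[1]]
  impulse <- matrix(0, 15, 15); impulse[8, 8] <- 1
  z <- encode_features(pp, impulse)
  ext <- apply(z, 3, function(ch) support_extent(ch))
  expect_true(all(ext <= 7))
  expect_true(any(apply(ext, 2, function(e) all(e == 7))))
  r <- decode_features(pp, channel_shrink(z, rep(0, 8)))
  expect_true(all(support_extent(r) <= 13))
})

test_that("channelwise shrinkage: identity at zero, scalar case, monotone sparsity", {
  z <- random_feature_map(6, 6, 4, seed = 32)
  expect_equal(channel_shrink(z, rep(0, 4)), z)
  z1 <- array(3, c(1, 1, 1))
  expect_equal(as.numeric(channel_shrink(z1, 1)), 2)
  zeros <- vapply(seq(0, 2, by = 0.25), function(th)
    sum(channel_shrink(z, rep(th, 4)) == 0), numeric(1))
  expect_true(all(diff(zeros) >= 0))
})

test_that("residual update composes encode, shrink, decode around a skip connection", {
  net <- epgn_network(epgn_config(1, 8), seed = 33)
  pp <- net$phases[[1]]
  set.seed(33)
  b <- matrix(rnorm(81), 9, 9)
  manual <- b + decode_features(pp, channel_shrink(encode_features(pp, b),
                                                  pp$theta))
  expect_equal(residual_update(pp, b), manual, tolerance = 1e-12)
  # zero kernels: identity
  z0 <- zero_network(1, 8)$phases[[1]]
  expect_equal(residual_update(z0, b), b)
  # huge thresholds kill every feature
  pp2 <- pp; pp2$theta <- rep(1e6, 8)
  expect_equal(residual_update(pp2, b), b)
})

test_that("nonlocal variant inserts the fusion operator between shrink and decode", {
  net <- epgn_network(epgn_config(1, 4, nonlocal = TRUE), seed = 34)
  pp <- net$phases[[1]]
  set.seed(34)
  b <- matrix(rnorm(49), 7, 7)
  manual <- b + decode_features(pp,
    fuse_local_nonlocal(pp$nl, channel_shrink(encode_features(pp, b), pp$theta)))
  expect_equal(residual_update(pp, b), manual, tolerance = 1e-12)
})

test_that("a phase with zero kernels reproduces the classical step exactly", {
  op <- make_gaussian_operator(64, 0.5, seed = 35)
  set.seed(35)
  xk <- matrix(runif(64), 8, 8); xh <- matrix(runif(64), 8, 8)
  y <- op_forward(op, as.vector(xk))
  net <- zero_network(1, 8, alpha = 0.7, beta = 0.9, gamma = 0.3)
  pf <- phase_forward(net$phases[[1]], xk, xh, op, y)
  st <- extra_prox_step(list(x_current = as.vector(xk),
                             x_half_prev = as.vector(xh), k = 1L),
                        op, y, step_schedule(0.7, 0.9, 0.3), identity_prox())
  expect_equal(as.vector(pf$x_next), st$x_current, tolerance = 1e-12)
  expect_equal(as.vector(pf$x_half), st$x_half_prev, tolerance = 1e-12)
})

test_that("zero-parameter network of any depth is the identity on x0", {
  op <- make_gaussian_operator(64, 0.5, seed = 36)
  set.seed(36)
  y <- op_forward(op, runif(64))
  for (K in c(1, 4)) {
    net <- zero_network(K, 8)
    out <- network_forward(net, op, y)
    expect_equal(as.vector(out), op_adjoint(op, y), tolerance = 1e-14)
  }
})

test_that("network preserves the image shape for patches and full frames", {
  net <- epgn_network(epgn_config(2, 4), seed = 37)
  op33 <- make_gaussian_operator(33^2, 0.25, seed = 37)
  set.seed(37)
  y <- op_forward(op33, runif(33^2))
  expect_equal(dim(network_forward(net, op33, y)), c(33L, 33L))
  # non-square frame through the Fourier operator
  opf <- make_fourier_operator(make_radial_mask(12, 16, 0.4, tol = 0.1))
  yf <- op_forward(opf, runif(12 * 16))
  expect_equal(dim(network_forward(net, opf, yf)), c(12L, 16L))
  # batch input returns stacked columns
  Y <- op_forward(op33, matrix(runif(33^2 * 3), ncol = 3))
  expect_equal(dim(network_forward(net, op33, Y)), c(1089L, 3L))
})

test_that("checkpoints round-trip bit-exactly", {
  net <- epgn_network(epgn_config(2, 4, nonlocal = TRUE), seed = 38)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(net, path, extra = list(note = "x"))
  back <- load_checkpoint(path)
  expect_identical(back$net$phases, net$phases)
  expect_identical(unclass(back$net$config), unclass(net$config))
  expect_equal(back$extra$note, "x")
})

test_that("analytic loss gradients match central finite differences", {
  cfg <- epgn_config(2, 4, nonlocal = TRUE)
  net <- epgn_network(cfg, seed = 39)
  op <- make_gaussian_operator(49, 0.5, seed = 39)
  set.seed(39)
  X <- matrix(runif(49 * 2), 49, 2)
  Y <- op_forward(op, X)
  lg <- epgn_loss_gradient(net, op, Y, X, shape = c(7, 7))
  eps <- 1e-6
  poke <- function(setter) {
    (epgn_loss(setter(net, eps), op, Y, X, shape = c(7, 7)) -
     epgn_loss(setter(net, -eps), op, Y, X, shape = c(7, 7))) / (2 * eps)
  }
  cases <- list(
    list(g = lg$grads[[1]]$D[2, 2, 1, 3],
         s = function(n, d) { n$phases[[1]]$D[2, 2, 1, 3] <- n$phases[[1]]$D[2, 2, 1, 3] + d; n }),
    list(g = lg$grads[[2]]$A[1, 3, 2, 4],
         s = function(n, d) { n$phases[[2]]$A[1, 3, 2, 4] <- n$phases[[2]]$A[1, 3, 2, 4] + d; n }),
    list(g = lg$grads[[1]]$theta[2],
         s = function(n, d) { n$phases[[1]]$theta[2] <- n$phases[[1]]$theta[2] + d; n }),
    list(g = lg$grads[[1]]$gamma,
         s = function(n, d) { n$phases[[1]]$gamma <- n$phases[[1]]$gamma + d; n }),
    list(g = lg$grads[[2]]$alpha,
         s = function(n, d) { n$phases[[2]]$alpha <- n$phases[[2]]$alpha + d; n }),
    list(g = lg$grads[[1]]$beta,
         s = function(n, d) { n$phases[[1]]$beta <- n$phases[[1]]$beta + d; n }),
    list(g = lg$grads[[1]]$nl$Walpha[2, 1],
         s = function(n, d) { n$phases[[1]]$nl$Walpha[2, 1] <- n$phases[[1]]$nl$Walpha[2, 1] + d; n }),
    list(g = lg$grads[[2]]$nl$Ck[5, 2],
         s = function(n, d) { n$phases[[2]]$nl$Ck[5, 2] <- n$phases[[2]]$nl$Ck[5, 2] + d; n })
  )
  for (cs in cases) {
    num <- poke(cs$s)
    expect_equal(cs$g, num, tolerance = 1e-4)
  }
})
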