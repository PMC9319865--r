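# Training loop: the loss definition, Xavier initialization, determinism,
# degenerate runs, resume semantics, and a miniature learning check.
# (The full learning-sanity experiment lives in the acceptance suite.)

test_that("training loss is the batch mean of squared distances", {
  net <- zero_network(1, 4)                 # network output equals A^H y
  op <- make_gaussian_operator(25, 1.0, seed = 51)  # full ratio: A^H y = x
  set.seed(51)
  X <- matrix(runif(50), 25, 2)
  Y <- op_forward(op, X)
  expect_equal(epgn_loss(net, op, Y, X, shape = c(5, 5)), 0, tolerance = 1e-20)
  # constant offset on a 33x33 patch: ||0.1||^2 * 1089 = 10.89
  op33 <- make_gaussian_operator(1089, 1.0, seed = 51)
  x <- matrix(runif(1089), ncol = 1)
  out <- network_forward(net, op33, drop(op_forward(op33, x)))
  expect_equal(mean(colSums((as.vector(out) + 0.1 - x)^2)), 10.89,
               tolerance = 1e-8)
  # hand-written two-pair sum and order invariance
  net2 <- epgn_network(epgn_config(1, 4), seed = 52)
  op2 <- make_gaussian_operator(36, 0.5, seed = 52)
  X2 <- matrix(runif(72), 36, 2)
  Y2 <- op_forward(op2, X2)
  o1 <- network_forward(net2, op2, Y2[, 1])
  o2 <- network_forward(net2, op2, Y2[, 2])
  byhand <- (sum((as.vector(o1) - X2[, 1])^2) +
             sum((as.vector(o2) - X2[, 2])^2)) / 2
  expect_equal(epgn_loss(net2, op2, Y2, X2), byhand, tolerance = 1e-10)
  expect_equal(epgn_loss(net2, op2, Y2[, 2:1], X2[, 2:1]), byhand,
               tolerance = 1e-10)
})

test_that("initialization is Xavier-scaled and reproducible", {
  n1 <- epgn_network(epgn_config(2, 32), seed = 5)
  n2 <- epgn_network(epgn_config(2, 32), seed = 5)
  expect_identical(n1$phases, n2$phases)
  expect_false(identical(n1$phases,
                         epgn_network(epgn_config(2, 32), seed = 6)$phases))
  # uniform(-a, a) with a^2 = 6/(fan_in+fan_out) has variance 2/(fan_in+fan_out)
  A <- n1$phases[[1]]$A                     # fan_in = fan_out = 9 * 32
  expect_lt(abs(stats::var(as.vector(A)) / (2 / (288 + 288)) - 1), 0.2)
  expect_equal(n1$phases[[1]]$theta, rep(0.01, 32))
  expect_equal(n1$phases[[1]]$gamma, 0)
  expect_equal(n1$phases[[1]]$alpha, 1)
  expect_equal(n1$phases[[1]]$beta, 1)
})

test_that("zero learning rate leaves parameters untouched with a flat history", {
  set.seed(53)
  X <- matrix(runif(16 * 10), 16, 10)
  op <- make_gaussian_operator(16, 0.5, seed = 53)
  net <- epgn_network(epgn_config(1, 4), seed = 53)
  fit <- epgn_train(net, X, op, train_config(learning_rate = 0, epochs = 3,
                                             batch_size = 5, seed = 1))
  expect_identical(fit$net$phases, net$phases)
  expect_equal(length(unique(round(fit$history$loss, 12))), 1L)
})

test_that("resuming from a checkpoint replays the uninterrupted trajectory", {
  set.seed(54)
  X <- matrix(runif(16 * 12), 16, 12)
  op <- make_gaussian_operator(16, 0.5, seed = 54)
  net <- epgn_network(epgn_config(1, 4), seed = 54)
  ckdir <- tempfile("ck")
  cfg4 <- train_config(learning_rate = 1e-3, epochs = 4, batch_size = 4,
                       seed = 9, checkpoint_dir = ckdir)
  full <- epgn_train(net, X, op, cfg4)
  cfg2 <- cfg4; cfg2$epochs <- 2L; cfg2$checkpoint_dir <- NULL
  half <- epgn_train(net, X, op, cfg2)
  resumed <- epgn_train(net, X, op, cfg4,
                        resume_from = file.path(ckdir, "epoch_0002.rds"))
  expect_identical(resumed$net$phases, full$net$phases)
  expect_equal(resumed$history$loss, full$history$loss, tolerance = 1e-12)
  # the first two epochs of the full run match the short run
  expect_equal(half$history$loss, full$history$loss[1:2], tolerance = 1e-12)
})

test_that("YAML training configs mirror the constructor arguments", {
  skip_if_not_installed("yaml")
  path <- tempfile(fileext = ".yaml")
  writeLines(c("learning_rate: 0.001", "epochs: 12", "batch_size: 8",
               "seed: 3"), path)
  cfg <- read_train_config(path)
  expect_equal(cfg$learning_rate, 1e-3)
  expect_equal(cfg$epochs, 12L)
  expect_equal(cfg$batch_size, 8L)
  expect_equal(cfg$seed, 3L)
  writeLines("not_a_key: 1", path)
  expect_error(read_train_config(path), "unknown")
})

test_that("a miniature run reduces the loss and records validation PSNR", {
  phant <- make_phantoms(4, phantom_spec(size = c(16L, 16L), n_shapes = 3),
                         seed = 55)
  X <- patches_to_matrix(extract_patches(phant, patch = 12, count = 40,
                                         seed = 55))
  op <- make_gaussian_operator(144, 0.25, seed = 55)
  net <- epgn_network(epgn_config(2, 4), seed = 55)
  fit <- epgn_train(net, X, op,
                    train_config(learning_rate = 1e-3, epochs = 5,
                                 batch_size = 10, seed = 2),
                    val_patches = X[, 1:5])
  expect_lt(fit$history$loss[5], fit$history$loss[1])
  expect_true(all(is.finite(fit$history$val_psnr)))
})
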