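# Shared fixtures for the test suite.  Everything is generated in code under
# fixed seeds; no data files are read.

# network whose residual updates are exact identities (all kernels zero) and
# whose steps/momentum are set explicitly
zero_network <- function(K, Nf, alpha = 0, beta = 0, gamma = 0,
                         nonlocal = FALSE, seed = 1L) {
  net <- epgn_network(epgn_config(K, Nf, nonlocal), seed = seed)
  for (k in seq_len(K)) {
    for (nm in c("D", "A", "B", "Btil", "Atil", "Dtil"))
      net$phases[[k]][[nm]][] <- 0
    net$phases[[k]]$alpha <- alpha
    net$phases[[k]]$beta <- beta
    net$phases[[k]]$gamma <- gamma
  }
  net
}

# naive direct-summation 3x3 convolution oracle (zero padding, bias-free,
# cross-correlation orientation) on an (H, W, Cin) array
naive_conv3 <- function(x, w) {
  H <- dim(x)[1]; W <- dim(x)[2]; Cin <- dim(x)[3]; Cout <- dim(w)[4]
  out <- array(0, c(H, W, Cout))
  for (co in seq_len(Cout)) for (r in seq_len(H)) for (cc in seq_len(W)) {
    acc <- 0
    for (i in 1:3) for (j in 1:3) for (ci in seq_len(Cin)) {
      r2 <- r + i - 2; c2 <- cc + j - 2
      if (r2 >= 1 && r2 <= H && c2 >= 1 && c2 <= W)
        acc <- acc + x[r2, c2, ci] * w[i, j, ci, co]
    }
    out[r, cc, co] <- acc
  }
  out
}

# spatial support (bounding box side lengths) of the nonzero part of a map
support_extent <- function(m, tol = 1e-12) {
  nz <- which(abs(m) > tol, arr.ind = TRUE)
  if (nrow(nz) == 0) return(c(0L, 0L))
  c(diff(range(nz[, 1])) + 1L, diff(range(nz[, 2])) + 1L)
}

random_feature_map <- function(H, W, C, seed = 1L) {
  set.seed(seed)
  array(rnorm(H * W * C), c(H, W, C))
}
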