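# Hand-derived reverse-mode gradients for the unrolled network.
#
# Every building block of the forward pass (3x3 convolution, ReLU,
# channelwise shrinkage, attention, momentum extrapolation, fidelity
# gradient step) is linear or piecewise smooth, so the chain rule is applied
# explicitly layer by layer.  The Jacobian of the gradient step
# b = x - s * A^H(A x - y) with respect to x is I - s * A^H A, which is
# symmetric as a real operator for both sensing kinds, so its transpose
# action reuses op_normal().

.zero_phase_grads <- function(pp) {
  g <- list(
    D = array(0, dim(pp$D)), A = array(0, dim(pp$A)), B = array(0, dim(pp$B)),
    Btil = array(0, dim(pp$Btil)), Atil = array(0, dim(pp$Atil)),
    Dtil = array(0, dim(pp$Dtil)),
    theta = numeric(length(pp$theta)), gamma = 0, alpha = 0, beta = 0
  )
  if (!is.null(pp$nl)) g$nl <- .nl_zero_grads(pp$nl)
  g
}

.add_grads <- function(a, b) {
  for (nm in names(b)) {
    if (is.list(b[[nm]])) a[[nm]] <- .add_grads(a[[nm]], b[[nm]])
    else a[[nm]] <- a[[nm]] + b[[nm]]
  }
  a
}

# Backward through one residual update.  gout: (R, 1) upstream gradient on
# the output; cache from .residual_fw.  Returns gradient on b and parameter
# gradients (conv kernels, theta, nonlocal projections).
.residual_bw <- function(pp, cache, gout, plan) {
  g <- .zero_phase_grads(pp)
  dec <- cache$dec
  bw <- conv3_backward(dec$q3, gout, pp$Dtil, plan)
  gq3 <- bw$gX; g$Dtil <- bw$gW
  bw <- conv3_backward(dec$q2, gq3, pp$Atil, plan)
  gq2 <- bw$gX; g$Atil <- bw$gW
  gq1 <- relu_backward(gq2, dec$q1)
  bw <- conv3_backward(dec$u, gq1, pp$Btil, plan)
  gu <- bw$gX; g$Btil <- bw$gW
  if (!is.null(pp$nl)) {
    nb <- .nl_bw(pp$nl, cache$nl, gu)
    g$nl <- nb$grads
    gs <- nb$gS
  } else {
    gs <- gu
  }
  shr <- cache$shr
  gz <- gs * shr$mask
  g$theta <- -colSums(sign(shr$z) * gz)
  enc <- cache$enc
  bw <- conv3_backward(enc$m3, gz, pp$B, plan)
  gm3 <- bw$gX; g$B <- bw$gW
  gh2 <- relu_backward(gm3, enc$h2)
  bw <- conv3_backward(enc$h1, gh2, pp$A, plan)
  gh1 <- bw$gX; g$A <- bw$gW
  bw <- conv3_backward(enc$b, gh1, pp$D, plan)
  gb_chain <- bw$gX; g$D <- bw$gW
  list(g_b = gout + gb_chain, grads = g)
}

# Backward through one phase.  g_next, g_half: (n, B) upstream gradients on
# the phase outputs x_next and x_half.  Returns gradients on the phase inputs
# (x_k, x_half_prev) plus accumulated parameter gradients.
.phase_bw <- function(pp, cache, g_next, g_half, op, plan) {
  n <- nrow(g_next); B <- ncol(g_next)
  tocol <- function(M) matrix(as.vector(M), ncol = 1L)
  tomat <- function(cl) matrix(cl, n, B)
  gam <- pp$gamma

  rb2 <- .residual_bw(pp, cache$ru2, tocol(g_next), plan)
  gBn <- tomat(rb2$g_b)
  gXhat <- gBn - pp$beta * op_normal(op, gBn)
  g_beta <- -sum(gBn * cache$Gf2)

  gXhalf <- (1 + gam) * gXhat + g_half
  gXk <- -gam * gXhat
  g_gamma <- sum(gXhat * (cache$x_half - cache$Xk))

  rb1 <- .residual_bw(pp, cache$ru1, tocol(gXhalf), plan)
  gBh <- tomat(rb1$g_b)
  gXt <- gBh - pp$alpha * op_normal(op, gBh)
  g_alpha <- -sum(gBh * cache$Gf1)

  gXk <- gXk + (1 + gam) * gXt
  gXh <- -gam * gXt
  g_gamma <- g_gamma + sum(gXt * (cache$Xk - cache$Xh))

  grads <- .add_grads(rb1$grads, rb2$grads)
  grads$alpha <- g_alpha
  grads$beta <- g_beta
  grads$gamma <- g_gamma
  list(g_xk = gXk, g_xh = gXh, grads = grads)
}

#' Mean-squared training loss
#'
#' Mean over the batch of the squared Euclidean distance between the network
#' output and the ground truth: `mean_i ||xK(y_i) - x_i||^2` (summed over
#' pixels within each image, averaged over images).
#'
#' @param net an `epgn_network`
#' @param op a `sensing_operator`
#' @param Y (m, B) measurement matrix
#' @param X (n, B) matrix of vectorised ground-truth images
#' @param shape image shape `c(H, W)` when not inferable from the operator
#' @return numeric scalar
#' @export
epgn_loss <- function(net, op, Y, X, shape = NULL) {
  out <- .network_fw(net, op, Y, shape = shape)$x
  mean(colSums((out - X)^2))
}

# Forward + backward on a batch; returns loss, output and per-phase gradient
# lists structured like net$phases.
.loss_and_grads <- function(net, op, Y, X, shape = NULL) {
  fw <- .network_fw(net, op, Y, shape = shape, keep_cache = TRUE)
  B <- ncol(Y)
  diff <- fw$x - X
  loss <- mean(colSums(diff^2))
  gXk <- (2 / B) * diff
  gXh <- matrix(0, nrow(gXk), ncol(gXk))
  K <- net$config$K
  grads <- vector("list", K)
  for (k in rev(seq_len(K))) {
    pb <- .phase_bw(net$phases[[k]], fw$caches[[k]], gXk, gXh, op, fw$plan)
    grads[[k]] <- pb$grads
    gXk <- pb$g_xk
    gXh <- pb$g_xh
  }
  list(loss = loss, grads = grads, output = fw$x)
}

#' Loss and analytic parameter gradients for one batch
#'
#' Exposed mainly for gradient verification and custom training loops; the
#' gradient lists mirror the structure of `net$phases`.
#'
#' @inheritParams epgn_loss
#' @return list with `loss` (scalar), `grads` (length-K list of per-phase
#'   gradient lists) and `output` ((n, B) reconstruction matrix)
#' @export
epgn_loss_gradient <- function(net, op, Y, X, shape = NULL) {
  .loss_and_grads(net, op, Y, X, shape = shape)
}
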