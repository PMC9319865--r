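# The unrolled extra proximal-gradient network (EPGN / NL-EPGN).
#
# A network of K phases mirrors K iterations of the classical accelerated
# extra proximal-gradient algorithm: the two momentum extrapolations and two
# gradient steps of each iteration are kept as exact linear layers (with
# learned momentum gamma_k and step sizes alpha_k, beta_k), while each of the
# two proximal steps is replaced by a learned residual update
#   x = b + decode(shrink(encode(b)))          (EPGN)
#   x = b + decode(Nk(shrink(encode(b))))      (NL-EPGN)
# where encode = B . ReLU . A . D (three bias-free 3x3 convolutions),
# shrink is channelwise soft thresholding with learned per-channel
# thresholds, decode = Dtil . Atil . ReLU . Btil mirrors the encoder back to
# one channel, and Nk is the embedded-Gaussian nonlocal operator (nonlocal.R).
# The two stages inside a phase share one parameter set; phases do not share
# parameters with each other.

#' Network configuration
#'
#' @param K number of phases (the full-scale defaults are 9 for the plain
#'   network and 7 for the nonlocal variant)
#' @param Nf feature channels per pixel (default 32; must be even when
#'   `nonlocal = TRUE` since the attention bottleneck uses Nf/2)
#' @param nonlocal include the embedded-Gaussian nonlocal operator
#' @return an `epgn_config` list
#' @export
epgn_config <- function(K, Nf = 32L, nonlocal = FALSE) {
  K <- as.integer(K); Nf <- as.integer(Nf)
  if (K < 1) stop("K must be >= 1")
  if (nonlocal && Nf %% 2L != 0L) stop("Nf must be even for the nonlocal block")
  structure(list(K = K, Nf = Nf, nonlocal = isTRUE(nonlocal)),
            class = "epgn_config")
}

.xavier <- function(shape, fan_in, fan_out) {
  a <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(shape), -a, a), shape)
}

.init_phase <- function(Nf, nonlocal) {
  pp <- list(
    D    = .xavier(c(3, 3, 1, Nf), 9 * 1,  9 * Nf),
    A    = .xavier(c(3, 3, Nf, Nf), 9 * Nf, 9 * Nf),
    B    = .xavier(c(3, 3, Nf, Nf), 9 * Nf, 9 * Nf),
    Btil = .xavier(c(3, 3, Nf, Nf), 9 * Nf, 9 * Nf),
    Atil = .xavier(c(3, 3, Nf, Nf), 9 * Nf, 9 * Nf),
    Dtil = .xavier(c(3, 3, Nf, 1), 9 * Nf, 9 * 1),
    theta = rep(0.01, Nf),
    gamma = 0,
    alpha = 1,
    beta  = 1
  )
  if (nonlocal) {
    h <- Nf %/% 2L
    pp$nl <- list(
      Walpha = .xavier(c(Nf, h), Nf, h),
      Wbeta  = .xavier(c(Nf, h), Nf, h),
      Wphi   = .xavier(c(Nf, h), Nf, h),
      Wexp   = .xavier(c(h, Nf), h, Nf),
      Ck     = .xavier(c(2L * Nf, Nf), 2L * Nf, Nf)
    )
  }
  pp
}

#' Construct an EPGN / NL-EPGN network with Xavier-initialized parameters
#'
#' Convolution kernels are drawn uniform on (-a, a) with
#' a = sqrt(6 / (fan_in + fan_out)); thresholds start at 0.01 per channel,
#' the momentum at 0 (phases start as plain proximal-gradient steps) and both
#' step sizes at 1.  Initialization is deterministic given `seed`.
#'
#' @param config an [epgn_config()]
#' @param seed integer seed for reproducible initialization
#' @return an object of class `epgn_network`: list with `config` and
#'   `phases` (length-K list of per-phase parameter lists)
#' @export
epgn_network <- function(config, seed = 0L) {
  stopifnot(inherits(config, "epgn_config"))
  set.seed(as.integer(seed))
  phases <- lapply(seq_len(config$K), function(k)
    .init_phase(config$Nf, config$nonlocal))
  structure(list(config = config, phases = phases), class = "epgn_network")
}

#' Analytic count of learnable parameters
#'
#' Per phase: encoder 3*3*Nf*(1 + 2*Nf), decoder the same, one momentum
#' coefficient, two step sizes, Nf thresholds; the nonlocal variant adds
#' 4*Nf^2 (three bottleneck projections, the expansion, and the fusion
#' projection from 2*Nf to Nf channels).  At Nf = 32 this gives 37,475 per
#' plain phase and 41,571 per nonlocal phase.
#'
#' @param config an [epgn_config()]
#' @return list with `per_phase` and `total`
#' @export
count_parameters <- function(config) {
  stopifnot(inherits(config, "epgn_config"))
  Nf <- config$Nf
  enc <- 3 * 3 * Nf * (1 + 2 * Nf)
  dec <- 3 * 3 * Nf * (2 * Nf + 1)
  per <- enc + dec + 1 + 2 + Nf
  if (config$nonlocal) per <- per + 4 * Nf^2
  list(per_phase = per, total = config$K * per)
}

#' Brute-force parameter count by enumerating stored tensors
#'
#' Walks every numeric array held by the network and sums their lengths;
#' serves as the independent check of [count_parameters()].
#'
#' @param net an `epgn_network`
#' @return list with `per_phase` (integer vector, one entry per phase) and
#'   `total`
#' @export
enumerate_parameters <- function(net) {
  stopifnot(inherits(net, "epgn_network"))
  count_one <- function(x) {
    if (is.list(x)) sum(vapply(x, count_one, numeric(1))) else length(x)
  }
  per <- vapply(net$phases, count_one, numeric(1))
  list(per_phase = as.integer(per), total = as.integer(sum(per)))
}

#' @export
print.epgn_network <- function(x, ...) {
  cnt <- count_parameters(x$config)
  cat(sprintf("<epgn_network: %s, K = %d phases, Nf = %d, %s parameters (%s/phase)>\n",
              if (x$config$nonlocal) "NL-EPGN" else "EPGN",
              x$config$K, x$config$Nf,
              format(cnt$total, big.mark = ","),
              format(cnt$per_phase, big.mark = ",")))
  invisible(x)
}

# ---- feature-map helpers ---------------------------------------------------

# (H, W, C) array <-> (H*W, C) matrix (column-major spatial flattening)
.fm_to_mat <- function(z) {
  d <- dim(z)
  if (length(d) == 2L) d <- c(d, 1L)
  matrix(z, d[1L] * d[2L], d[3L])
}

.mat_to_fm <- function(m, H, W) {
  array(m, c(H, W, ncol(m)))
}

# ---- forward building blocks ----------------------------------------------

# Internal forms operate on stacked feature matrices (B*H*W, C) with an
# im2col plan; the exported single-image forms wrap them with (H, W, C)
# arrays for interactive use and testing.

.encode_fw <- function(pp, b, plan) {
  h1 <- conv3_forward(b, pp$D, plan)
  h2 <- conv3_forward(h1, pp$A, plan)
  m3 <- relu(h2)
  z <- conv3_forward(m3, pp$B, plan)
  list(z = z, b = b, h1 = h1, h2 = h2, m3 = m3)
}

.decode_fw <- function(pp, u, plan) {
  q1 <- conv3_forward(u, pp$Btil, plan)
  q2 <- relu(q1)
  q3 <- conv3_forward(q2, pp$Atil, plan)
  r <- conv3_forward(q3, pp$Dtil, plan)
  list(r = r, u = u, q1 = q1, q2 = q2, q3 = q3)
}

.shrink_fw <- function(z, theta) {
  th <- matrix(theta, nrow(z), length(theta), byrow = TRUE)
  mask <- abs(z) > th
  s <- (abs(z) - th) * sign(z) * mask
  list(s = s, mask = mask, z = z)
}

.residual_fw <- function(pp, b, plan) {
  enc <- .encode_fw(pp, b, plan)
  shr <- .shrink_fw(enc$z, pp$theta)
  nl <- NULL
  u <- shr$s
  if (!is.null(pp$nl)) {
    nl <- .nl_fw(pp$nl, shr$s, plan$H * plan$W, plan$B)
    u <- nl$out
  }
  dec <- .decode_fw(pp, u, plan)
  list(out = b + dec$r, enc = enc, shr = shr, nl = nl, dec = dec)
}

#' Encoder: three stacked bias-free 3x3 convolutions with one ReLU
#'
#' Computes `B . ReLU . A . D` applied to a single-channel image, producing a
#' feature map with `Nf` channels; same (zero) padding preserves the spatial
#' shape and the receptive field of the composition is 7x7.
#'
#' @param params a phase-parameter list (one element of `net$phases`)
#' @param x image matrix (H x W)
#' @return feature array (H, W, Nf)
#' @export
encode_features <- function(params, x) {
  H <- nrow(x); W <- ncol(x)
  plan <- conv_plan(H, W, 1L)
  .mat_to_fm(.encode_fw(params, matrix(as.vector(x), ncol = 1L), plan)$z, H, W)
}

#' Channelwise soft shrinkage of a feature map
#'
#' Applies [soft_shrink()] per channel j with threshold `theta[j]`.
#'
#' @param z feature array (H, W, Nf)
#' @param theta length-Nf threshold vector (learned; may be any real, the
#'   shrinkage formula remains well defined for negative values)
#' @return shrunken feature array of the same shape
#' @export
channel_shrink <- function(z, theta) {
  d <- dim(z)
  if (length(theta) != d[3L]) stop("theta length must equal channel count")
  out <- .shrink_fw(.fm_to_mat(z), theta)$s
  .mat_to_fm(out, d[1L], d[2L])
}

#' Decoder: mirror of the encoder back to one channel
#'
#' Computes `Dtil . Atil . ReLU . Btil`; `Dtil` compresses the Nf channels
#' back to a single channel.
#'
#' @param params a phase-parameter list
#' @param z feature array (H, W, Nf)
#' @return image matrix (H x W)
#' @export
decode_features <- function(params, z) {
  d <- dim(z)
  plan <- conv_plan(d[1L], d[2L], 1L)
  matrix(.decode_fw(params, .fm_to_mat(z), plan)$r, d[1L], d[2L])
}

#' Learned residual update replacing the proximal step
#'
#' `b + decode(shrink(encode(b)))`, with the nonlocal operator inserted
#' between shrinkage and decoding when the phase carries nonlocal parameters.
#'
#' @param params a phase-parameter list
#' @param b image matrix (H x W)
#' @return updated image matrix (H x W)
#' @export
residual_update <- function(params, b) {
  H <- nrow(b); W <- ncol(b)
  plan <- conv_plan(H, W, 1L)
  matrix(.residual_fw(params, matrix(as.vector(b), ncol = 1L), plan)$out, H, W)
}

# One full phase on a batch: x_k, x_half_prev are (n, B); returns cache for
# reverse mode.  The two residual updates share the same parameters.
.phase_fw <- function(pp, Xk, Xh, op, Y, plan) {
  B <- ncol(Xk); n <- nrow(Xk)
  tocol <- function(M) matrix(as.vector(M), ncol = 1L)
  tomat <- function(cl) matrix(cl, n, B)
  g <- pp$gamma
  Xt <- Xk + g * (Xk - Xh)
  Gf1 <- fidelity_gradient(op, Xt, Y)
  Bh <- Xt - pp$alpha * Gf1
  ru1 <- .residual_fw(pp, tocol(Bh), plan)
  Xhalf <- tomat(ru1$out)
  if (!all(is.finite(Xhalf))) stop("phase divergence: non-finite half iterate")
  Xhat <- Xhalf + g * (Xhalf - Xk)
  Gf2 <- fidelity_gradient(op, Xhat, Y)
  Bn <- Xhat - pp$beta * Gf2
  ru2 <- .residual_fw(pp, tocol(Bn), plan)
  Xnext <- tomat(ru2$out)
  if (!all(is.finite(Xnext))) stop("phase divergence: non-finite iterate")
  list(x_next = Xnext, x_half = Xhalf,
       Xk = Xk, Xh = Xh, Xt = Xt, Gf1 = Gf1, Bh = Bh, ru1 = ru1,
       Xhat = Xhat, Gf2 = Gf2, Bn = Bn, ru2 = ru2)
}

#' One network phase applied to a single image
#'
#' Executes the momentum extrapolation, the alpha gradient step, the learned
#' residual update, the second extrapolation, the beta gradient step, and the
#' second residual update (sharing the same parameters), exactly mirroring
#' one iteration of the classical algorithm with learned proximal steps.
#'
#' @param params a phase-parameter list
#' @param x_k current iterate, H x W matrix
#' @param x_half_prev previous half iterate, H x W matrix
#' @param op a `sensing_operator` on n = H*W pixels
#' @param y measurement vector
#' @return list with `x_next` and `x_half` (both H x W matrices)
#' @export
phase_forward <- function(params, x_k, x_half_prev, op, y) {
  H <- nrow(x_k); W <- ncol(x_k)
  plan <- conv_plan(H, W, 1L)
  res <- .phase_fw(params,
                   matrix(as.vector(x_k), ncol = 1L),
                   matrix(as.vector(x_half_prev), ncol = 1L),
                   op, matrix(y, ncol = 1L), plan)
  list(x_next = matrix(res$x_next, H, W), x_half = matrix(res$x_half, H, W))
}

# Resolve the spatial shape of the reconstruction domain.
.op_shape <- function(op, shape = NULL) {
  if (!is.null(shape)) return(as.integer(shape))
  if (op$kind == "fourier_masked") return(c(op$H, op$W))
  s <- sqrt(op$n)
  if (s != round(s)) stop("non-square pixel count; supply `shape = c(H, W)`")
  c(as.integer(s), as.integer(s))
}

.network_fw <- function(net, op, Y, x0 = NULL, shape = NULL, keep_cache = FALSE) {
  hw <- .op_shape(op, shape)
  B <- ncol(Y)
  plan <- conv_plan(hw[1L], hw[2L], B)
  if (is.null(x0)) {
    x0 <- op_adjoint(op, Y)
    if (is.complex(x0)) x0 <- Re(x0)
  }
  Xk <- x0; Xh <- x0
  caches <- if (keep_cache) vector("list", net$config$K) else NULL
  for (k in seq_len(net$config$K)) {
    res <- tryCatch(
      .phase_fw(net$phases[[k]], Xk, Xh, op, Y, plan),
      error = function(e) stop(sprintf("phase %d: %s", k, conditionMessage(e)))
    )
    Xk <- res$x_next; Xh <- res$x_half
    if (keep_cache) caches[[k]] <- res
  }
  list(x = Xk, caches = caches, plan = plan, x0 = x0)
}

#' Full forward pass of the unrolled network
#'
#' Initializes with `x0 = A^H y` (the adjoint / zero-filled reconstruction)
#' unless given, sets the initial half iterate equal to `x0`, and chains the
#' K phases.
#'
#' @param net an `epgn_network`
#' @param op a `sensing_operator`
#' @param y measurement vector, or (m, B) matrix for a batch
#' @param x0 optional initial iterate(s), shaped like the vectorised image(s)
#' @param shape image shape `c(H, W)`; inferred from the operator when
#'   possible (Fourier operators know their grid; Gaussian operators assume a
#'   square image)
#' @return reconstruction: H x W matrix for a vector `y`, else an (n, B)
#'   matrix of vectorised reconstructions
#' @export
network_forward <- function(net, op, y, x0 = NULL, shape = NULL) {
  vec_in <- is.null(dim(y))
  Y <- if (vec_in) matrix(y, ncol = 1L) else y
  if (!is.null(x0) && is.null(dim(x0))) x0 <- matrix(as.vector(x0), ncol = 1L)
  out <- .network_fw(net, op, Y, x0 = x0, shape = shape)$x
  if (vec_in) {
    hw <- .op_shape(op, shape)
    matrix(out, hw[1L], hw[2L])
  } else out
}

# ---- checkpointing ---------------------------------------------------------

#' Save network parameters (and optional optimizer state) to disk
#'
#' The container stores the configuration plus every named tensor per phase;
#' round-trips are bit-exact.
#'
#' @param net an `epgn_network`
#' @param path file path (conventionally `.rds`)
#' @param extra optional list stored alongside (e.g. optimizer state)
#' @export
save_checkpoint <- function(net, path, extra = NULL) {
  saveRDS(list(config = unclass(net$config), phases = net$phases,
               extra = extra), path)
  invisible(path)
}

#' Load a checkpoint written by [save_checkpoint()]
#' @param path file path
#' @return list with `net` (`epgn_network`) and `extra`
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  cfg <- structure(obj$config, class = "epgn_config")
  net <- structure(list(config = cfg, phases = obj$phases),
                   class = "epgn_network")
  list(net = net, extra = obj$extra)
}
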