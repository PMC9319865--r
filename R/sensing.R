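# Sensing operators: measurement models for block compressed sensing
# (row-orthonormalized random Gaussian matrices) and CS-MRI (radial-mask
# partial Fourier), together with the data-fidelity gradient they induce.
#
# Throughout, images are H x W real matrices with intensities in [0, 1] and
# are vectorised column-major; batches are (n, B) matrices of stacked columns.
# The fidelity is f(x; y) = 0.5 * ||A x - y||^2, so grad f = A^H (A x - y);
# the factor-of-two difference from the unsquared-halved convention is
# absorbed by the (learned or user-chosen) step sizes.

#' Create a random Gaussian sensing operator with orthonormal rows
#'
#' Draws an m x n matrix of i.i.d. standard normal entries with
#' m = round(ratio * n), then orthonormalizes its rows (QR on the transpose)
#' so that `A %*% t(A)` is the identity on measurement space.  Used for block
#' compressed sensing of vectorised 33 x 33 luminance patches.
#'
#' @param n number of pixels (length of the vectorised image)
#' @param ratio sampling ratio m/n in (0, 1]
#' @param seed integer seed; the operator is reproducible bit-for-bit
#' @return an object of class `sensing_operator` with fields `kind`
#'   (`"gaussian"`), `A` (the m x n matrix), `n`, `m`, `ratio`,
#'   `achieved_ratio`
#' @examples
#' op <- make_gaussian_operator(16, 0.5, seed = 1)
#' max(abs(op$A %*% t(op$A) - diag(op$m)))   # ~1e-16
#' @export
make_gaussian_operator <- function(n, ratio, seed = 0L) {
  if (!is.numeric(ratio) || length(ratio) != 1L || ratio <= 0 || ratio > 1)
    stop("`ratio` must be a single number in (0, 1]")
  if (!is.numeric(n) || n < 1) stop("`n` must be a positive integer")
  n <- as.integer(n)
  m <- as.integer(round(ratio * n))
  if (m < 1L) stop("ratio too small: m = round(ratio * n) is 0")
  G <- local({
    set.seed(as.integer(seed))
    matrix(stats::rnorm(m * n), m, n)
  })
  # Rows of A span the row space of G with A A^T = I: QR of t(G).
  Q <- qr.Q(qr(t(G)))[, seq_len(m), drop = FALSE]
  A <- t(Q)
  structure(
    list(kind = "gaussian", A = A, n = n, m = m, ratio = ratio,
         achieved_ratio = m / n, seed = as.integer(seed)),
    class = "sensing_operator"
  )
}

#' Construct a binary radial k-space sampling mask
#'
#' Evenly rotated straight spokes through the k-space centre, rasterized by
#' nearest-neighbour; the spoke count is found by bisection so that the
#' sampled fraction is within +/- `tol` of `ratio`.  The DC coefficient is
#' always sampled.  The mask is returned in "centred" layout with DC at
#' (floor(H/2)+1, floor(W/2)+1); the Fourier operator shifts it internally.
#'
#' @param H,W mask height and width
#' @param ratio target fraction of sampled frequencies, in (0, 1)
#' @param tol acceptable deviation of the achieved fraction (default 0.02)
#' @return object of class `radial_mask`: list with `mask` (H x W 0/1
#'   matrix), `ratio`, `achieved_ratio`, `n_spokes`
#' @export
make_radial_mask <- function(H, W, ratio, tol = 0.02) {
  if (ratio <= 0 || ratio >= 1) stop("`ratio` must be in (0, 1)")
  H <- as.integer(H); W <- as.integer(W)
  build <- function(ns) {
    mask <- matrix(0L, H, W)
    cr <- H %/% 2 + 1L; cc <- W %/% 2 + 1L
    L <- ceiling(sqrt(H^2 + W^2))
    tgrid <- seq(-L / 2, L / 2, by = 0.5)
    for (s in seq_len(ns)) {
      ang <- pi * (s - 1) / ns
      rr <- round(cr + tgrid * sin(ang))
      cc2 <- round(cc + tgrid * cos(ang))
      ok <- rr >= 1 & rr <= H & cc2 >= 1 & cc2 <= W
      mask[cbind(rr[ok], cc2[ok])] <- 1L
    }
    mask[cr, cc] <- 1L
    mask
  }
  frac <- function(ns) mean(build(ns))
  lo <- 1L; hi <- 2L
  while (frac(hi) < ratio && hi < 4L * max(H, W)) hi <- hi * 2L
  if (frac(hi) < ratio - tol)
    stop(sprintf("requested ratio %.3f unreachable at %dx%d; max achievable %.3f",
                 ratio, H, W, frac(hi)))
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (frac(mid) < ratio) lo <- mid else hi <- mid
  }
  # pick the endpoint closest to the target
  ns <- if (abs(frac(lo) - ratio) <= abs(frac(hi) - ratio)) lo else hi
  mask <- build(ns)
  achieved <- mean(mask)
  if (abs(achieved - ratio) > tol)
    stop(sprintf("radial mask: achieved fraction %.4f outside %.3f +/- %.3f",
                 achieved, ratio, tol))
  structure(list(mask = mask, ratio = ratio, achieved_ratio = achieved,
                 n_spokes = ns),
            class = "radial_mask")
}

#' Create a masked-Fourier (CS-MRI) sensing operator
#'
#' The forward map selects the masked coefficients of the orthonormal 2-D
#' discrete Fourier transform (scaling 1/sqrt(n) both ways), i.e. Phi = P F;
#' the adjoint zero-fills and inverse-transforms.  Measurements are complex;
#' the fidelity gradient takes the real part of the adjoint residual since
#' images are real-valued.
#'
#' @param mask a `radial_mask`, or any H x W 0/1 matrix in centred layout
#' @return an object of class `sensing_operator` with `kind = "fourier_masked"`
#' @export
make_fourier_operator <- function(mask) {
  if (inherits(mask, "radial_mask")) {
    M <- mask$mask; ratio <- mask$achieved_ratio
  } else {
    M <- mask
    if (!all(M %in% c(0, 1))) stop("mask entries must be 0/1")
    ratio <- mean(M)
  }
  H <- nrow(M); W <- ncol(M); n <- H * W
  # shift centred mask so DC lands at [1,1], matching stats::fft layout
  Mshift <- ifftshift2(M)
  sel <- which(Mshift == 1)          # column-major indices into the FFT grid
  structure(
    list(kind = "fourier_masked", H = H, W = W, n = n, m = length(sel),
         ratio = ratio, achieved_ratio = length(sel) / n,
         mask_centred = M, sel = sel),
    class = "sensing_operator"
  )
}

# circular shifts moving the centred DC bin (floor/2 + 1) to [1,1] and back
ifftshift2 <- function(M) {
  H <- nrow(M); W <- ncol(M)
  M[c((H %/% 2 + 1):H, seq_len(H %/% 2)), c((W %/% 2 + 1):W, seq_len(W %/% 2))]
}

#' Apply a sensing operator to one or more vectorised images
#'
#' @param op a `sensing_operator`
#' @param x numeric vector of length n, or (n, B) matrix of B stacked images
#' @return measurements: (m, B) matrix (real for Gaussian, complex for
#'   masked-Fourier); a vector input returns a vector
#' @export
op_forward <- function(op, x) {
  vec_in <- is.null(dim(x))
  X <- if (vec_in) matrix(x, ncol = 1L) else x
  if (nrow(X) != op$n) stop("image size does not match operator")
  Y <- switch(op$kind,
    gaussian = op$A %*% X,
    fourier_masked = {
      B <- ncol(X)
      out <- matrix(0+0i, op$m, B)
      for (b in seq_len(B)) {
        F2 <- stats::fft(matrix(X[, b], op$H, op$W)) / sqrt(op$n)
        out[, b] <- F2[op$sel]
      }
      out
    },
    stop("unknown operator kind"))
  if (vec_in) drop(Y) else Y
}

#' Apply the adjoint of a sensing operator
#'
#' For the Gaussian kind this is `t(A) %*% y`; for the masked-Fourier kind the
#' measurements are zero-filled onto the k-space grid and inverse transformed
#' (the classical zero-filled reconstruction when applied to data).
#'
#' @param op a `sensing_operator`
#' @param y measurement vector (length m) or (m, B) matrix
#' @param real if `TRUE` (default) return the real part for the Fourier kind,
#'   appropriate for real-valued images; set `FALSE` to obtain the exact
#'   complex adjoint (used e.g. in adjoint-identity checks)
#' @return (n, B) matrix, or vector if `y` was a vector
#' @export
op_adjoint <- function(op, y, real = TRUE) {
  vec_in <- is.null(dim(y))
  Y <- if (vec_in) matrix(y, ncol = 1L) else y
  if (nrow(Y) != op$m) stop("measurement size does not match operator")
  X <- switch(op$kind,
    gaussian = crossprod(op$A, Y),
    fourier_masked = {
      B <- ncol(Y)
      out <- matrix(0+0i, op$n, B)
      for (b in seq_len(B)) {
        Z <- matrix(0+0i, op$H, op$W)
        Z[op$sel] <- Y[, b]
        out[, b] <- as.vector(stats::fft(Z, inverse = TRUE) / sqrt(op$n))
      }
      if (real) Re(out) else out
    },
    stop("unknown operator kind"))
  if (vec_in) drop(X) else X
}

#' Normal operator A^H A (real part for the Fourier kind)
#'
#' The Jacobian of [fidelity_gradient()] with respect to `x`; symmetric as a
#' real operator for both kinds, which the network backward pass exploits.
#'
#' @inheritParams op_forward
#' @keywords internal
op_normal <- function(op, x) {
  vec_in <- is.null(dim(x))
  X <- if (vec_in) matrix(x, ncol = 1L) else x
  Z <- switch(op$kind,
    gaussian = crossprod(op$A, op$A %*% X),
    fourier_masked = {
      B <- ncol(X)
      out <- matrix(0, op$n, B)
      msk <- as.numeric(ifftshift2(op$mask_centred))
      for (b in seq_len(B)) {
        F2 <- stats::fft(matrix(X[, b], op$H, op$W))
        F2 <- F2 * matrix(msk, op$H, op$W)
        out[, b] <- Re(as.vector(stats::fft(F2, inverse = TRUE))) / op$n
      }
      out
    })
  if (vec_in) drop(Z) else Z
}

#' Gradient of the data-fidelity term
#'
#' Returns grad_x 0.5 * ||A x - y||^2 = A^H (A x - y), taking the real part
#' for the masked-Fourier kind (real-valued images, complex measurements).
#'
#' @param op a `sensing_operator`
#' @param x vectorised image(s), length-n vector or (n, B) matrix
#' @param y measurements matching `op_forward(op, x)` in shape
#' @return gradient with the same shape as `x`
#' @export
fidelity_gradient <- function(op, x, y) {
  r <- op_forward(op, x) - y
  g <- op_adjoint(op, r, real = TRUE)
  if (is.complex(g)) g <- Re(g)
  g
}

#' Data-fidelity value 0.5 * ||A x - y||^2
#' @inheritParams fidelity_gradient
#' @return numeric scalar (summed over the batch if `x` is a matrix)
#' @export
fidelity_value <- function(op, x, y) {
  r <- op_forward(op, x) - y
  0.5 * sum(Mod(r)^2)
}

#' @export
print.sensing_operator <- function(x, ...) {
  cat(sprintf("<sensing_operator: %s, n = %d, m = %d (ratio %.3f)>\n",
              x$kind, x$n, x$m, x$achieved_ratio))
  invisible(x)
}

#' @export
print.radial_mask <- function(x, ...) {
  cat(sprintf("<radial_mask: %d x %d, %d spokes, sampled fraction %.3f (target %.3f)>\n",
              nrow(x$mask), ncol(x$mask), x$n_spokes, x$achieved_ratio, x$ratio))
  invisible(x)
}
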