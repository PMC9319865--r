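# Reconstruction quality metrics and experiment orchestration: PSNR, SSIM,
# block tiling for patch-based compressed sensing, and aggregate evaluation
# reports (mean +/- sd over a test set).

#' Peak signal-to-noise ratio in dB
#'
#' `10 * log10(peak^2 / MSE)`.  Identical images (MSE = 0) return a capped
#' value of 99 dB with attribute `capped = TRUE`.
#'
#' @param x,ref images (any conformable numeric arrays)
#' @param peak peak intensity (1 for normalized images)
#' @return PSNR in dB
#' @export
psnr <- function(x, ref, peak = 1) {
  if (length(x) != length(ref)) stop("shapes differ")
  mse <- mean((as.numeric(x) - as.numeric(ref))^2)
  if (mse == 0) return(structure(99, capped = TRUE))
  10 * log10(peak^2 / mse)
}

# 1-D Gaussian taps for the SSIM window
.ssim_window <- function(size = 11L, sigma = 1.5) {
  t <- seq_len(size) - (size + 1) / 2
  g <- exp(-t^2 / (2 * sigma^2))
  g / sum(g)
}

# separable valid-mode filtering with a 1-D kernel
.filter_valid <- function(M, g) {
  k <- length(g)
  H <- nrow(M); W <- ncol(M)
  out <- matrix(0, H - k + 1L, W)
  for (t in seq_len(k)) out <- out + g[t] * M[t:(H - k + t), , drop = FALSE]
  out2 <- matrix(0, nrow(out), W - k + 1L)
  for (t in seq_len(k)) out2 <- out2 + g[t] * out[, t:(W - k + t), drop = FALSE]
  out2
}

#' Structural similarity index (mean SSIM)
#'
#' Standard single-scale SSIM with an 11 x 11 Gaussian window (sigma 1.5),
#' stabilization constants K1 = 0.01, K2 = 0.03 and dynamic range `peak`;
#' local statistics are computed on valid windows only and averaged.
#'
#' @param x,ref H x W image matrices
#' @param peak dynamic range (1 for normalized images)
#' @return mean SSIM in [-1, 1]
#' @export
ssim <- function(x, ref, peak = 1) {
  if (!all(dim(x) == dim(ref))) stop("shapes differ")
  if (min(dim(x)) < 11L) stop("image smaller than the 11 x 11 SSIM window")
  g <- .ssim_window()
  C1 <- (0.01 * peak)^2; C2 <- (0.03 * peak)^2
  mx <- .filter_valid(x, g); my <- .filter_valid(ref, g)
  sxx <- .filter_valid(x * x, g) - mx^2
  syy <- .filter_valid(ref * ref, g) - my^2
  sxy <- .filter_valid(x * ref, g) - mx * my
  sm <- ((2 * mx * my + C1) * (2 * sxy + C2)) /
    ((mx^2 + my^2 + C1) * (sxx + syy + C2))
  mean(sm)
}

# ---- block tiling for patch-based CS --------------------------------------

#' Pad an image to a multiple of a block size by edge replication
#' @param img H x W matrix
#' @param block block side length
#' @return padded matrix with attribute `orig_dim`
#' @export
pad_to_multiple <- function(img, block = 33L) {
  H <- nrow(img); W <- ncol(img)
  H2 <- ceiling(H / block) * block; W2 <- ceiling(W / block) * block
  out <- img[c(seq_len(H), rep.int(H, H2 - H)),
             c(seq_len(W), rep.int(W, W2 - W)), drop = FALSE]
  attr(out, "orig_dim") <- c(H, W)
  out
}

#' Split an image into non-overlapping vectorised blocks
#' @param img H x W matrix with H, W multiples of `block`
#' @param block block side length
#' @return (block^2, n_blocks) matrix; blocks ordered column-major over the
#'   block grid, with attribute `grid = c(rows, cols)`
#' @export
image_to_blocks <- function(img, block = 33L) {
  H <- nrow(img); W <- ncol(img)
  if (H %% block != 0 || W %% block != 0) stop("image is not block-aligned")
  br <- H %/% block; bc <- W %/% block
  out <- matrix(0, block^2, br * bc)
  k <- 0L
  for (j in seq_len(bc)) for (i in seq_len(br)) {
    k <- k + 1L
    out[, k] <- as.vector(img[((i - 1L) * block + 1L):(i * block),
                              ((j - 1L) * block + 1L):(j * block)])
  }
  attr(out, "grid") <- c(br, bc)
  out
}

#' Reassemble blocks produced by [image_to_blocks()]
#' @param blocks (block^2, n_blocks) matrix
#' @param grid block-grid dimensions `c(rows, cols)` (defaults to the
#'   attribute left by [image_to_blocks()])
#' @param block block side length
#' @return reassembled image matrix
#' @export
blocks_to_image <- function(blocks, grid = attr(blocks, "grid"), block = 33L) {
  br <- grid[1L]; bc <- grid[2L]
  img <- matrix(0, br * block, bc * block)
  k <- 0L
  for (j in seq_len(bc)) for (i in seq_len(br)) {
    k <- k + 1L
    img[((i - 1L) * block + 1L):(i * block),
        ((j - 1L) * block + 1L):(j * block)] <- matrix(blocks[, k], block, block)
  }
  img
}

# ---- reconstructors and evaluation ----------------------------------------

#' Reconstructor backed by a trained network
#' @param net an `epgn_network`
#' @param op the `sensing_operator` the measurements come from
#' @param shape image shape when not inferable from `op`
#' @return function mapping an (m, B) measurement matrix to an (n, B)
#'   reconstruction matrix
#' @export
network_reconstructor <- function(net, op, shape = NULL) {
  function(Y) .network_fw(net, op, Y, shape = shape)$x
}

#' Baseline adjoint reconstructor (zero-filled reconstruction for MRI)
#' @param op a `sensing_operator`
#' @return function mapping measurements to `Re(A^H y)`
#' @export
adjoint_reconstructor <- function(op) {
  function(Y) {
    X <- op_adjoint(op, Y)
    if (is.complex(X)) X <- Re(X)
    X
  }
}

#' Evaluate a reconstructor on a test set
#'
#' In `"cs"` mode each image is edge-padded to a multiple of the block size,
#' measured and reconstructed block by block, reassembled and cropped; in
#' `"csmri"` mode whole images are measured and reconstructed directly.
#' PSNR and SSIM are computed per image and aggregated as mean +/- sd.
#'
#' @param reconstruct function mapping an (m, B) measurement matrix to an
#'   (n, B) reconstruction matrix (see [network_reconstructor()])
#' @param images list of ground-truth H x W matrices
#' @param op a `sensing_operator` (block-sized in `"cs"` mode, image-sized in
#'   `"csmri"` mode)
#' @param mode `"cs"` or `"csmri"`
#' @param block block side length in `"cs"` mode
#' @return a `metric_report`: list with `per_image` (data.frame psnr/ssim),
#'   `mean_psnr`, `sd_psnr`, `mean_ssim`, `sd_ssim`, and the reconstructions
#' @export
evaluate_reconstruction <- function(reconstruct, images, op,
                                    mode = c("cs", "csmri"), block = 33L) {
  mode <- match.arg(mode)
  if (length(images) == 0) stop("empty test set")
  recs <- vector("list", length(images))
  for (i in seq_along(images)) {
    img <- images[[i]]
    if (mode == "cs") {
      pad <- pad_to_multiple(img, block)
      blocks <- image_to_blocks(pad, block)
      Y <- op_forward(op, blocks)
      Xr <- reconstruct(Y)
      rec <- blocks_to_image(Xr, attr(blocks, "grid"), block)
      od <- attr(pad, "orig_dim")
      rec <- rec[seq_len(od[1L]), seq_len(od[2L]), drop = FALSE]
    } else {
      y <- op_forward(op, as.vector(img))
      xr <- reconstruct(matrix(y, ncol = 1L))
      rec <- matrix(xr, nrow(img), ncol(img))
    }
    recs[[i]] <- rec
  }
  ps <- vapply(seq_along(images), function(i)
    as.numeric(psnr(recs[[i]], images[[i]])), numeric(1))
  ss <- vapply(seq_along(images), function(i)
    ssim(recs[[i]], images[[i]]), numeric(1))
  structure(list(
    per_image = data.frame(psnr = ps, ssim = ss),
    mean_psnr = mean(ps), sd_psnr = stats::sd(ps),
    mean_ssim = mean(ss), sd_ssim = stats::sd(ss),
    reconstructions = recs
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report: %d image(s); PSNR %.2f +/- %.2f dB; SSIM %.4f +/- %.4f>\n",
              nrow(x$per_image), x$mean_psnr,
              ifelse(is.na(x$sd_psnr), 0, x$sd_psnr),
              x$mean_ssim, ifelse(is.na(x$sd_ssim), 0, x$sd_ssim)))
  invisible(x)
}

#' Parameter audit table
#'
#' Prints per-phase and total learnable-parameter counts for a model family
#' and checks the analytic formula against brute-force enumeration of a
#' constructed network's tensors.
#'
#' @param model `"epgn"` or `"nlepgn"`
#' @param phases phase count K
#' @param nf feature channels (default 32)
#' @param quiet suppress printing
#' @return invisible list with `per_phase`, `total`, `agrees` (logical:
#'   formula vs enumeration)
#' @export
audit_parameters <- function(model = c("epgn", "nlepgn"), phases, nf = 32L,
                             quiet = FALSE) {
  model <- match.arg(model)
  cfg <- epgn_config(K = phases, Nf = nf, nonlocal = (model == "nlepgn"))
  cnt <- count_parameters(cfg)
  net <- epgn_network(cfg, seed = 0L)
  enum <- enumerate_parameters(net)
  agrees <- all(enum$per_phase == cnt$per_phase) && enum$total == cnt$total
  if (!quiet) {
    cat(sprintf("model: %s   phases: %d   Nf: %d\n", toupper(model), phases, nf))
    cat(sprintf("  per-phase parameters: %s\n", format(cnt$per_phase, big.mark = ",")))
    cat(sprintf("  total parameters:     %s\n", format(cnt$total, big.mark = ",")))
    cat(sprintf("  tensor enumeration:   %s (%s)\n",
                format(enum$total, big.mark = ","),
                if (agrees) "agrees" else "MISMATCH"))
  }
  invisible(list(per_phase = cnt$per_phase, total = cnt$total, agrees = agrees))
}
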