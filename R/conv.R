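# Convolution layer used by the unrolled network.
#
# Feature maps are stored as dense matrices of shape (B*H*W, C): column-major
# pixel order within each image, images stacked along rows.  The same-padded
# bias-free 3x3 convolutions (cross-correlation orientation) and their
# reverse-mode gradients are evaluated in compiled code (src/conv3.cpp),
# which is what makes CPU-only training of the network practical.

#' Layout descriptor for a batch of H-by-W images
#'
#' Records the spatial shape and batch size shared by all convolutions of a
#' forward/backward pass.  Memoised per (H, W, B).
#'
#' @param H,W image height and width in pixels
#' @param B batch size (number of images stacked along rows)
#' @return list with `H`, `W`, `B`
#' @keywords internal
conv_plan <- function(H, W, B = 1L) {
  list(H = as.integer(H), W = as.integer(W), B = as.integer(B))
}

#' Same-padded 3x3 convolution (cross-correlation), bias-free
#'
#' Kernel entry `w[i, j, ci, co]` multiplies the input pixel at spatial
#' offset (i-2, j-2) of channel `ci`; zero padding outside the image.
#'
#' @param X feature matrix (B*H*W x Cin)
#' @param w kernel array (3, 3, Cin, Cout)
#' @param plan a layout descriptor from [conv_plan()]
#' @return feature matrix (B*H*W x Cout)
#' @keywords internal
conv3_forward <- function(X, w, plan) {
  .cpp_conv3_fw(X, w, plan$H, plan$W, plan$B)
}

#' Fused gradient of a 3x3 convolution (input and kernel together)
#'
#' @param X the forward-pass input (B*H*W x Cin)
#' @param gY upstream gradient (B*H*W x Cout)
#' @inheritParams conv3_forward
#' @return list with `gX` (B*H*W x Cin) and `gW` (3, 3, Cin, Cout)
#' @keywords internal
conv3_backward <- function(X, gY, w, plan) {
  .cpp_conv3_bw(X, gY, w, plan$H, plan$W, plan$B)
}

#' Gradient of a 3x3 convolution with respect to its input
#' @inheritParams conv3_backward
#' @keywords internal
conv3_backward_input <- function(gY, w, plan) {
  Cin <- dim(w)[3L]
  .cpp_conv3_bw(matrix(0, nrow(gY), Cin), gY, w, plan$H, plan$W, plan$B)$gX
}

#' Gradient of a 3x3 convolution with respect to its kernel
#' @inheritParams conv3_backward
#' @keywords internal
conv3_backward_kernel <- function(X, gY, plan) {
  Cin <- ncol(X); Cout <- ncol(gY)
  .cpp_conv3_bw(X, gY, array(0, c(3, 3, Cin, Cout)), plan$H, plan$W, plan$B)$gW
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

relu_backward <- function(g, pre) {
  g * (pre > 0)
}
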