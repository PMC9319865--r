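# Embedded-Gaussian nonlocal operator with bottleneck structure.
#
# Given a feature map z with Nf channels, attention weights between pixel
# pairs are softmax-normalized dot products of two learned Nf/2-dimensional
# embeddings; the attended representation (a third Nf/2 embedding averaged
# under those weights) is expanded back to Nf channels, concatenated with
# the local features, projected from 2*Nf to Nf channels by a learned 1x1
# map and passed through ReLU.  All projections are bias-free 1x1
# convolutions, i.e. plain channel-mixing matrices.

.softmax_rows <- function(L) {
  L <- L - apply(L, 1L, max)
  E <- exp(L)
  E / rowSums(E)
}

#' Embedded-Gaussian attention weights
#'
#' Row i of the returned matrix holds softmax over j of
#' `<Walpha' z_i, Wbeta' z_j>`; each row is an exact probability vector.
#' Computed with row-max subtraction for numerical stability.
#'
#' @param Walpha,Wbeta channel-projection matrices (Nf x Nf/2)
#' @param z feature array (H, W, Nf)
#' @return attention matrix (H*W x H*W), rows summing to 1
#' @export
nonlocal_weights <- function(Walpha, Wbeta, z) {
  Z <- .fm_to_mat(z)
  .softmax_rows(tcrossprod(Z %*% Walpha, Z %*% Wbeta))
}

#' Nonlocal feature extraction block
#'
#' Computes, at every pixel i, the attention-weighted average of the
#' bottleneck representation `Wphi' z_j` over all pixels j, then expands the
#' result from Nf/2 back to Nf channels with `Wexp`.
#'
#' @param params nonlocal parameter list with `Walpha`, `Wbeta`, `Wphi`,
#'   `Wexp` (see `epgn_network()`)
#' @param z feature array (H, W, Nf)
#' @return feature array (H, W, Nf)
#' @export
nonlocal_block_forward <- function(params, z) {
  d <- dim(z)
  Z <- .fm_to_mat(z)
  W <- .softmax_rows(tcrossprod(Z %*% params$Walpha, Z %*% params$Wbeta))
  V <- W %*% (Z %*% params$Wphi)
  .mat_to_fm(V %*% params$Wexp, d[1L], d[2L])
}

#' Local/nonlocal fusion layer (the full nonlocal operator)
#'
#' Concatenates the local features with the nonlocal block output pixelwise
#' (2*Nf channels), projects back to Nf channels with the learned 1x1 map
#' `Ck` and applies ReLU.  This is the operator inserted between shrinkage
#' and decoding in the nonlocal network variant.
#'
#' @param params nonlocal parameter list (`Walpha`, `Wbeta`, `Wphi`, `Wexp`,
#'   `Ck`)
#' @param z feature array (H, W, Nf)
#' @return feature array (H, W, Nf)
#' @export
fuse_local_nonlocal <- function(params, z) {
  d <- dim(z)
  out <- .nl_fw(params, .fm_to_mat(z), d[1L] * d[2L], 1L)$out
  .mat_to_fm(out, d[1L], d[2L])
}

# ---- batched internal forward/backward ------------------------------------

# S: (B*N, Nf) stacked feature matrix; attention is computed per sample.
.nl_fw <- function(nl, S, N, B) {
  Nf <- ncol(S)
  out <- matrix(0, nrow(S), Nf)
  per <- vector("list", B)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * N + 1L):(b * N)
    Z <- S[rows, , drop = FALSE]
    Ao <- Z %*% nl$Walpha
    Bo <- Z %*% nl$Wbeta
    Po <- Z %*% nl$Wphi
    W <- .softmax_rows(tcrossprod(Ao, Bo))
    V <- W %*% Po
    E <- V %*% nl$Wexp
    C <- cbind(Z, E)
    U <- C %*% nl$Ck
    O <- relu(U)
    out[rows, ] <- O
    per[[b]] <- list(Z = Z, Ao = Ao, Bo = Bo, Po = Po, W = W, V = V,
                     C = C, U = U)
  }
  list(out = out, per = per, N = N, B = B)
}

.nl_zero_grads <- function(nl) {
  lapply(nl, function(w) array(0, dim(w)))
}

# gOut: (B*N, Nf) upstream gradient; returns gradient wrt S and wrt the five
# projection matrices.
.nl_bw <- function(nl, cache, gOut) {
  N <- cache$N; B <- cache$B
  gS <- matrix(0, nrow(gOut), ncol(gOut))
  g <- .nl_zero_grads(nl)
  Nf <- ncol(gOut)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * N + 1L):(b * N)
    cc <- cache$per[[b]]
    gU <- relu_backward(gOut[rows, , drop = FALSE], cc$U)
    g$Ck <- g$Ck + crossprod(cc$C, gU)
    gC <- tcrossprod(gU, nl$Ck)
    gZ <- gC[, seq_len(Nf), drop = FALSE]
    gE <- gC[, Nf + seq_len(Nf), drop = FALSE]
    g$Wexp <- g$Wexp + crossprod(cc$V, gE)
    gV <- tcrossprod(gE, nl$Wexp)
    gW <- tcrossprod(gV, cc$Po)
    gPo <- crossprod(cc$W, gV)
    # softmax rows: gL = W * (gW - rowSums(gW * W))
    gL <- cc$W * (gW - rowSums(gW * cc$W))
    gAo <- gL %*% cc$Bo
    gBo <- crossprod(gL, cc$Ao)
    g$Walpha <- g$Walpha + crossprod(cc$Z, gAo)
    g$Wbeta  <- g$Wbeta + crossprod(cc$Z, gBo)
    g$Wphi   <- g$Wphi + crossprod(cc$Z, gPo)
    gZ <- gZ + tcrossprod(gAo, nl$Walpha) + tcrossprod(gBo, nl$Wbeta) +
      tcrossprod(gPo, nl$Wphi)
    gS[rows, ] <- gZ
  }
  list(gS = gS, grads = g)
}
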