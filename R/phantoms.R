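# Synthetic phantoms and patch extraction.
#
# The generator stands in for natural-image / MR training corpora at desk
# scale: piecewise-constant shapes (ellipses, rectangles, bars) over a flat
# background, plus a smooth low-frequency texture and optional Gaussian
# noise.  The resulting images are sparse under gradient-like transforms,
# which is the structure the learned shrinkage regularizer exploits.

#' Phantom specification
#'
#' @param size image size `c(H, W)`; 64 x 64 default for block-CS work, use
#'   190 x 190 for whole-image MRI-style experiments
#' @param n_shapes number of random shapes superimposed per phantom
#' @param texture_amplitude amplitude of the smooth additive texture
#' @param noise_sigma standard deviation of additive Gaussian noise (0 = none)
#' @return a `phantom_spec` list
#' @export
phantom_spec <- function(size = c(64L, 64L), n_shapes = 6L,
                         texture_amplitude = 0.03, noise_sigma = 0) {
  structure(list(size = as.integer(size), n_shapes = as.integer(n_shapes),
                 texture_amplitude = texture_amplitude,
                 noise_sigma = noise_sigma),
            class = "phantom_spec")
}

.draw_phantom <- function(spec) {
  H <- spec$size[1L]; W <- spec$size[2L]
  rr <- matrix(rep(seq_len(H), W), H, W)
  cc <- matrix(rep(seq_len(W), each = H), H, W)
  img <- matrix(stats::runif(1, 0.05, 0.25), H, W)
  if (spec$n_shapes > 0) for (s in seq_len(spec$n_shapes)) {
    kind <- sample(c("ellipse", "rect", "bar"), 1L)
    val <- stats::runif(1, 0.15, 0.95)
    cy <- stats::runif(1, 0.2, 0.8) * H; cx <- stats::runif(1, 0.2, 0.8) * W
    if (kind == "ellipse") {
      a <- stats::runif(1, 0.06, 0.3) * H; b <- stats::runif(1, 0.06, 0.3) * W
      ang <- stats::runif(1, 0, pi)
      u <- (rr - cy) * cos(ang) + (cc - cx) * sin(ang)
      v <- -(rr - cy) * sin(ang) + (cc - cx) * cos(ang)
      m <- (u / a)^2 + (v / b)^2 <= 1
    } else {
      # bar = thin rotated rectangle
      hh <- if (kind == "bar") stats::runif(1, 0.01, 0.04) * H
            else stats::runif(1, 0.08, 0.3) * H
      ww <- stats::runif(1, 0.08, 0.4) * W
      ang <- stats::runif(1, 0, pi)
      u <- (rr - cy) * cos(ang) + (cc - cx) * sin(ang)
      v <- -(rr - cy) * sin(ang) + (cc - cx) * cos(ang)
      m <- abs(u) <= hh & abs(v) <= ww
    }
    img[m] <- val
  }
  if (spec$texture_amplitude > 0) {
    for (t in 1:2) {
      lam <- stats::runif(1, max(H, W) / 2, max(H, W))
      ang <- stats::runif(1, 0, pi); ph <- stats::runif(1, 0, 2 * pi)
      img <- img + (spec$texture_amplitude / 2) *
        sin(2 * pi * (rr * sin(ang) + cc * cos(ang)) / lam + ph)
    }
  }
  if (spec$noise_sigma > 0)
    img <- img + matrix(stats::rnorm(H * W, 0, spec$noise_sigma), H, W)
  pmin(pmax(img, 0), 1)
}

#' Generate reproducible synthetic phantoms
#'
#' @param count number of phantoms (>= 1)
#' @param spec a [phantom_spec()]
#' @param seed integer seed; the full set is deterministic given the seed
#' @return list of H x W matrices with intensities in [0, 1]
#' @export
make_phantoms <- function(count, spec = phantom_spec(), seed = 0L) {
  if (count < 1) stop("count must be >= 1")
  set.seed(as.integer(seed))
  lapply(seq_len(count), function(i) .draw_phantom(spec))
}

#' Randomly crop fixed-size patches from a set of images
#'
#' Uniform random crop positions, deterministic given `seed`.  Images smaller
#' than the patch size are skipped with a warning.
#'
#' @param images list of H x W matrices
#' @param patch patch side length (33 for block-CS training)
#' @param count number of patches to draw
#' @param seed integer seed
#' @return a `patch_set`: list with `patches` (array patch x patch x count)
#'   and `meta` (data.frame with source image index and top-left offsets)
#' @export
extract_patches <- function(images, patch = 33L, count = 100L, seed = 0L) {
  patch <- as.integer(patch)
  ok <- vapply(images, function(im) nrow(im) >= patch && ncol(im) >= patch,
               logical(1))
  if (!all(ok)) {
    warning(sprintf("skipping %d image(s) smaller than %d x %d",
                    sum(!ok), patch, patch))
    images <- images[ok]
  }
  if (length(images) == 0) stop("no image is large enough for the patch size")
  set.seed(as.integer(seed))
  arr <- array(0, c(patch, patch, count))
  meta <- data.frame(image = integer(count), row = integer(count),
                     col = integer(count))
  for (i in seq_len(count)) {
    j <- sample.int(length(images), 1L)
    im <- images[[j]]
    r0 <- sample.int(nrow(im) - patch + 1L, 1L)
    c0 <- sample.int(ncol(im) - patch + 1L, 1L)
    arr[, , i] <- im[r0:(r0 + patch - 1L), c0:(c0 + patch - 1L)]
    meta$image[i] <- j; meta$row[i] <- r0; meta$col[i] <- c0
  }
  structure(list(patches = arr, meta = meta, patch = patch),
            class = "patch_set")
}

#' Stack a patch set into a training matrix
#' @param ps a `patch_set`
#' @return (patch^2, count) matrix of vectorised patches
#' @export
patches_to_matrix <- function(ps) {
  d <- dim(ps$patches)
  matrix(ps$patches, d[1L] * d[2L], d[3L])
}

#' BT.601 luminance of an RGB image
#'
#' `0.299 R + 0.587 G + 0.114 B` on an (H, W, 3) array with values in [0, 1].
#'
#' @param rgb (H, W, 3) array
#' @return H x W matrix
#' @export
to_luminance <- function(rgb) {
  d <- dim(rgb)
  if (length(d) != 3L || d[3L] != 3L) stop("expected an (H, W, 3) array")
  0.299 * rgb[, , 1L] + 0.587 * rgb[, , 2L] + 0.114 * rgb[, , 3L]
}

#' Read a grayscale image from PNG, TIFF or PGM
#'
#' RGB inputs are converted to luminance; alpha channels are dropped.
#' Intensities are returned in [0, 1].
#'
#' @param path file path; the format is chosen by extension
#' @return H x W matrix
#' @export
read_grayscale <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = {
      if (!requireNamespace("png", quietly = TRUE)) stop("package `png` required")
      png::readPNG(path)
    },
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) stop("package `tiff` required")
      tiff::readTIFF(path)
    },
    pgm = return(.read_pgm(path)),
    stop(sprintf("unsupported image format: %s", ext)))
  if (length(dim(img)) == 3L) {
    if (dim(img)[3L] >= 3L) img <- to_luminance(img[, , 1:3, drop = FALSE])
    else img <- img[, , 1L]
  }
  img
}

.read_pgm <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  raw_all <- readBin(con, "raw", file.size(path))
  txt <- rawToChar(raw_all[1:min(200L, length(raw_all))])
  magic <- substr(txt, 1, 2)
  if (!magic %in% c("P2", "P5")) stop("not a PGM file")
  # tokenize header, skipping comments
  hdr_tokens <- c(); pos <- 3L; tok <- ""
  while (length(hdr_tokens) < 3L && pos <= length(raw_all)) {
    ch <- rawToChar(raw_all[pos]); pos <- pos + 1L
    if (ch == "#") { while (pos <= length(raw_all) &&
                            rawToChar(raw_all[pos]) != "\n") pos <- pos + 1L }
    else if (grepl("[0-9]", ch)) tok <- paste0(tok, ch)
    else if (nzchar(tok)) { hdr_tokens <- c(hdr_tokens, tok); tok <- "" }
  }
  W <- as.integer(hdr_tokens[1]); H <- as.integer(hdr_tokens[2])
  maxv <- as.integer(hdr_tokens[3])
  if (magic == "P5") {
    vals <- as.integer(raw_all[pos:(pos + H * W - 1L)])
  } else {
    body <- rawToChar(raw_all[pos:length(raw_all)])
    vals <- as.integer(strsplit(trimws(body), "\\s+")[[1]])[seq_len(H * W)]
  }
  t(matrix(vals / maxv, W, H))   # PGM stores row-major
}

#' Write a manifest describing a generated fixture set
#'
#' Records counts, seeds and content checksums so generated inputs are
#' auditable; written as JSON next to the data.
#'
#' @param path output path for the manifest (`.json`)
#' @param ps a `patch_set` or list of phantom matrices
#' @param seed the seed the set was generated with
#' @param note free-text description
#' @export
write_fixture_manifest <- function(path, ps, seed, note = "") {
  if (inherits(ps, "patch_set")) {
    dat <- ps$patches
    info <- list(kind = "patch_set", count = dim(dat)[3L],
                 patch = ps$patch)
  } else {
    dat <- simplify2array(ps)
    info <- list(kind = "phantom_set", count = length(ps),
                 size = dim(ps[[1L]]))
  }
  info$seed <- seed
  info$note <- note
  info$checksum <- list(sum = sum(dat), sumsq = sum(dat^2),
                        min = min(dat), max = max(dat))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(info, path, auto_unbox = TRUE, digits = NA)
  } else {
    writeLines(utils::capture.output(utils::str(info)), path)
  }
  invisible(path)
}
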