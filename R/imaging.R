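# Binarization operators for studio leaf / tiller photographs.
#
# Images are numeric arrays indexed [row j, column i(, channel)], matching
# png::readPNG. Values may be 0..1 or 0..255; the graying operator preserves
# the input scale and the thresholding operators normalize internally.

#' Read a plant photograph
#'
#' Thin wrapper over `EBImage::readImage` (PNG/TIFF/JPEG) returning a
#' `[row, col, channel]` array.
#'
#' @param path image file.
#' @return numeric array, `[j, i]` for grayscale or `[j, i, channel]`.
#' @export
read_plant_image <- function(path) {
  img <- EBImage::imageData(EBImage::readImage(path))
  # EBImage stores [x, y(, c)]; transpose to [row, col(, c)]
  if (length(dim(img)) == 2L) t(img) else aperm(img, c(2L, 1L, 3L))
}

#' Excess-green graying of a plant photograph
#'
#' `Gray = G - R/3 - B/3`, clamped at zero: green plant tissue scores high,
#' neutral background (where R = G = B) scores G/3, and strongly non-green
#' pixels are suppressed to 0.
#'
#' @param rgb numeric array `[row, col, 3]` (extra channels beyond the first
#'   three, e.g. alpha, are ignored).
#' @return numeric matrix `[row, col]` on the input scale.
#' @export
gray_plant <- function(rgb) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3] < 3L)
    stopf("gray_plant needs a 3-channel [row, col, channel] array")
  g <- pmax(rgb[, , 2] - rgb[, , 1] / 3 - rgb[, , 3] / 3, 0)
  dim(g) <- dim(rgb)[1:2]
  g
}

# normalize a gray image to [0, 1] for Otsu (0..255 inputs are scaled down)
norm_gray <- function(gray) {
  m <- max(gray)
  if (m > 1) gray / 255 else gray
}

# box mean filter by shift-summation; edge pixels average the in-image part.
# 'size' 3 centres the window; 'size' 2 uses the top-left anchored window.
box_mean <- function(m, size) {
  offs <- if (size == 3L) -1:1 else 0:1
  acc <- matrix(0, nrow(m), ncol(m))
  cnt <- matrix(0, nrow(m), ncol(m))
  nr <- nrow(m); nc <- ncol(m)
  for (dj in offs) for (di in offs) {
    js <- seq_len(nr) + dj; is <- seq_len(nc) + di
    ok_j <- js >= 1 & js <= nr; ok_i <- is >= 1 & is <= nc
    acc[ok_j, ok_i] <- acc[ok_j, ok_i] + m[js[ok_j], is[ok_i]]
    cnt[ok_j, ok_i] <- cnt[ok_j, ok_i] + 1
  }
  acc / cnt
}

#' Binarize a leaf photograph
#'
#' Global Otsu threshold on the gray image, then a 3x3 average filter on the
#' binary image, re-thresholded at 0.5 (the filter output is fractional).
#'
#' @param gray numeric gray matrix (from [gray_plant()]).
#' @return logical foreground mask `[row, col]`. A constant input yields an
#'   empty mask with a warning.
#' @export
binarize_leaf <- function(gray) {
  g <- norm_gray(gray)
  if (diff(range(g)) < 1e-12) {
    warning("constant image: returning an empty mask")
    return(matrix(FALSE, nrow(g), ncol(g)))
  }
  thr <- EBImage::otsu(g, range = c(0, 1))
  bin <- (g > thr) * 1
  box_mean(bin, 3L) >= 0.5
}

# Otsu class-separability (between-class variance / total variance) at a
# given threshold; ~1 for clean bimodal data, well below 1 for unimodal.
otsu_eta <- function(g, thr) {
  tot <- stats::var(as.vector(g))
  if (tot < 1e-12) return(0)
  fg <- g > thr
  w2 <- mean(fg)
  if (w2 == 0 || w2 == 1) return(0)
  m1 <- mean(g[!fg]); m2 <- mean(g[fg])
  w2 * (1 - w2) * (m2 - m1)^2 / tot
}

#' Binarize a tiller photograph with block-adaptive thresholds
#'
#' The tiller spans a large frame, so illumination varies across it. The gray
#' image is partitioned into 16 equal square-ish sub-blocks (a 4x4 grid; the
#' image is edge-padded to a multiple of 4 and cropped back), each block is
#' thresholded by Otsu's method, and the binary image is smoothed by a 2x2
#' average filter re-thresholded at 0.5.
#'
#' A block's own Otsu split is trusted when it looks genuinely bimodal:
#' between-class variance ratio `eta >= eta_strong`, or `eta >= eta_weak`
#' with a foreground fraction no larger than `fg_frac_max` (plant organs are
#' thin; a pure-background block under an illumination ramp splits in half).
#' Untrusted blocks inherit the mean trusted threshold of their block-row
#' (the same illumination level), then the overall trusted mean, then the
#' global Otsu threshold.
#'
#' @param gray numeric gray matrix.
#' @param eta_strong,eta_weak,fg_frac_max block-trust parameters (see above).
#' @return logical foreground mask.
#' @export
binarize_tiller <- function(gray, eta_strong = 0.85, eta_weak = 0.4,
                            fg_frac_max = 0.25) {
  g <- norm_gray(gray)
  if (diff(range(g)) < 1e-12) {
    warning("constant image: returning an empty mask")
    return(matrix(FALSE, nrow(g), ncol(g)))
  }
  nr <- nrow(g); nc <- ncol(g)
  nr4 <- ceiling(nr / 4) * 4; nc4 <- ceiling(nc / 4) * 4
  gp <- g[c(seq_len(nr), rep(nr, nr4 - nr)), c(seq_len(nc), rep(nc, nc4 - nc)), drop = FALSE]
  thr_global <- EBImage::otsu(g, range = c(0, 1))
  rb <- nr4 / 4; cb <- nc4 / 4

  # pass 1: per-block Otsu with a bimodality judgement. A pure-background
  # block under an illumination ramp also shows a high between-class
  # variance ratio, but its Otsu split covers ~half the block; genuine plant
  # blocks split off a small foreground fraction.
  thr <- matrix(NA_real_, 4, 4)
  for (bi in 1:4) for (bj in 1:4) {
    blk <- gp[((bi - 1) * rb + 1):(bi * rb), ((bj - 1) * cb + 1):(bj * cb)]
    if (diff(range(blk)) < 1e-12) next
    t_b <- EBImage::otsu(blk, range = c(0, 1))
    eta <- otsu_eta(blk, t_b)
    fg_frac <- mean(blk > t_b)
    if (eta >= eta_strong || (eta >= eta_weak && fg_frac <= fg_frac_max))
      thr[bi, bj] <- t_b
  }
  # pass 2: blocks without a trusted split inherit the threshold of the
  # trusted blocks in their block-row (same illumination level), falling
  # back to the mean trusted threshold, then to the global Otsu threshold
  fill <- thr
  for (bi in 1:4) for (bj in 1:4) {
    if (!is.na(thr[bi, bj])) next
    fill[bi, bj] <- if (any(!is.na(thr[bi, ]))) mean(thr[bi, ], na.rm = TRUE)
                    else if (any(!is.na(thr))) mean(thr, na.rm = TRUE)
                    else thr_global
  }
  bin <- matrix(0, nr4, nc4)
  for (bi in 1:4) for (bj in 1:4) {
    rows <- ((bi - 1) * rb + 1):(bi * rb)
    cols <- ((bj - 1) * cb + 1):(bj * cb)
    bin[rows, cols] <- (gp[rows, cols] > fill[bi, bj]) * 1
  }
  bin <- bin[seq_len(nr), seq_len(nc), drop = FALSE]
  box_mean(bin, 2L) >= 0.5
}

#' Label connected foreground components
#'
#' @param mask logical mask.
#' @param min_px components smaller than this many pixels are dropped as
#'   noise.
#' @return integer matrix of component labels (0 = background), relabelled
#'   1..k after the size filter.
#' @export
label_components <- function(mask, min_px = 50L) {
  lab <- EBImage::bwlabel(mask * 1)
  if (max(lab) == 0) return(matrix(0L, nrow(mask), ncol(mask)))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_px)
  out <- matrix(0L, nrow(mask), ncol(mask))
  for (k in seq_along(keep)) out[lab == keep[k]] <- k
  out
}

# real-world coordinates of the foreground pixels of a mask
mask_to_real <- function(mask, cal) {
  idx <- which(mask, arr.ind = TRUE)
  pixel_to_real(cal, i = idx[, 2], j = idx[, 1])
}
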