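# Leaf image analysis: from a single-leaf binary mask to the leaf shape
# profile (width along the blade and its 6th-degree polynomial fit).

#' Extract the leaf shape profile from a single-leaf mask
#'
#' The foreground pixels are mapped to real cm coordinates through the
#' calibration, rotated so the leaf vein runs approximately along the
#' abscissa (principal axis of the second-moment matrix), and shifted so the
#' centre of the leaf base sits at the origin. Widths are measured per
#' abscissa bin of one pixel pitch (`max(y) - min(y)` plus a pixel, since a
#' pixel covers its pitch), halved, and fitted by a 6th-degree polynomial.
#'
#' @param mask logical single-leaf mask.
#' @param cal a `calibration_model`.
#' @param base_edge which image edge the leaf base points to before rotation
#'   (`"left"`, `"right"`, `"top"`, `"bottom"`); breaks the principal-axis
#'   sign ambiguity.
#' @param min_px noise threshold for [label_components()].
#' @return a [leaf_shape_profile()] with extra fields `length`, `max_width`
#'   and `area` (cm, cm, cm^2; area by trapezoid over the width samples).
#' @export
extract_leaf_shape <- function(mask, cal, base_edge = "left", min_px = 50L) {
  lab <- label_components(mask, min_px)
  ncomp <- max(lab)
  if (ncomp == 0) stopf("empty mask: no leaf component found")
  if (ncomp > 1)
    stopf("mask has %d components; label the organs first and pass one leaf", ncomp)

  idx <- which(lab == 1L, arr.ind = TRUE)
  real <- pixel_to_real(cal, i = idx[, 2], j = idx[, 1])
  eps <- calibration_pitch(cal, i = mean(idx[, 2]), j = mean(idx[, 1]))

  pc <- stats::prcomp(cbind(real$x, real$y), center = TRUE, scale. = FALSE)
  X <- pc$x[, 1]; Y <- pc$x[, 2]

  # orient the abscissa so the designated base edge maps to small X
  q <- stats::quantile(X, c(0.05, 0.95))
  lo <- X <= q[1]; hi <- X >= q[2]
  edge_coord <- switch(base_edge,
    left = idx[, 2], right = -idx[, 2], top = idx[, 1], bottom = -idx[, 1],
    stopf("unknown base_edge '%s'", base_edge))
  if (mean(edge_coord[lo]) > mean(edge_coord[hi])) { X <- -X; Y <- -Y }

  X <- X - min(X)
  bin <- floor(X / eps)
  wtab <- tapply(Y, bin, function(y) c(max(y), min(y)))
  bins <- as.integer(names(wtab))
  ymax <- vapply(wtab, `[`, 0, 1); ymin <- vapply(wtab, `[`, 0, 2)
  o <- order(bins)
  bins <- bins[o]; ymax <- ymax[o]; ymin <- ymin[o]

  Y <- Y - (ymax[1] + ymin[1]) / 2         # centre of the leaf base -> 0
  l <- (bins + 0.5) * eps
  width <- ymax - ymin + eps
  leaf_len <- max(X) + eps

  samples <- data.frame(l = l, halfwidth = width / 2)
  s <- l / leaf_len                         # scaled abscissa for conditioning
  deg <- min(6L, length(unique(s)) - 1L)
  if (deg < 1L) stopf("too few width bins (%d) to fit a shape polynomial", length(l))
  fit <- stats::lm(samples$halfwidth ~ poly(s, deg, raw = TRUE))
  cf <- c(stats::coef(fit), rep(0, 6L - deg))
  cf[is.na(cf)] <- 0
  coef_raw <- cf / leaf_len^(0:6)

  area <- sum(diff(l) * (width[-1] + width[-length(width)]) / 2)
  out <- leaf_shape_profile(samples, coef_raw, tip_tol = Inf)
  out$length <- leaf_len
  out$max_width <- max(width)
  out$area <- area
  out$fit_rmse <- sqrt(mean(stats::residuals(fit)^2))
  out
}

#' Analyze a leaf photograph end to end
#'
#' Gray (excess green), binarize ([binarize_leaf()]) and extract the shape
#' profile.
#'
#' @param img RGB array `[row, col, 3]` or a path readable by
#'   [read_plant_image()].
#' @param cal a `calibration_model`.
#' @param ... passed to [extract_leaf_shape()].
#' @return see [extract_leaf_shape()].
#' @export
analyze_leaf_image <- function(img, cal, ...) {
  if (is.character(img)) img <- read_plant_image(img)
  mask <- binarize_leaf(gray_plant(img))
  extract_leaf_shape(mask, cal, ...)
}
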