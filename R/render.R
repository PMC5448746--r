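# Raster renderers: synthetic leaf and tiller photographs with known ground
# truth, used to exercise the calibration and image-analysis operators end to
# end (render-and-recover).

# RGB canvas filled with a background colour
blank_canvas <- function(H, W, bg) {
  img <- array(0, c(H, W, 3))
  for (ch in 1:3) img[, , ch] <- bg[ch]
  img
}

paint_rgb <- function(img, mask, col) {
  for (ch in 1:3) {
    m <- img[, , ch]
    m[mask] <- col[ch]
    img[, , ch] <- m
  }
  img
}

# top-to-bottom brightness ramp on the green channel; at full amplitude the
# bottom background is brighter than the top foreground, so no global
# threshold can separate them
apply_gradient <- function(img, mask, g) {
  H <- nrow(mask)
  jfrac <- (row(mask) - 1) / max(H - 1, 1)
  G <- 0.05 + 0.55 * g * jfrac
  G[mask] <- 0.50 + 0.45 * g * jfrac[mask]
  img[, , 1] <- 0
  img[, , 2] <- G
  img[, , 3] <- 0
  img
}

#' Render a synthetic leaf photograph
#'
#' The blade is laid flat along the abscissa (as on the leaf image bench):
#' foreground where `0 <= x <= L` and `|y| <= halfwidth(x)`. Each pixel is
#' classified through the true pixel-to-real map, so the rendered image is
#' consistent with the returned calibration even under quadratic distortion.
#'
#' @param leaf a [leaf_record()] (its shape profile and midrib length are
#'   used).
#' @param spec a [render_spec()]; if `spec$distortion` is set it is the true
#'   map and `image_size` must be given.
#' @param image_size optional `c(rows, cols)`; computed from the blade
#'   dimensions for the scale-only case.
#' @return list with `image` (`[row, col, 3]`), `cal` (the true
#'   `calibration_model`) and `mask` (the ground-truth foreground). A blade
#'   narrower than a pixel yields an (almost) empty mask flagged by attribute
#'   `degenerate = TRUE` with a warning.
#' @export
render_leaf_image <- function(leaf, spec = render_spec(), image_size = NULL) {
  L <- leaf$midrib2d$length
  cpp <- spec$cm_per_px
  hwmax <- max(shape_halfwidth(leaf$shape, seq(0, L, length.out = 200)))
  m <- spec$margin
  degenerate <- hwmax < cpp / 2
  if (degenerate) warning("blade narrower than one pixel: rendering a degenerate mask")

  if (is.null(spec$distortion)) {
    W <- ceiling((L + 2 * m) / cpp)
    H <- ceiling(2 * (hwmax + m) / cpp)
    if (!is.null(image_size)) {
      if (image_size[1] < H || image_size[2] < W)
        stopf("leaf larger than the canvas (%d x %d px needed)", H, W)
      H <- image_size[1]; W <- image_size[2]
    }
    cal <- calibration_model(c(0, 0, 0, cpp, 0, -(m + 0.5 * cpp),
                               0, 0, 0, 0, -cpp, (H + 0.5) * cpp - (hwmax + m)))
    x <- pixel_to_real(cal, seq_len(W), rep(1, W))$x
    y <- pixel_to_real(cal, rep(1, H), seq_len(H))$y
    # 3x3 supersampled coverage for anti-aliased edges
    cov <- matrix(0, H, W)
    for (du in (-1:1) / 3) for (dv in (-1:1) / 3) {
      xs <- x + du * cpp
      hwx <- shape_halfwidth(leaf$shape, xs)
      hwx[xs < 0 | xs > L] <- -1
      cov <- cov + outer(abs(y + dv * cpp), hwx, `<=`)
    }
    cov <- cov / 9
    mask <- cov >= 0.5
  } else {
    if (is.null(image_size))
      stopf("image_size is required when rendering through a distortion map")
    H <- image_size[1]; W <- image_size[2]
    cal <- spec$distortion
    I <- matrix(rep(seq_len(W), each = H), H, W)
    J <- matrix(rep(seq_len(H), W), H, W)
    real <- pixel_to_real(cal, as.vector(I), as.vector(J))
    X <- matrix(real$x, H, W); Y <- matrix(real$y, H, W)
    HW <- matrix(shape_halfwidth(leaf$shape, as.vector(X)), H, W)
    mask <- X >= 0 & X <= L & abs(Y) <= HW
    cov <- mask * 1
  }
  img <- blank_canvas(H, W, spec$bg)
  for (ch in 1:3) img[, , ch] <- spec$bg[ch] + cov * (spec$fg[ch] - spec$bg[ch])
  if (spec$gradient > 0) img <- apply_gradient(img, mask, spec$gradient)
  out <- list(image = img, cal = cal, mask = mask)
  attr(out, "degenerate") <- degenerate
  out
}

#' Render a synthetic tiller photograph
#'
#' The stem stands vertically from the frame origin; each leaf is painted as
#' a tube around its 2D midrib curve (node at the stem surface, radius equal
#' to the local half-width), on alternating sides of the stem so the organs
#' stay separable. Rendering uses a pure scale calibration; an optional
#' illumination gradient exercises the block-adaptive binarization.
#'
#' @param tl a [tiller()].
#' @param spec a [render_spec()] (`distortion` is ignored here).
#' @param occlusion_max warn when more than this fraction of leaf pixels is
#'   painted by two leaves.
#' @return list with `image`, `cal`, `mask` (all foreground) and `truth`:
#'   `stem` mask, list of per-leaf masks bottom-up, per-leaf `sides`, and
#'   `core` - the certainly-covered foreground (pixel centres at least half a
#'   pixel inside an organ), the fair reference for recall checks since the
#'   half-pixel boundary band is genuinely ambiguous at the raster scale.
#' @export
render_tiller_image <- function(tl, spec = render_spec(cm_per_px = 0.04),
                                occlusion_max = 0.05) {
  cpp <- spec$cm_per_px
  m <- spec$margin
  st <- tl$stem
  rad_at <- stem_radius_at(st)
  nl <- length(tl$leaves)
  sides <- rep(c(1, -1), length.out = nl)

  pts <- list()
  for (li in seq_len(nl)) {
    lf <- tl$leaves[[li]]
    lg <- seq(0, lf$midrib2d$length, by = cpp / 2)
    m2 <- midrib2d_eval(lf$midrib2d, lg)
    pts[[li]] <- data.frame(x = sides[li] * (lf$node_image[1] + m2$x),
                            y = lf$node_image[2] + m2$y,
                            r = shape_halfwidth(lf$shape, lg))
  }
  allx <- c(0, unlist(lapply(pts, function(p) range(p$x))),
            -max(st$radius_profile$r), max(st$radius_profile$r))
  ally <- c(0, st$length, unlist(lapply(pts, function(p) range(p$y))))
  xmin <- min(allx) - m; xmax <- max(allx) + m
  ymax <- max(ally) + m
  W <- ceiling((xmax - xmin) / cpp)
  H <- ceiling((ymax + m) / cpp)
  cal <- calibration_model(c(0, 0, 0, cpp, 0, xmin - 0.5 * cpp,
                             0, 0, 0, 0, -cpp, (H + 0.5) * cpp - m))
  xc <- pixel_to_real(cal, seq_len(W), rep(1, W))$x
  yr <- pixel_to_real(cal, rep(1, H), seq_len(H))$y

  sr <- rad_at(clamp(yr, 0, st$length))
  sr[yr < 0 | yr > st$length] <- -1
  stem_mask <- outer(sr, abs(xc), `>=`)
  stem_core <- outer(sr - cpp / 2, abs(xc), `>=`)   # certainly-covered pixels

  to_px <- function(x, y) {
    co <- cal$coef
    list(i = (x - co[["f1"]]) / co[["d1"]], j = (y - co[["f2"]]) / co[["e2"]])
  }
  paint_leaf <- function(p, shrink = 0) {
    mk <- matrix(FALSE, H, W)
    px <- to_px(p$x, p$y)
    rp <- p$r / cpp - shrink
    for (k in seq_len(nrow(p))) {     # inline disc painting (hot loop)
      r <- rp[k]
      if (r <= 0.35) next
      cj <- px$j[k]; ci <- px$i[k]
      j0 <- max(1L, floor(cj - r)); j1 <- min(H, ceiling(cj + r))
      i0 <- max(1L, floor(ci - r)); i1 <- min(W, ceiling(ci + r))
      if (j0 > j1 || i0 > i1) next
      js <- j0:j1; is <- i0:i1
      sub <- outer((js - cj)^2, (is - ci)^2, `+`) <= r^2
      mk[js, is] <- mk[js, is] | sub
    }
    mk
  }
  leaf_masks <- lapply(pts, paint_leaf)
  core <- Reduce(`|`, lapply(pts, paint_leaf, shrink = 0.5), stem_core)
  if (nl > 1) {
    cnt <- Reduce(`+`, lapply(leaf_masks, function(mm) mm * 1L))
    tot <- sum(cnt > 0)
    if (tot > 0 && sum(cnt > 1) / tot > occlusion_max)
      warning(sprintf("leaves overlap on %.1f%% of leaf pixels; extraction is not guaranteed",
                      100 * sum(cnt > 1) / tot))
  }
  mask <- Reduce(`|`, leaf_masks, stem_mask)
  img <- paint_rgb(blank_canvas(H, W, spec$bg), mask, spec$fg)
  if (spec$gradient > 0) img <- apply_gradient(img, mask, spec$gradient)
  list(image = img, cal = cal, mask = mask,
       truth = list(stem = stem_mask, leaves = leaf_masks, sides = sides,
                    core = core))
}
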