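# Tiller image analysis: organ separation, stem length/radius profile, leaf
# node and midrib curve extraction.

#' Separate a tiller mask into stem and leaves
#'
#' The stem corridor is a robust vertical line (M-estimator fit of column on
#' row, through the per-row medians of the foreground columns) of half-width
#' equal to the median stem half-width. Pixels inside the corridor form the
#' stem; each remaining connected component of at least `min_px` pixels is one
#' leaf, labelled in order of increasing node height (bottom leaf first).
#'
#' @param mask logical tiller mask, stem approximately vertical.
#' @param min_px noise threshold for leaf components.
#' @return an object of class `organ_set`: `stem` and `leaves` (logical
#'   masks), plus the fitted `corridor` (`intercept`, `slope` of column on
#'   row, `halfwidth_px`).
#' @export
separate_tiller_organs <- function(mask, min_px = 50L) {
  if (!any(mask)) stopf("empty tiller mask")
  # coarse stem locator: the stem is the structure filling the most rows, so
  # its columns dominate the column occupancy histogram
  cs <- colSums(mask)
  k <- min(15L, ncol(mask))
  csm <- as.numeric(stats::filter(cs, rep(1 / k, k), sides = 2))
  csm[is.na(csm)] <- 0
  c0 <- which.max(csm)
  if (!any(mask[, c0])) c0 <- which.max(cs)   # smoothing overshot the stem
  # rough stem width from the run lengths through c0
  runs <- vapply(which(mask[, c0]), function(j) {
    cols <- which(mask[j, ])
    grp <- cumsum(c(1, diff(cols) != 1))
    sum(grp == grp[match(c0, cols)])
  }, 0)
  w0 <- max(stats::median(runs), 2, na.rm = TRUE)
  win <- max(5 * w0, 20)
  # per-row medians restricted to the locator window, then a robust line
  rows_fg <- which(rowSums(mask[, pmax(1, c0 - win):pmin(ncol(mask), c0 + win),
                                drop = FALSE]) > 0)
  if (length(rows_fg) < 10)
    stopf("no vertical stem corridor found (too few foreground rows)")
  med_col <- vapply(rows_fg, function(j) {
    cols <- which(mask[j, ])
    stats::median(cols[abs(cols - c0) <= win])
  }, 0)
  fit <- suppressWarnings(MASS::rlm(med_col ~ rows_fg, maxit = 50))
  pred_col <- function(j) stats::coef(fit)[1] + stats::coef(fit)[2] * j

  # per-row half-width of the contiguous run under the fitted line
  halfw <- rep(NA_real_, length(rows_fg))
  for (k in seq_along(rows_fg)) {
    j <- rows_fg[k]
    cols <- which(mask[j, ])
    grp <- cumsum(c(1, diff(cols) != 1))   # contiguous runs of columns
    pc <- pred_col(j)
    for (g in unique(grp)) {
      cg <- cols[grp == g]
      if (pc >= cg[1] - 1 && pc <= cg[length(cg)] + 1) {
        halfw[k] <- length(cg) / 2
        break
      }
    }
  }
  if (all(is.na(halfw)))
    stopf("no vertical stem corridor found (fitted line misses the mask)")
  # corridor width = 2 x the median stem half-width, so the wider stem base
  # stays inside the corridor despite the taper
  w <- 2 * stats::median(halfw, na.rm = TRUE)

  jj <- row(mask); ii <- col(mask)
  corridor <- abs(ii - pred_col(jj)) <= w
  stem <- mask & corridor
  # keep only the connected stem body: leaves crossing the corridor above the
  # stem tip would otherwise inflate the stem
  slab <- EBImage::bwlabel(stem * 1)
  if (max(slab) > 1) {
    sizes <- tabulate(slab[slab > 0])
    stem <- slab == which.max(sizes)
  }
  rest <- mask & !stem & !corridor
  lab <- label_components(rest, min_px)
  nlv <- max(lab)
  leaves <- vector("list", nlv)
  node_row <- numeric(nlv)
  for (k in seq_len(nlv)) {
    leaves[[k]] <- lab == k
    pix <- which(lab == k, arr.ind = TRUE)
    d <- abs(pix[, 2] - pred_col(pix[, 1]))
    node_row[k] <- pix[which.min(d), 1]
  }
  # larger row number = lower in the image = lower on the stem
  ord <- order(-node_row)
  structure(list(stem = stem, leaves = leaves[ord],
                 corridor = list(intercept = unname(stats::coef(fit)[1]),
                                 slope = unname(stats::coef(fit)[2]),
                                 halfwidth_px = w)),
            class = "organ_set")
}

# Shared tiller frame: rotation + shift taking real coordinates into a frame
# with the stem vertical and the centre of the stem base at the origin.
tiller_frame <- function(stem_mask, cal) {
  if (!any(stem_mask)) stopf("empty stem mask")
  real <- mask_to_real(stem_mask, cal)
  eps <- calibration_pitch(cal)
  pc <- stats::prcomp(cbind(real$x, real$y), center = TRUE, scale. = FALSE)
  R <- pc$rotation                     # columns: principal axes
  # vertical = first PC, oriented upward (along +y of the real frame)
  vert <- R[, 1]; if (vert[2] < 0) vert <- -vert
  horiz <- c(-vert[2], vert[1])        # right-handed
  ctr <- pc$center
  tf <- function(xy) {
    dx <- xy$x - ctr[1]; dy <- xy$y - ctr[2]
    data.frame(u = dx * horiz[1] + dy * horiz[2],
               v = dx * vert[1] + dy * vert[2])
  }
  st <- tf(real)
  base_v <- min(st$v)
  base_u <- mean(range(st$u[st$v <= base_v + 3 * eps]))
  function(xy) {
    out <- tf(xy)
    out$u <- out$u - base_u
    out$v <- out$v - base_v
    out
  }
}

#' Extract stem length and radius profile from a stem mask
#'
#' In the tiller frame (stem vertical, base centre at the origin) the stem
#' length is the maximum height and the radius at height z is half the
#' horizontal extent of the pixels in the one-pixel-pitch height bin around z
#' (plus one pitch, a pixel covering its pitch; a single-pixel column thus has
#' radius pitch/2).
#'
#' @param stem_mask logical stem mask.
#' @param cal a `calibration_model`.
#' @param frame optional frame function from an enclosing tiller analysis;
#'   computed from the stem mask itself if missing.
#' @return a [stem_record()] with `length` and `radius_profile` populated.
#' @export
extract_stem <- function(stem_mask, cal, frame = NULL) {
  if (!any(stem_mask)) stopf("empty stem mask")
  if (is.null(frame)) frame <- tiller_frame(stem_mask, cal)
  eps <- calibration_pitch(cal)
  st <- frame(mask_to_real(stem_mask, cal))
  S_l <- max(st$v) - min(st$v) + eps
  bin <- floor((st$v - min(st$v)) / eps)
  agg <- tapply(st$u, bin, function(u) (max(u) - min(u) + eps) / 2)
  z <- (as.integer(names(agg)) + 0.5) * eps
  o <- order(z)
  stem_record(S_l, data.frame(z = z[o], r = unname(agg)[o]))
}

#' Extract a leaf's node and midrib curve from a tiller-frame leaf mask
#'
#' The node is the leaf point nearest the stem axis (minimum |u|, height
#' averaged over the pixels within one pitch of it). The midrib is the mean
#' height per one-pitch u-bin, shifted to the node origin; arc length `l`
#' accumulates along the binned polyline and two quadratics `x(l)`, `y(l)`
#' are fitted. Leaves extending to negative u are mirrored so the radial
#' coordinate is non-negative (the measured azimuth carries the direction).
#'
#' @param leaf_mask logical mask of one leaf.
#' @param cal a `calibration_model`.
#' @param frame tiller frame function (see [extract_stem()]); mandatory here
#'   since the leaf mask alone does not define the stem frame.
#' @return list with `node_image` (`c(x, y)` in the tiller frame, x >= 0) and
#'   `midrib2d` (a [midrib_curve2d()]). If the per-bin height spread suggests
#'   a multivalued (strongly drooping) midrib the result carries attribute
#'   `multivalued = TRUE` and a warning is issued.
#' @export
extract_leaf_midrib <- function(leaf_mask, cal, frame) {
  if (!any(leaf_mask)) stopf("empty leaf mask")
  eps <- calibration_pitch(cal)
  lp <- frame(mask_to_real(leaf_mask, cal))
  if (mean(lp$u) < 0) lp$u <- -lp$u
  x_n <- min(lp$u)
  y_n <- mean(lp$v[lp$u <= x_n + eps])

  bin <- floor((lp$u - x_n) / eps)
  ymean <- tapply(lp$v, bin, mean)
  yspread <- tapply(lp$v, bin, function(v) diff(range(v)))
  bins <- as.integer(names(ymean))
  o <- order(bins)
  xs <- x_n + (bins[o] + 0.5) * eps
  ys <- unname(ymean[o])
  if (length(xs) < 3) stopf("fewer than 3 midrib bins; cannot fit the midrib curve")

  multivalued <- stats::quantile(yspread, 0.95) > 4 * stats::median(yspread) + 4 * eps
  if (multivalued)
    warning("leaf midrib looks multivalued along u (strong droop); fit covers the binned means only")

  xr <- xs - x_n; yr <- ys - y_n
  l <- cumsum(c(sqrt(xr[1]^2 + yr[1]^2),
                sqrt(diff(xr)^2 + diff(yr)^2)))
  fx <- stats::lm(xr ~ poly(l, 2, raw = TRUE))
  fy <- stats::lm(yr ~ poly(l, 2, raw = TRUE))
  cx <- rev(stats::coef(fx)); cy <- rev(stats::coef(fy))  # a, b, c order
  fit <- c(cx[1], cx[2], cx[3], cy[1], cy[2], cy[3])

  # arc length of the fitted curve over [0, max(l)]
  lg <- seq(0, max(l), length.out = 201)
  sp <- sqrt((2 * fit[1] * lg + fit[2])^2 + (2 * fit[4] * lg + fit[5])^2)
  arc <- sum((sp[-1] + sp[-201]) / 2 * diff(lg))

  mid <- midrib_curve2d(fit, arc, points = data.frame(l = l, x = xr, y = yr),
                        origin_tol = max(0.35, 3 * eps))
  out <- list(node_image = c(x_n, y_n), midrib2d = mid)
  attr(out, "multivalued") <- multivalued
  out
}

#' Base and dropping angles of a midrib curve
#'
#' The base angle is the angle between the midrib tangent at the node and the
#' stem (vertical) axis; the dropping angle is the total bend between the base
#' tangent and the tangent at the tip.
#'
#' When the curve carries its binned observation points, the endpoint
#' tangents are estimated from local quadratic fits over a `gauge`-long
#' window at each end: the global quadratic is a least-squares compromise
#' along the whole blade and its endpoint derivatives are biased on strongly
#' bent leaves, whereas the local tangent is a geometric invariant.
#'
#' @param midrib2d a [midrib_curve2d()].
#' @param gauge window length (cm) for the local tangent fits; default
#'   `min(6, 0.3 * length)`.
#' @return `c(base, dropping)` in radians.
#' @export
leaf_angles <- function(midrib2d, gauge = NULL) {
  ang <- function(a, b) {
    cb <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
    acos(clamp(cb, -1, 1))
  }
  pts <- midrib2d$points
  if (!is.null(pts) && !is.null(pts$l) && nrow(pts) >= 8) {
    gauge <- gauge %||% min(6, 0.3 * midrib2d$length)
    lmax <- max(pts$l)
    # the first few millimetres next to the stem-corridor cut mix blade-tube
    # pixels from a range of arc positions; keep them out of the base fit and
    # read the tangent at the first clean point (extrapolating along the
    # local quadratic amplifies its curvature noise)
    skip <- min(0.4, gauge / 4)
    selb <- pts$l >= min(pts$l) + skip & pts$l <= min(pts$l) + skip + gauge
    selt <- pts$l >= lmax - gauge
    if (sum(selb) >= 4 && sum(selt) >= 4) {
      lb <- pts$l[selb]
      fb <- stats::lm(cbind(pts$x, pts$y)[selb, ] ~ poly(lb, 2, raw = TRUE))
      t0 <- stats::coef(fb)[2, ]        # derivative at the node, l = 0
      ft <- stats::lm(cbind(pts$x, pts$y)[selt, ] ~ poly(pts$l[selt] - lmax, 2, raw = TRUE))
      t1 <- stats::coef(ft)[2, ]
      return(c(base = unname(atan2(abs(t0[1]), t0[2])),
               dropping = unname(ang(t0, t1))))
    }
  }
  f <- midrib2d$fit
  t0 <- c(f["b1"], f["b2"])
  t1 <- c(2 * f["a1"] * midrib2d$length + f["b1"],
          2 * f["a2"] * midrib2d$length + f["b2"])
  c(base = unname(atan2(abs(t0[1]), t0[2])), dropping = unname(ang(t0, t1)))
}

#' Analyze a tiller photograph end to end
#'
#' Gray, block-adaptive binarization, organ separation, stem extraction and
#' per-leaf node/midrib extraction, all in a shared tiller frame.
#'
#' @param img RGB array or image path.
#' @param cal a `calibration_model`.
#' @param min_px noise threshold for organ components.
#' @return list with `stem` (a [stem_record()]), `leaves` (each a list with
#'   `node_image`, `midrib2d`, `angles`) ordered bottom-up, and the
#'   `organ_set`.
#' @export
analyze_tiller_image <- function(img, cal, min_px = 50L) {
  if (is.character(img)) img <- read_plant_image(img)
  mask <- binarize_tiller(gray_plant(img))
  organs <- separate_tiller_organs(mask, min_px)
  frame <- tiller_frame(organs$stem, cal)
  stem <- extract_stem(organs$stem, cal, frame)
  leaves <- lapply(organs$leaves, function(lm) {
    r <- extract_leaf_midrib(lm, cal, frame)
    r$angles <- leaf_angles(r$midrib2d)
    r
  })
  list(stem = stem, leaves = leaves, organs = organs)
}
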