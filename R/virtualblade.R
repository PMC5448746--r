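# The virtual blade (virtual clipping) engine.
#
# Leaves are divided into fnum fragments along the midrib; each fragment
# carries its trapezoid area, the midpoint of its midrib segment, its azimuth
# and inclination. Parallel blade surfaces (horizontal planes, concentric
# cylinders around the hill axis, or a voxel grid) partition space into
# intervals; a fragment belongs wholly to the interval of its midpoint - the
# deliberate approximation that replaces exact surface-intersection clipping.

#' Divide one leaf into fragments
#'
#' Fragments live on an equal-l grid over the fitted midrib length. The area
#' of fragment i is the trapezoid `(l[i+1]-l[i]) * (W(l[i+1]) + W(l[i])) / 2`
#' with `W = 2 * halfwidth`; azimuth and inclination come from the 3D midrib
#' segment direction (four-quadrant azimuth; inclination
#' `asin(|dz| / |d|) in [0, pi/2]`).
#'
#' @param leaf a reconstructed [leaf_record()] (needs `node3d`).
#' @param fnum number of fragments, >= 1.
#' @param stem the leaf's [stem_record()] (for the stem tilt factor).
#' @return data.frame, one row per fragment: `frag`, `l_lo`, `l_hi`, `area`,
#'   midrib midpoint `mx, my, mz`, `az`, `incl`, and the four corner points
#'   `e{1,2}{x,y,z}_{lo,hi}` used by the voxel mode.
#' @export
fragment_leaf <- function(leaf, fnum, stem) {
  if (!is_scalar_num(fnum) || fnum < 1 || fnum != round(fnum))
    stopf("fnum must be an integer >= 1")
  if (is.null(leaf$node3d))
    stopf("leaf has no node3d; run reconstruct_architecture first")
  lg <- seq(0, leaf$midrib2d$length, length.out = fnum + 1L)
  m3 <- midrib_3d(leaf$midrib2d, leaf$azimuth, leaf$node3d, stem, l = lg)
  p <- venation_normal(m3)
  hw <- shape_halfwidth(leaf$shape, lg)
  W <- 2 * hw
  i <- seq_len(fnum)
  dl <- diff(lg)
  dx <- diff(m3$x); dy <- diff(m3$y); dz <- diff(m3$z)
  seg <- sqrt(dx^2 + dy^2 + dz^2)
  az <- wrap_angle(atan2(dy, dx))            # the four-quadrant table of the
  az[seg == 0] <- 0                          # azimuth formula, closed form
  incl <- ifelse(seg > 0, asin(clamp(abs(dz) / seg, 0, 1)), 0)
  e <- function(sgn, k) {                    # corner coords: k = lo/hi index
    cbind(x = m3$x[k] + sgn * hw[k] * p[1],
          y = m3$y[k] + sgn * hw[k] * p[2],
          z = m3$z[k] + sgn * hw[k] * p[3])
  }
  lo <- i; hi <- i + 1L
  e1l <- e(-1, lo); e2l <- e(1, lo); e1h <- e(-1, hi); e2h <- e(1, hi)
  data.frame(frag = i, l_lo = lg[lo], l_hi = lg[hi],
             area = dl * (W[hi] + W[lo]) / 2,
             mx = (m3$x[lo] + m3$x[hi]) / 2,
             my = (m3$y[lo] + m3$y[hi]) / 2,
             mz = (m3$z[lo] + m3$z[hi]) / 2,
             az = az, incl = incl,
             e1x_lo = e1l[, 1], e1y_lo = e1l[, 2], e1z_lo = e1l[, 3],
             e2x_lo = e2l[, 1], e2y_lo = e2l[, 2], e2z_lo = e2l[, 3],
             e1x_hi = e1h[, 1], e1y_hi = e1h[, 2], e1z_hi = e1h[, 3],
             e2x_hi = e2h[, 1], e2y_hi = e2h[, 2], e2z_hi = e2h[, 3])
}

#' Fragment every leaf of an architecture
#'
#' @param arch a reconstructed [digital_architecture()].
#' @param fnum fragments per leaf.
#' @return data.frame of all fragments with hill/tiller/leaf identifiers,
#'   hill origins `ox, oy`, and `r_hill` - the horizontal distance of the
#'   fragment midpoint from its hill axis.
#' @export
fragment_canopy <- function(arch, fnum = 100L) {
  out <- list()
  for (h in arch$hills) {
    for (ti in seq_along(h$tillers)) {
      tl <- h$tillers[[ti]]
      for (li in seq_along(tl$leaves)) {
        fr <- fragment_leaf(tl$leaves[[li]], fnum, tl$stem)
        fr <- cbind(data.frame(hill_rn = h$position$rn, hill_cn = h$position$cn,
                               ox = h$origin[1], oy = h$origin[2],
                               tiller = ti, leaf = li), fr)
        out[[length(out) + 1L]] <- fr
      }
    }
  }
  if (!length(out)) {
    fr <- fragment_empty()
  } else {
    fr <- do.call(rbind, out)
  }
  fr$r_hill <- sqrt(fr$mx^2 + fr$my^2)
  fr
}

fragment_empty <- function() {
  d <- data.frame(hill_rn = integer(), hill_cn = integer(), ox = numeric(),
                  oy = numeric(), tiller = integer(), leaf = integer(),
                  frag = integer(), l_lo = numeric(), l_hi = numeric(),
                  area = numeric(), mx = numeric(), my = numeric(),
                  mz = numeric(), az = numeric(), incl = numeric())
  for (nm in c(t(outer(c("e1x", "e1y", "e1z", "e2x", "e2y", "e2z"),
                       c("_lo", "_hi"), paste0))))
    d[[nm]] <- numeric()
  d
}

#' Interval index between horizontal blade sections
#'
#' `floor(((z1 + z2) / 2) / Dns) + 1`: the fragment goes wholly to the
#' interval containing the midpoint of its midrib segment; boundary values
#' fall upward.
#'
#' @param z1,z2 heights of the fragment's midrib endpoints (cm).
#' @param Dns section spacing (cm), > 0.
#' @return integer interval indices (1-based from z = 0).
#' @export
assign_planar_z <- function(z1, z2, Dns) {
  if (Dns <= 0) stopf("Dns must be > 0")
  # rounding guard: boundary values fall upward even under fp noise
  as.integer(floor(round(((z1 + z2) / 2) / Dns, 9)) + 1)
}

#' Interval index between concentric cylindrical blade sections
#'
#' `floor(dist / Dns) + 1` where `dist` is the horizontal distance of the
#' fragment's midrib midpoint from the hill axis.
#'
#' @param dist distances from the hill axis (cm).
#' @param Dns cylinder spacing (cm), > 0.
#' @return integer interval indices.
#' @export
assign_cylindrical <- function(dist, Dns) {
  if (Dns <= 0) stopf("Dns must be > 0")
  as.integer(floor(round(dist / Dns, 9)) + 1)
}

as_fragments <- function(x, fnum) {
  if (inherits(x, "digital_architecture")) fragment_canopy(x, fnum)
  else as.data.frame(x)
}

trait_profile <- function(df, mode, ...) {
  structure(df, class = c("trait_profile", "data.frame"),
            mode = mode, params = list(...))
}

#' Leaf area profile along the vertical axis
#'
#' Sums fragment areas per horizontal interval; the density divides by the
#' slab volume factor `Dns * pm * rs * ps` and the probability density further
#' normalizes by the total area, so
#' `sum(area_pdensity) * Dns * pm * rs * ps == 1` for a nonempty canopy.
#'
#' @param x a reconstructed [digital_architecture()] or a fragment
#'   data.frame from [fragment_canopy()].
#' @param fnum fragments per leaf (used when `x` is an architecture).
#' @param Dns section spacing (cm).
#' @param ctx a [canopy_context()]; defaults to the architecture's own.
#' @return a `trait_profile` data.frame: `interval`, `z_lo`, `z_hi`, `area`
#'   (cm^2), `area_density` (cm^2 leaf per cm^3 of canopy slab per the
#'   printed normalization), `area_pdensity`.
#' @export
area_profile_z <- function(x, fnum = 100L, Dns = 5, ctx = NULL) {
  ctx <- ctx %||% x$context
  fr <- as_fragments(x, fnum)
  if (!nrow(fr)) {
    return(trait_profile(data.frame(interval = 1L, z_lo = 0, z_hi = Dns,
                                    area = 0, area_density = 0, area_pdensity = 0),
                         "planar-z", Dns = Dns, fnum = fnum))
  }
  iv <- assign_planar_z(fr$mz, fr$mz, Dns)   # mz is already the midpoint
  nmax <- max(iv)
  area <- vapply(seq_len(nmax), function(n) sum(fr$area[iv == n]), 0)
  norm <- Dns * ctx$pm * ctx$spec$rs * ctx$spec$ps
  dens <- area / norm
  trait_profile(data.frame(interval = seq_len(nmax),
                           z_lo = (seq_len(nmax) - 1) * Dns,
                           z_hi = seq_len(nmax) * Dns,
                           area = area, area_density = dens,
                           area_pdensity = dens / sum(area)),
                "planar-z", Dns = Dns, fnum = fnum, total_area = sum(area))
}

#' Leaf area profile over the distance to the hill axis
#'
#' As [area_profile_z()] but with concentric cylindrical sections around each
#' hill's axis; the density divides by the ground-plane annulus area
#' `pi * ((n * Dns)^2 - ((n-1) * Dns)^2)` and the number of hills.
#'
#' @inheritParams area_profile_z
#' @return a `trait_profile`: `interval`, `r_lo`, `r_hi`, `area`,
#'   `area_density`.
#' @export
area_profile_radial <- function(x, fnum = 100L, Dns = 5, ctx = NULL) {
  ctx <- ctx %||% x$context
  fr <- as_fragments(x, fnum)
  if (!nrow(fr)) {
    return(trait_profile(data.frame(interval = 1L, r_lo = 0, r_hi = Dns,
                                    area = 0, area_density = 0),
                         "cylindrical", Dns = Dns, fnum = fnum))
  }
  iv <- assign_cylindrical(fr$r_hill, Dns)
  nmax <- max(iv)
  n <- seq_len(nmax)
  area <- vapply(n, function(k) sum(fr$area[iv == k]), 0)
  annulus <- pi * ((n * Dns)^2 - ((n - 1) * Dns)^2)
  trait_profile(data.frame(interval = n, r_lo = (n - 1) * Dns, r_hi = n * Dns,
                           area = area,
                           area_density = area / annulus / ctx$pm),
                "cylindrical", Dns = Dns, fnum = fnum, total_area = sum(area))
}

#' Voxel-grid leaf area distribution
#'
#' Each first-order fragment is further divided width-wise into four strips
#' of area `farea / 4`; strip centres interpolate between the two edge
#' midpoints at cross-width weights 1/8, 3/8, 5/8, 7/8. Voxel x/y indices use
#' the strip centre in canopy (hill-origin-shifted) coordinates; the z index
#' is the planar interval of the midrib midpoint with `Dns = Dz`.
#'
#' @param x architecture or fragment data.frame.
#' @param fnum fragments per leaf.
#' @param Dx,Dy,Dz voxel edge lengths (cm).
#' @return a `trait_profile`: `nx`, `ny`, `nz`, `area`, `area_density`
#'   (`area / (Dx * Dy * Dz)`). Indices can be non-positive for geometry
#'   left/below the block origin.
#' @export
area_voxel <- function(x, fnum = 100L, Dx = 5, Dy = 5, Dz = 5) {
  if (any(c(Dx, Dy, Dz) <= 0)) stopf("voxel spacings must be > 0")
  fr <- as_fragments(x, fnum)
  if (!nrow(fr)) {
    return(trait_profile(data.frame(nx = integer(), ny = integer(),
                                    nz = integer(), area = numeric(),
                                    area_density = numeric()),
                         "voxel", Dx = Dx, Dy = Dy, Dz = Dz, fnum = fnum))
  }
  e1mx <- (fr$e1x_lo + fr$e1x_hi) / 2 + fr$ox
  e1my <- (fr$e1y_lo + fr$e1y_hi) / 2 + fr$oy
  e2mx <- (fr$e2x_lo + fr$e2x_hi) / 2 + fr$ox
  e2my <- (fr$e2y_lo + fr$e2y_hi) / 2 + fr$oy
  nz <- assign_planar_z(fr$mz, fr$mz, Dz)
  acc <- new.env(parent = emptyenv())
  rows <- list()
  for (k in 1:4) {
    w <- (2 * k - 1) / 8
    cx <- (1 - w) * e1mx + w * e2mx
    cy <- (1 - w) * e1my + w * e2my
    rows[[k]] <- data.frame(nx = as.integer(floor(cx / Dx) + 1),
                            ny = as.integer(floor(cy / Dy) + 1),
                            nz = nz, area = fr$area / 4)
  }
  all <- do.call(rbind, rows)
  agg <- stats::aggregate(area ~ nx + ny + nz, data = all, FUN = sum)
  agg <- agg[order(agg$nz, agg$ny, agg$nx), ]
  rownames(agg) <- NULL
  agg$area_density <- agg$area / (Dx * Dy * Dz)
  trait_profile(agg, "voxel", Dx = Dx, Dy = Dy, Dz = Dz, fnum = fnum,
                total_area = sum(agg$area))
}

#' Area-weighted leaf azimuth distribution
#'
#' The circle is divided into `dn` equal sectors; fragment areas accumulate
#' into the sector of their midrib-segment azimuth and the histogram is
#' normalized to sum to one.
#'
#' @param x architecture or fragment data.frame.
#' @param fnum fragments per leaf.
#' @param dn number of azimuth sectors.
#' @return a `trait_profile`: `interval`, `az_lo`, `az_hi` (rad), `area`,
#'   `azimuth_density` (sums to 1 for a nonempty canopy).
#' @export
azimuth_distribution <- function(x, fnum = 100L, dn = 36L) {
  if (!is_scalar_num(dn) || dn < 1) stopf("dn must be an integer >= 1")
  fr <- as_fragments(x, fnum)
  n <- seq_len(dn)
  width <- 2 * pi / dn
  if (!nrow(fr)) area <- rep(0, dn)
  else {
    iv <- pmin(as.integer(floor(round(fr$az / (2 * pi) * dn, 9)) + 1), dn)
    area <- vapply(n, function(k) sum(fr$area[iv == k]), 0)
  }
  tot <- sum(area)
  trait_profile(data.frame(interval = n, az_lo = (n - 1) * width,
                           az_hi = n * width, area = area,
                           azimuth_density = if (tot > 0) area / tot else rep(0, dn)),
                "azimuth", dn = dn, fnum = fnum, total_area = tot)
}

weighted_incl <- function(area, incl, iv, nmax) {
  vapply(seq_len(nmax), function(n) {
    sel <- iv == n
    a <- sum(area[sel])
    if (a == 0) NA_real_ else sum(area[sel] * incl[sel]) / a
  }, 0)
}

#' Area-weighted mean leaf inclination per vertical interval
#'
#' Empty intervals report `NA` (no leaf surface to average over), never zero.
#'
#' @inheritParams area_profile_z
#' @return a `trait_profile`: `interval`, `z_lo`, `z_hi`, `area`,
#'   `inclination` (rad).
#' @export
inclination_profile_z <- function(x, fnum = 100L, Dns = 5) {
  fr <- as_fragments(x, fnum)
  if (!nrow(fr))
    return(trait_profile(data.frame(interval = integer(), z_lo = numeric(),
                                    z_hi = numeric(), area = numeric(),
                                    inclination = numeric()),
                         "inclination-z", Dns = Dns, fnum = fnum))
  iv <- assign_planar_z(fr$mz, fr$mz, Dns)
  nmax <- max(iv)
  n <- seq_len(nmax)
  trait_profile(data.frame(interval = n, z_lo = (n - 1) * Dns, z_hi = n * Dns,
                           area = vapply(n, function(k) sum(fr$area[iv == k]), 0),
                           inclination = weighted_incl(fr$area, fr$incl, iv, nmax)),
                "inclination-z", Dns = Dns, fnum = fnum)
}

#' Area-weighted mean leaf inclination per hill-axis distance interval
#'
#' @inheritParams area_profile_radial
#' @return a `trait_profile`: `interval`, `r_lo`, `r_hi`, `area`,
#'   `inclination` (rad); empty intervals are `NA`.
#' @export
inclination_profile_radial <- function(x, fnum = 100L, Dns = 5) {
  fr <- as_fragments(x, fnum)
  if (!nrow(fr))
    return(trait_profile(data.frame(interval = integer(), r_lo = numeric(),
                                    r_hi = numeric(), area = numeric(),
                                    inclination = numeric()),
                         "inclination-radial", Dns = Dns, fnum = fnum))
  iv <- assign_cylindrical(fr$r_hill, Dns)
  nmax <- max(iv)
  n <- seq_len(nmax)
  trait_profile(data.frame(interval = n, r_lo = (n - 1) * Dns, r_hi = n * Dns,
                           area = vapply(n, function(k) sum(fr$area[iv == k]), 0),
                           inclination = weighted_incl(fr$area, fr$incl, iv, nmax)),
                "inclination-radial", Dns = Dns, fnum = fnum)
}

#' Solar geometry for the light profile
#'
#' @param theta solar altitude angle above the horizon (rad, in `[0, pi/2]`).
#' @param phi solar azimuth (rad).
#' @param PAR0 radiation incident at the canopy top (any consistent unit;
#'   the profile is linear in it).
#' @return an object of class `sun_config`.
#' @export
sun_config <- function(theta, phi, PAR0 = 1) {
  if (theta < 0 || theta > pi / 2) stopf("solar altitude must lie in [0, pi/2]")
  if (PAR0 < 0) stopf("PAR0 must be >= 0")
  structure(list(theta = theta, phi = phi, PAR0 = PAR0), class = "sun_config")
}

#' Projection factor of a leaf element onto the sun-normal plane
#'
#' `A = cos(theta_sun) cos(theta_leaf) +
#'      sin(theta_sun) sin(theta_leaf) cos(phi_sun - phi_leaf)`,
#' the dot product of the unit sun vector and the leaf-normal direction
#' constructed from the element's inclination and azimuth. Negative values
#' mean the element is lit from behind; the light profile uses `|A|`.
#'
#' @param sun a [sun_config()].
#' @param theta_leaf element inclination (rad).
#' @param phi_leaf element azimuth (rad).
#' @return dimensionless projection factor in `[-1, 1]`.
#' @export
projection_factor <- function(sun, theta_leaf, phi_leaf) {
  cos(sun$theta) * cos(theta_leaf) +
    sin(sun$theta) * sin(theta_leaf) * cos(sun$phi - phi_leaf)
}

#' Light interception profile along the vertical axis
#'
#' Per interval n: the sun-projected leaf area
#' `PSAREA(n) = sum(farea * |A|)`, the layer interception coefficient
#' `LIC(n) = 1 - PSAREA(n) / G` and the relative light density reaching the
#' interval, `LID(n) = PAR0 * prod(LIC(i))` over the intervals i above n
#' (top-down attenuation). `G` is the ground area of the sampled block,
#' `(rows * rs) * (cols * ps)`, or the raw plant count
#' `plantnum * rows * cols` under `normalization = "count"`.
#'
#' A layer whose projected area exceeds `G` would give a negative `LIC`; it is
#' clamped to 0 with a warning.
#'
#' @param x architecture or fragment data.frame.
#' @param fnum fragments per leaf.
#' @param Dns section spacing (cm).
#' @param sun a [sun_config()].
#' @param ctx a [canopy_context()]; defaults to the architecture's own.
#' @param normalization `"ground_area"` (default) or `"count"`.
#' @param n_intervals minimum number of intervals to report (useful for an
#'   empty canopy).
#' @return a `trait_profile`: `interval`, `z_lo`, `z_hi`, `area`, `psarea`,
#'   `lic`, `lid`.
#' @export
light_profile_z <- function(x, fnum = 100L, Dns = 5, sun = sun_config(pi / 2, 0),
                            ctx = NULL, normalization = c("ground_area", "count"),
                            n_intervals = NULL) {
  normalization <- match.arg(normalization)
  ctx <- ctx %||% x$context
  fr <- as_fragments(x, fnum)
  nmax <- max(if (nrow(fr)) assign_planar_z(fr$mz, fr$mz, Dns) else 1L,
              n_intervals %||% 1L)
  n <- seq_len(nmax)
  if (nrow(fr)) {
    iv <- assign_planar_z(fr$mz, fr$mz, Dns)
    A <- abs(projection_factor(sun, fr$incl, fr$az))
    area <- vapply(n, function(k) sum(fr$area[iv == k]), 0)
    psarea <- vapply(n, function(k) sum((fr$area * A)[iv == k]), 0)
  } else {
    area <- psarea <- rep(0, nmax)
  }
  G <- if (normalization == "ground_area")
    (ctx$rows * ctx$spec$rs) * (ctx$cols * ctx$spec$ps)
  else ctx$plantnum * ctx$rows * ctx$cols
  lic <- 1 - psarea / G
  if (any(lic < 0)) {
    warning("layer interception coefficient below 0; clamped (projected area exceeds the ground area)")
    lic <- pmax(lic, 0)
  }
  # attenuate from the canopy top downward
  lid <- sun$PAR0 * rev(cumprod(c(1, rev(lic)[-nmax])))
  trait_profile(data.frame(interval = n, z_lo = (n - 1) * Dns, z_hi = n * Dns,
                           area = area, psarea = psarea, lic = lic, lid = lid),
                "light-z", Dns = Dns, fnum = fnum, sun = sun,
                normalization = normalization)
}

#' @export
print.trait_profile <- function(x, ...) {
  cat(sprintf("<trait_profile> mode = %s\n", attr(x, "mode")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Write a trait profile as tidy CSV
#'
#' @param profile a `trait_profile`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_profile <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}
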