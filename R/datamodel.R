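# Domain types of the digital plant architecture.
#
# All types are plain S3 lists so they serialize naturally to the CSV archive
# dialect (see read_archive). Units: cm for lengths, radians for angles.
# Coordinate frame: right-handed, z up; hill (rn, cn) sits at
# ((cn-1)*ps, (rn-1)*rs) with the row index running along y.

#' Planting specification
#'
#' Row spacing `rs` and plant spacing `ps` of the transplanting grid, in cm.
#'
#' @param rs row spacing (cm), > 0.
#' @param ps plant spacing (cm), > 0.
#' @return an object of class `planting_spec`.
#' @export
planting_spec <- function(rs, ps) {
  if (!is_scalar_num(rs) || rs <= 0) validation_error("rs must be a positive number")
  if (!is_scalar_num(ps) || ps <= 0) validation_error("ps must be a positive number")
  structure(list(rs = rs, ps = ps), class = "planting_spec")
}

#' Hill position in the sampling block
#'
#' @param rn row index (1-based).
#' @param cn column index (1-based).
#' @return an object of class `hill_position`.
#' @export
hill_position <- function(rn, cn) {
  if (!is_scalar_num(rn) || rn < 1 || rn != round(rn))
    validation_error("rn must be an integer >= 1")
  if (!is_scalar_num(cn) || cn < 1 || cn != round(cn))
    validation_error("cn must be an integer >= 1")
  structure(list(rn = as.integer(rn), cn = as.integer(cn)), class = "hill_position")
}

#' Canopy aggregation context
#'
#' Counts used by the trait-profile normalizations: `pm` hills are aggregated,
#' `plantnum` plants per hill enter the count-based light normalization, and
#' `rows` x `cols` is the sampled block.
#'
#' @param pm number of hills aggregated.
#' @param plantnum plants per hill.
#' @param rows,cols extent of the sampled block in hills.
#' @param spec a [planting_spec()].
#' @return an object of class `canopy_context`.
#' @export
canopy_context <- function(pm, plantnum, rows, cols, spec) {
  for (nm in c("pm", "plantnum", "rows", "cols")) {
    v <- get(nm)
    if (!is_scalar_num(v) || v < 1 || v != round(v))
      validation_error("%s must be an integer >= 1", nm)
  }
  stopifnot(inherits(spec, "planting_spec"))
  structure(list(pm = as.integer(pm), plantnum = as.integer(plantnum),
                 rows = as.integer(rows), cols = as.integer(cols), spec = spec),
            class = "canopy_context")
}

#' Stem record
#'
#' One tiller's stem: its length, radius profile along the stem, the raw
#' cylindrical-coordinatograph surface points, and (once reconstructed) the two
#' 3D axis endpoints.
#'
#' @param length stem length S_l (cm), > 0.
#' @param radius_profile data.frame with columns `z` (height, strictly
#'   increasing) and `r` (radius > 0), both cm.
#' @param cc_points optional data.frame with columns `r`, `a`, `h`: polar
#'   radius (cm), azimuth (rad) and height (cm) of stem *surface* points
#'   measured around the hill axis.
#' @param axis_bottom,axis_top optional numeric length-3 axis endpoints; the
#'   bottom must lie on the ground plane (z = 0) and `0 <= z_t <= length`.
#' @return an object of class `stem_record`.
#' @export
stem_record <- function(length, radius_profile, cc_points = NULL,
                        axis_bottom = NULL, axis_top = NULL) {
  if (!is_scalar_num(length) || length <= 0)
    validation_error("stem length must be > 0")
  radius_profile <- as.data.frame(radius_profile)
  if (!all(c("z", "r") %in% names(radius_profile)))
    validation_error("radius_profile needs columns z and r")
  if (nrow(radius_profile) > 1 && any(diff(radius_profile$z) <= 0))
    validation_error("radius_profile z values must be strictly increasing")
  if (any(radius_profile$r <= 0))
    validation_error("stem radii must be > 0")
  if (!is.null(cc_points)) {
    cc_points <- as.data.frame(cc_points)
    if (!all(c("r", "a", "h") %in% names(cc_points)))
      validation_error("cc_points needs columns r, a, h")
  }
  if (!is.null(axis_top)) {
    if (axis_top[3] < -1e-9 || axis_top[3] > length + 1e-9)
      validation_error("axis top height z_t must lie in [0, S_l]")
  }
  if (!is.null(axis_bottom) && abs(axis_bottom[3]) > 1e-9)
    validation_error("axis bottom must lie on the ground plane z = 0")
  structure(list(length = length, radius_profile = radius_profile,
                 cc_points = cc_points, axis_bottom = axis_bottom,
                 axis_top = axis_top),
            class = "stem_record")
}

#' Stem radius lookup
#'
#' Linear interpolation of the stored radius profile, held constant beyond its
#' ends.
#'
#' @param stem a [stem_record()].
#' @return a function `f(z)` returning the radius (cm) at height `z`.
#' @export
stem_radius_at <- function(stem) {
  rp <- stem$radius_profile
  if (nrow(rp) == 1L) {
    r <- rp$r[1]
    return(function(z) rep(r, length(z)))
  }
  stats::approxfun(rp$z, rp$r, rule = 2)
}

#' Leaf shape profile
#'
#' Half-width samples along the blade and the 6th-degree polynomial fitted to
#' them. `coef` is ascending: `coef[1]` is the constant (the fit residual g),
#' `coef[7]` multiplies `l^6`.
#'
#' @param samples data.frame with columns `l` (arc distance from the node,
#'   strictly increasing, >= 0) and `halfwidth` (cm, >= 0).
#' @param coef numeric length-7 polynomial coefficients, ascending degree.
#' @param tip_tol tolerance (cm) for the half-width at the leaf tip.
#' @return an object of class `leaf_shape_profile`.
#' @export
leaf_shape_profile <- function(samples, coef, tip_tol = 0.35) {
  samples <- as.data.frame(samples)
  if (!all(c("l", "halfwidth") %in% names(samples)))
    validation_error("shape samples need columns l and halfwidth")
  if (nrow(samples) < 2) validation_error("need at least 2 shape samples")
  if (samples$l[1] < 0 || any(diff(samples$l) <= 0))
    validation_error("shape l grid must be strictly increasing and start >= 0")
  if (any(samples$halfwidth < -1e-9))
    validation_error("halfwidths must be >= 0")
  samples$halfwidth <- pmax(samples$halfwidth, 0)
  if (length(coef) != 7) validation_error("shape polynomial needs 7 coefficients")
  tip <- samples$halfwidth[nrow(samples)]
  if (tip > tip_tol)
    validation_error("half-width at the leaf tip (%.3f cm) exceeds tolerance %.3f", tip, tip_tol)
  structure(list(samples = samples, coef = as.numeric(coef)),
            class = "leaf_shape_profile")
}

#' Evaluate a leaf's half-width at arc positions
#'
#' Evaluates the fitted shape polynomial, clamped at zero (the unconstrained
#' fit can dip marginally negative near the tip).
#'
#' @param shape a [leaf_shape_profile()].
#' @param l arc distances from the node (cm).
#' @return half-widths (cm).
#' @export
shape_halfwidth <- function(shape, l) pmax(poly_eval(shape$coef, l), 0)

#' 2D midrib curve in the tiller-image frame
#'
#' Quadratic fits `x(l) = a1 l^2 + b1 l + c1`, `y(l) = a2 l^2 + b2 l + c2`
#' with the origin at the leaf node; `l` is arc distance from the node.
#'
#' @param fit named numeric vector `a1,b1,c1,a2,b2,c2`.
#' @param length total arc length of the blade midrib (cm), > 0.
#' @param points optional data.frame of binned midrib observations with
#'   columns `x`, `y` (cm, node at the origin).
#' @param origin_tol tolerance (cm) for the first point lying at the origin.
#' @return an object of class `midrib_curve2d`.
#' @export
midrib_curve2d <- function(fit, length, points = NULL, origin_tol = 0.35) {
  fit <- as.numeric(fit)
  if (base::length(fit) != 6) validation_error("midrib fit needs 6 coefficients")
  names(fit) <- c("a1", "b1", "c1", "a2", "b2", "c2")
  if (!is_scalar_num(length) || length <= 0)
    validation_error("midrib length must be > 0")
  if (!is.null(points)) {
    points <- as.data.frame(points)
    if (!all(c("x", "y") %in% names(points)))
      validation_error("midrib points need columns x and y")
    if (nrow(points) > 0 && sqrt(points$x[1]^2 + points$y[1]^2) > origin_tol)
      validation_error("first midrib point must lie at the node origin")
  }
  structure(list(fit = fit, length = length, points = points),
            class = "midrib_curve2d")
}

# Evaluate the 2D midrib fit at parameter l -> data.frame(x, y)
midrib2d_eval <- function(midrib, l) {
  f <- midrib$fit
  data.frame(x = f["a1"] * l^2 + f["b1"] * l + f["c1"],
             y = f["a2"] * l^2 + f["b2"] * l + f["c2"])
}

#' Leaf record
#'
#' One leaf: azimuth, node in the tiller-image frame, half-width shape
#' profile, 2D midrib fit, and, once lifted, the 3D node, midrib and blade
#' edges.
#'
#' @param azimuth leaf azimuth theta (rad); wrapped into `[0, 2*pi)`.
#' @param node_image numeric length-2 `(x, y)`: radial offset from the stem
#'   axis and node height in the tiller-image frame (cm).
#' @param shape a [leaf_shape_profile()].
#' @param midrib2d a [midrib_curve2d()].
#' @param node3d,midrib3d,edges3d optional reconstructed 3D fields:
#'   `node3d` length-3 numeric; `midrib3d` data.frame `l,x,y,z`; `edges3d` a
#'   list of two such data.frames sharing `midrib3d`'s `l` grid.
#' @return an object of class `leaf_record`.
#' @export
leaf_record <- function(azimuth, node_image, shape, midrib2d,
                        node3d = NULL, midrib3d = NULL, edges3d = NULL) {
  stopifnot(inherits(shape, "leaf_shape_profile"), inherits(midrib2d, "midrib_curve2d"))
  if (length(node_image) != 2) validation_error("node_image must be (x, y)")
  if (!is.null(midrib3d) && !is.null(edges3d)) {
    if (!isTRUE(all.equal(midrib3d$l, edges3d[[1]]$l)) ||
        !isTRUE(all.equal(midrib3d$l, edges3d[[2]]$l)))
      validation_error("midrib3d and edges3d must share the same l grid")
  }
  structure(list(azimuth = wrap_angle(azimuth), node_image = as.numeric(node_image),
                 shape = shape, midrib2d = midrib2d, node3d = node3d,
                 midrib3d = midrib3d, edges3d = edges3d),
            class = "leaf_record")
}

#' Tiller: one stem plus its leaves
#'
#' @param stem a [stem_record()].
#' @param leaves list of [leaf_record()]s.
#' @return an object of class `tiller`.
#' @export
tiller <- function(stem, leaves = list()) {
  stopifnot(inherits(stem, "stem_record"))
  for (lf in leaves) {
    stopifnot(inherits(lf, "leaf_record"))
    if (lf$node_image[2] > stem$length + 1e-9)
      validation_error("leaf node height %.2f exceeds stem length %.2f",
                       lf$node_image[2], stem$length)
  }
  structure(list(stem = stem, leaves = leaves), class = "tiller")
}

#' Digital plant architecture
#'
#' The full structural dataset: aggregation context plus a list of hills, each
#' with its grid position, ground-plane origin and tillers.
#'
#' @param context a [canopy_context()].
#' @param hills list of `list(position = hill_position(), origin = c(x, y),
#'   tillers = list(...))`. Origins must follow the planting convention: hill
#'   `(rn, cn)` at `((cn-1)*ps, (rn-1)*rs)`.
#' @param origin_tol tolerance (cm) on the origin convention.
#' @return an object of class `digital_architecture`.
#' @export
digital_architecture <- function(context, hills = list(), origin_tol = 1e-6) {
  stopifnot(inherits(context, "canopy_context"))
  for (h in hills) {
    stopifnot(inherits(h$position, "hill_position"))
    expect_o <- c((h$position$cn - 1) * context$spec$ps,
                  (h$position$rn - 1) * context$spec$rs)
    if (max(abs(h$origin - expect_o)) > origin_tol)
      validation_error("hill (%d,%d) origin (%.3f,%.3f) violates the planting convention",
                       h$position$rn, h$position$cn, h$origin[1], h$origin[2])
    for (tl in h$tillers) stopifnot(inherits(tl, "tiller"))
  }
  structure(list(context = context, hills = hills), class = "digital_architecture")
}

#' Validate a digital architecture
#'
#' Re-runs every constructor invariant on an assembled architecture. Called by
#' [read_archive()] so invalid archives are rejected with the offending record
#' named.
#'
#' @param arch a [digital_architecture()].
#' @return invisibly `TRUE`; errors (class `riceCanopy_validation_error`)
#'   otherwise.
#' @export
validate_architecture <- function(arch) {
  stopifnot(inherits(arch, "digital_architecture"))
  ctx <- arch$context
  for (h in arch$hills) {
    hid <- sprintf("hill (%d,%d)", h$position$rn, h$position$cn)
    for (ti in seq_along(h$tillers)) {
      tl <- h$tillers[[ti]]
      id <- sprintf("%s tiller %d", hid, ti)
      res <- tryCatch({
        stem_record(tl$stem$length, tl$stem$radius_profile, tl$stem$cc_points,
                    tl$stem$axis_bottom, tl$stem$axis_top)
        for (li in seq_along(tl$leaves)) {
          lf <- tl$leaves[[li]]
          leaf_shape_profile(lf$shape$samples, lf$shape$coef)
          midrib_curve2d(lf$midrib2d$fit, lf$midrib2d$length, lf$midrib2d$points)
          if (lf$node_image[2] > tl$stem$length + 1e-9)
            validation_error("leaf %d node above the stem tip", li)
        }
        TRUE
      }, riceCanopy_validation_error = function(e) e)
      if (inherits(res, "error"))
        validation_error("%s: %s", id, conditionMessage(res))
    }
  }
  digital_architecture(ctx, arch$hills)  # origin convention re-check
  invisible(TRUE)
}

#' @export
print.digital_architecture <- function(x, ...) {
  nt <- sum(vapply(x$hills, function(h) length(h$tillers), 1L))
  nl <- sum(vapply(x$hills, function(h)
    sum(vapply(h$tillers, function(t) length(t$leaves), 1L)), 1L))
  cat(sprintf("<digital_architecture> %d hills, %d tillers, %d leaves\n",
              length(x$hills), nt, nl))
  cat(sprintf("  block %d x %d hills, rs = %g cm, ps = %g cm\n",
              x$context$rows, x$context$cols, x$context$spec$rs, x$context$spec$ps))
  invisible(x)
}
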