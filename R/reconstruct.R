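# Lifting measured records into 3D: stem axis from cylindrical-coordinatograph
# surface points, leaf nodes along the axis, midrib curves lifted by azimuth
# and stem tilt, blade edges offset perpendicular to the venation plane.

#' Fit the 3D stem axis from surface measurements
#'
#' The coordinatograph measures points on the outward-facing stem *surface*
#' in hill-cylindrical coordinates (r, a, h). Each is corrected to an axis
#' point by subtracting the stem radius at its height (`r - Sr(h)`) before
#' converting to Cartesian via `x = r cos a`, `y = r sin a`. A 3D line is
#' fitted (exactly for two points, total least squares otherwise); the bottom
#' endpoint is its intersection with the ground plane and the top endpoint
#' lies one stem length along the upward unit direction, so
#' `|top - bottom| = S_l` exactly.
#'
#' @param cc_points data.frame with columns `r`, `a`, `h` (cm, rad, cm); at
#'   least 2 points with distinct heights.
#' @param radius_at function `f(h)` returning the stem radius (cm), e.g. from
#'   [stem_radius_at()]; may also be a single number.
#' @param S_l stem length (cm).
#' @return list with `axis_bottom`, `axis_top` (numeric length-3).
#' @export
stem_axis_3d <- function(cc_points, radius_at, S_l) {
  cc <- as.data.frame(cc_points)
  if (nrow(cc) < 2) stopf("need at least 2 surface points to fit the stem axis")
  if (is.numeric(radius_at)) {
    r0 <- radius_at
    radius_at <- function(h) rep(r0, length(h))
  }
  rc <- cc$r - radius_at(cc$h)
  P <- cbind(x = rc * cos(cc$a), y = rc * sin(cc$a), z = cc$h)
  if (diff(range(cc$h)) < 1e-9)
    stopf("degenerate axis direction: all surface points at the same height")
  if (nrow(P) == 2) {
    d <- P[2, ] - P[1, ]
    ctr <- P[1, ]
  } else {
    ctr <- colMeans(P)
    d <- stats::prcomp(P, center = TRUE, scale. = FALSE)$rotation[, 1]
  }
  if (d[3] < 0) d <- -d
  if (d[3] <= 0) stopf("degenerate axis direction: no vertical component")
  d <- d / norm3(d)
  bottom <- ctr - (ctr[3] / d[3]) * d
  bottom[3] <- 0                       # exact ground intersection
  top <- bottom + S_l * d
  list(axis_bottom = unname(bottom), axis_top = unname(top))
}

#' Lift a leaf node into 3D
#'
#' The node sits on the stem axis at the fraction `y / S_l` of the axis
#' (which reduces to height y for a vertical stem), offset radially by the
#' node's image-frame distance x in the direction of the leaf azimuth.
#'
#' @param node_image `c(x, y)`: radial offset and node height in the tiller
#'   frame (cm); x is treated as non-negative, `0 <= y <= S_l`.
#' @param theta leaf azimuth (rad).
#' @param stem a [stem_record()] with axis endpoints populated.
#' @return numeric length-3 node position (cm).
#' @export
leaf_node_3d <- function(node_image, theta, stem) {
  if (is.null(stem$axis_bottom) || is.null(stem$axis_top))
    stopf("stem axis endpoints missing; run stem_axis_3d first")
  y <- node_image[2]
  if (y < -1e-9 || y > stem$length + 1e-9)
    stopf("node height %.2f outside [0, S_l = %.2f]", y, stem$length)
  f <- y / stem$length
  stem$axis_bottom + f * (stem$axis_top - stem$axis_bottom) +
    node_image[1] * c(cos(theta), sin(theta), 0)
}

#' Lift a 2D midrib curve into 3D
#'
#' The in-plane radial run `x(l)` is rotated to the leaf azimuth and the
#' height run `y(l)` is scaled by the stem tilt factor `z_t / S_l`, starting
#' from the 3D node:
#' `X = x(l) cos(theta) + x_ln`, `Y = x(l) sin(theta) + y_ln`,
#' `Z = z_ln + y(l) z_t / S_l`.
#'
#' @param midrib2d a [midrib_curve2d()].
#' @param theta leaf azimuth (rad).
#' @param node3d numeric length-3 node position.
#' @param stem a [stem_record()] with axis endpoints (for `z_t / S_l`).
#' @param n_samples number of arc samples over `[0, length]`.
#' @param l optional explicit arc positions (overrides `n_samples`).
#' @return data.frame `l, x, y, z`.
#' @export
midrib_3d <- function(midrib2d, theta, node3d, stem, n_samples = 100L, l = NULL) {
  if (is.null(l)) l <- seq(0, midrib2d$length, length.out = n_samples)
  m2 <- midrib2d_eval(midrib2d, l)
  kz <- if (is.null(stem$axis_top)) 1 else stem$axis_top[3] / stem$length
  data.frame(l = l,
             x = m2$x * cos(theta) + node3d[1],
             y = m2$x * sin(theta) + node3d[2],
             z = node3d[3] + m2$y * kz)
}

# Unit normal of the leaf venation plane: cross product of the chords
# (mid - first) x (last - mid); horizontal fallback when the midrib is
# straight (zero cross product).
venation_normal <- function(midrib3d) {
  n <- nrow(midrib3d)
  p1 <- as.numeric(midrib3d[1, c("x", "y", "z")])
  pm <- as.numeric(midrib3d[ceiling(n / 2), c("x", "y", "z")])
  pN <- as.numeric(midrib3d[n, c("x", "y", "z")])
  v1 <- pm - p1; v2 <- pN - pm
  P <- c(v1[2] * v2[3] - v1[3] * v2[2],
         v1[3] * v2[1] - v1[1] * v2[3],
         v1[1] * v2[2] - v1[2] * v2[1])
  if (norm3(P) < 1e-9 * max(norm3(v1) * norm3(v2), 1e-12)) {
    chord <- pN - p1
    P <- c(-chord[2], chord[1], 0)     # horizontal, perpendicular to the chord
    if (norm3(P) < 1e-12) P <- c(1, 0, 0)  # vertical midrib: any horizontal
  }
  P / norm3(P)
}

#' Offset the blade edges from the 3D midrib
#'
#' Each midrib sample is offset by plus/minus the local half-width along the
#' unit normal of the venation plane (the cross product of the midrib
#' chords); a straight midrib falls back to the horizontal normal
#' perpendicular to its chord.
#'
#' @param midrib3d data.frame `l, x, y, z` from [midrib_3d()].
#' @param shape a [leaf_shape_profile()].
#' @return list of two data.frames `l, x, y, z` (the two blade margins).
#' @export
leaf_edges_3d <- function(midrib3d, shape) {
  if (nrow(midrib3d) < 3) stopf("midrib3d needs at least 3 samples")
  p <- venation_normal(midrib3d)
  hw <- shape_halfwidth(shape, midrib3d$l)
  e1 <- data.frame(l = midrib3d$l, x = midrib3d$x - hw * p[1],
                   y = midrib3d$y - hw * p[2], z = midrib3d$z - hw * p[3])
  e2 <- data.frame(l = midrib3d$l, x = midrib3d$x + hw * p[1],
                   y = midrib3d$y + hw * p[2], z = midrib3d$z + hw * p[3])
  list(e1, e2)
}

#' Reconstruct all 3D fields of an architecture
#'
#' For every tiller: fit the stem axis from its coordinatograph points (when
#' present and not already fitted), then lift every leaf's node, midrib and
#' blade edges. Leaf coordinates are hill-local; hill origins are applied by
#' the trait and scene builders.
#'
#' @param arch a [digital_architecture()].
#' @param n_samples midrib samples per leaf.
#' @return the architecture with `axis_bottom`/`axis_top`, `node3d`,
#'   `midrib3d` and `edges3d` populated.
#' @export
reconstruct_architecture <- function(arch, n_samples = 100L) {
  for (hi in seq_along(arch$hills)) {
    h <- arch$hills[[hi]]
    for (ti in seq_along(h$tillers)) {
      tl <- h$tillers[[ti]]
      st <- tl$stem
      if (is.null(st$axis_bottom) || is.null(st$axis_top)) {
        if (is.null(st$cc_points))
          stopf("hill (%d,%d) tiller %d: no axis endpoints and no cc_points",
                h$position$rn, h$position$cn, ti)
        ax <- stem_axis_3d(st$cc_points, stem_radius_at(st), st$length)
        st$axis_bottom <- ax$axis_bottom
        st$axis_top <- ax$axis_top
      }
      for (li in seq_along(tl$leaves)) {
        lf <- tl$leaves[[li]]
        lf$node3d <- leaf_node_3d(lf$node_image, lf$azimuth, st)
        lf$midrib3d <- midrib_3d(lf$midrib2d, lf$azimuth, lf$node3d, st, n_samples)
        lf$edges3d <- leaf_edges_3d(lf$midrib3d, lf$shape)
        tl$leaves[[li]] <- lf
      }
      tl$stem <- st
      arch$hills[[hi]]$tillers[[ti]] <- tl
    }
  }
  arch
}
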