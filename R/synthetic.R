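# Parametric ground-truth canopies. The generator produces the measured 2D
# records (midrib quadratics, shape polynomials, azimuths, node positions,
# coordinatograph surface points) exactly as the measurement pipeline would,
# plus the lifted 3D truth, so every downstream module can be exercised
# without field data.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

rtrunc_norm <- function(n, mean, sd, lo) pmax(stats::rnorm(n, mean, sd), lo)

#' Plant template for the synthetic canopy generator
#'
#' Defaults describe a transplanted indica-type canopy around heading: 10
#' tillers per hill, 4 expanded blades per tiller, stems ~65 cm with mild
#' tilt, blades ~32 cm long with lanceolate half-width profiles (expressed
#' exactly in the 6th-degree polynomial family used by the shape fits, so
#' imaging refits have an attainable truth), and uniformly random leaf
#' azimuths.
#'
#' @param tillers_per_hill,leaves_per_tiller counts.
#' @param stem_length_mean,stem_length_sd stem length distribution (cm).
#' @param stem_tilt_sd sd of the stem tilt angle from vertical (rad).
#' @param stem_radius_base,stem_radius_top linear radius taper (cm).
#' @param leaf_length_mean,leaf_length_sd blade length distribution (cm).
#' @param halfwidth_mean,halfwidth_sd distribution of the maximum half-width
#'   (cm).
#' @param base_angle_range range of the blade base angle from vertical (rad).
#' @param curve_out_range,droop_range ranges of the outward (`a1`) and
#'   downward (`-a2`) quadratic midrib curvatures (1/cm).
#' @param node_span fraction of the stem over which leaf nodes spread.
#' @param azimuth_scheme `"uniform"` or a numeric vector of fixed azimuths
#'   (rad), recycled over the leaves of a tiller.
#' @param cc_n number of coordinatograph surface points per stem (>= 2).
#' @param cc_noise_sd measurement noise on the corrected radial position of
#'   the surface points (cm).
#' @param seed RNG seed (Mersenne-Twister).
#' @return an object of class `plant_template`.
#' @export
plant_template <- function(tillers_per_hill = 10L, leaves_per_tiller = 4L,
                           stem_length_mean = 65, stem_length_sd = 6,
                           stem_tilt_sd = 5 * pi / 180,
                           stem_radius_base = 0.35, stem_radius_top = 0.15,
                           leaf_length_mean = 32, leaf_length_sd = 6,
                           halfwidth_mean = 0.75, halfwidth_sd = 0.1,
                           base_angle_range = c(25, 45) * pi / 180,
                           curve_out_range = c(0.001, 0.008),
                           droop_range = c(0.003, 0.015),
                           node_span = c(0.45, 0.95),
                           azimuth_scheme = "uniform",
                           cc_n = 2L, cc_noise_sd = 0,
                           seed = 1L) {
  tpl <- as.list(environment())
  for (nm in c("stem_length_mean", "leaf_length_mean", "halfwidth_mean",
               "stem_radius_base", "stem_radius_top"))
    if (tpl[[nm]] <= 0) validation_error("%s must be > 0", nm)
  if (cc_n < 2) validation_error("cc_n must be >= 2")
  structure(tpl, class = "plant_template")
}

# exact degree-3 lanceolate half-width profile inside the degree-6 family:
# hw(l) = k * s (1-s) (2-s), s = l/L: widest ~42% from the base, simple zero
# at the tip (a pointed blade with finite apex angle, unlike a double root
# whose sub-pixel taper no finite-resolution measurement could resolve).
# Peak value is 2/(3*sqrt(3)) * k, so k = hm * 3*sqrt(3)/2.
lanceolate_coef <- function(hm, L) {
  k <- hm * 3 * sqrt(3) / 2
  # k * (2s - 3s^2 + s^3)
  c(0, 2 * k / L, -3 * k / L^2, k / L^3, 0, 0, 0)
}

#' Generate a synthetic digital architecture
#'
#' Deterministic for a fixed template seed. Every stem carries
#' coordinatograph surface points consistent with its (known) axis and radius
#' profile, so the reconstruction path can be exercised against the
#' generator's truth; all 3D fields are populated on return.
#'
#' @param template a [plant_template()].
#' @param ctx a [canopy_context()]; defaults to the 8-hill block (2 rows x 4
#'   hills) at 20 cm x 20 cm spacing with `plantnum = tillers_per_hill`.
#' @return a reconstructed [digital_architecture()].
#' @export
generate_architecture <- function(template, ctx = NULL) {
  stopifnot(inherits(template, "plant_template"))
  t <- template
  ctx <- ctx %||% canopy_context(pm = 8L, plantnum = t$tillers_per_hill,
                                 rows = 2L, cols = 4L,
                                 spec = planting_spec(20, 20))
  arch <- with_seed(t$seed, {
    hills <- list()
    for (rn in seq_len(ctx$rows)) for (cn in seq_len(ctx$cols)) {
      tillers <- list()
      for (ti in seq_len(t$tillers_per_hill)) {
        S_l <- rtrunc_norm(1, t$stem_length_mean, t$stem_length_sd,
                           0.55 * t$stem_length_mean)
        tilt <- min(abs(stats::rnorm(1, 0, t$stem_tilt_sd)), 15 * pi / 180)
        tdir <- stats::runif(1, 0, 2 * pi)
        rb <- stats::runif(1, 1, 3)
        ba <- stats::runif(1, 0, 2 * pi)
        bottom <- c(rb * cos(ba), rb * sin(ba), 0)
        d <- c(sin(tilt) * cos(tdir), sin(tilt) * sin(tdir), cos(tilt))
        top <- bottom + S_l * d
        zg <- seq(0, top[3], length.out = 5)
        rp <- data.frame(z = zg,
                         r = t$stem_radius_base +
                           (t$stem_radius_top - t$stem_radius_base) * zg / max(zg))
        rad_at <- stats::approxfun(rp$z, rp$r, rule = 2)
        # surface points seen by the coordinatograph: outward side of the stem
        hs <- seq(0.2, 0.8, length.out = t$cc_n) * top[3]
        axy <- cbind(bottom[1] + (hs / top[3]) * (top[1] - bottom[1]),
                     bottom[2] + (hs / top[3]) * (top[2] - bottom[2]))
        qn <- sqrt(rowSums(axy^2))
        cc <- data.frame(r = qn + rad_at(hs) + stats::rnorm(t$cc_n, 0, t$cc_noise_sd),
                         a = atan2(axy[, 2], axy[, 1]), h = hs)
        leaves <- list()
        fr <- seq(t$node_span[1], t$node_span[2],
                  length.out = t$leaves_per_tiller) +
          stats::runif(t$leaves_per_tiller, -0.02, 0.02)
        fr <- clamp(fr, 0.05, 0.99)
        for (li in seq_len(t$leaves_per_tiller)) {
          L <- rtrunc_norm(1, t$leaf_length_mean, t$leaf_length_sd,
                           0.4 * t$leaf_length_mean)
          if (L > 2 * t$leaf_length_mean)
            warning("generated leaf longer than a plausible blade; template may be infeasible")
          hm <- rtrunc_norm(1, t$halfwidth_mean, t$halfwidth_sd,
                            0.4 * t$halfwidth_mean)
          alpha <- stats::runif(1, t$base_angle_range[1], t$base_angle_range[2])
          a1 <- stats::runif(1, t$curve_out_range[1], t$curve_out_range[2])
          a2 <- -stats::runif(1, t$droop_range[1], t$droop_range[2])
          theta <- if (is.numeric(t$azimuth_scheme))
            t$azimuth_scheme[(li - 1L) %% length(t$azimuth_scheme) + 1L]
          else stats::runif(1, 0, 2 * pi)
          node_y <- fr[li] * S_l
          node_x <- rad_at(fr[li] * top[3])
          ls <- seq(0, L, length.out = 21)
          shp <- leaf_shape_profile(
            data.frame(l = ls, halfwidth = poly_eval(lanceolate_coef(hm, L), ls)),
            lanceolate_coef(hm, L))
          mid <- midrib_curve2d(c(a1, sin(alpha), 0, a2, cos(alpha), 0), L)
          leaves[[li]] <- leaf_record(theta, c(node_x, node_y), shp, mid)
        }
        tillers[[ti]] <- tiller(stem_record(S_l, rp, cc), leaves)
      }
      hills[[length(hills) + 1L]] <-
        list(position = hill_position(rn, cn),
             origin = c((cn - 1) * ctx$spec$ps, (rn - 1) * ctx$spec$rs),
             tillers = tillers)
    }
    digital_architecture(ctx, hills)
  })
  reconstruct_architecture(arch)
}

#' Raster rendering specification
#'
#' @param cm_per_px pixel pitch (cm), > 0.
#' @param distortion optional `calibration_model` used as the true
#'   pixel-to-real map (for exercising non-trivial calibrations); `NULL`
#'   means a pure scale map.
#' @param gradient illumination-gradient amplitude in `[0, 1]`; 0 = studio
#'   flat lighting, 1 = a top-to-bottom brightness ramp strong enough that no
#'   single global threshold separates plant from background.
#' @param margin canvas margin around the plant (cm).
#' @param fg,bg RGB triplets in `[0, 1]`.
#' @return an object of class `render_spec`.
#' @export
render_spec <- function(cm_per_px = 0.02, distortion = NULL, gradient = 0,
                        margin = 1, fg = c(0.10, 0.80, 0.15),
                        bg = c(0.10, 0.10, 0.10)) {
  if (cm_per_px <= 0) validation_error("cm_per_px must be > 0")
  structure(list(cm_per_px = cm_per_px, distortion = distortion,
                 gradient = gradient, margin = margin, fg = fg, bg = bg),
            class = "render_spec")
}

#' Generate calibration-grid correspondences
#'
#' An `nx` x `ny` pixel grid pushed through the spec's true pixel-to-real
#' map, as a printed validation grid would be.
#'
#' @param spec a [render_spec()]; its `distortion` (or scale map) is the
#'   truth.
#' @param nx,ny grid points per axis (`nx * ny >= 6`).
#' @param image_size pixel extent `c(rows, cols)` the grid spans.
#' @return data.frame `i, j, x, y` of correspondences, with the true
#'   `calibration_model` attached as attribute `"truth"`.
#' @export
generate_calibration_grid <- function(spec, nx = 5L, ny = 5L,
                                      image_size = c(480L, 640L)) {
  if (nx * ny < 6) stopf("need nx * ny >= 6 grid points")
  cal <- spec$distortion %||% scale_calibration(spec$cm_per_px)
  is <- seq(1, image_size[2], length.out = nx)
  js <- seq(1, image_size[1], length.out = ny)
  g <- expand.grid(i = is, j = js)
  real <- pixel_to_real(cal, g$i, g$j)
  out <- cbind(g, real)
  attr(out, "truth") <- cal
  out
}

#' Sample points uniformly on the canopy's leaf surfaces
#'
#' Monte-Carlo surface sampling used as an independent check of the virtual
#' blade profiles: arc positions are drawn proportionally to the local blade
#' width on a fine grid (much finer than any fragment grid), the cross-width
#' offset uniformly within the local half-width, and the point is placed on
#' the reconstructed blade surface. Histogramming the sampled heights (or
#' hill-axis distances) estimates the area proportions per interval without
#' any fragment approximation.
#'
#' @param arch a reconstructed [digital_architecture()].
#' @param n number of sample points.
#' @param grid_n fine-grid intervals per leaf for the arc-position draw.
#' @return data.frame with the sampled points: canopy coordinates `x, y, z`
#'   (hill origin applied) and `r_hill`, the horizontal distance from the
#'   hill axis.
#' @export
sample_canopy_surface <- function(arch, n = 1e5, grid_n = 200L) {
  leaves <- list()
  for (h in arch$hills)
    for (tl in h$tillers)
      for (lf in tl$leaves)
        leaves[[length(leaves) + 1L]] <- list(lf = lf, stem = tl$stem,
                                              origin = h$origin)
  if (!length(leaves)) stopf("architecture has no leaves to sample")

  prep <- lapply(leaves, function(e) {
    L <- e$lf$midrib2d$length
    lg <- seq(0, L, length.out = grid_n + 1L)
    w <- 2 * shape_halfwidth(e$lf$shape, lg)
    seg <- diff(lg) * (w[-1] + w[-length(w)]) / 2
    list(lg = lg, seg = seg, total = sum(seg))
  })
  wts <- vapply(prep, `[[`, 0, "total")
  pick <- sample.int(length(leaves), n, replace = TRUE, prob = wts)

  out <- data.frame(x = numeric(n), y = numeric(n), z = numeric(n),
                    r_hill = numeric(n))
  for (li in unique(pick)) {
    sel <- which(pick == li)
    e <- leaves[[li]]; p <- prep[[li]]
    seg <- sample.int(length(p$seg), length(sel), replace = TRUE, prob = p$seg)
    u <- stats::runif(length(sel))
    l <- p$lg[seg] + u * diff(p$lg)[seg]
    m3 <- midrib_3d(e$lf$midrib2d, e$lf$azimuth, e$lf$node3d, e$stem, l = l)
    nrm <- venation_normal(midrib_3d(e$lf$midrib2d, e$lf$azimuth, e$lf$node3d,
                                     e$stem, n_samples = 11L))
    hw <- shape_halfwidth(e$lf$shape, l)
    t_off <- stats::runif(length(sel), -1, 1) * hw
    px <- m3$x + t_off * nrm[1]
    py <- m3$y + t_off * nrm[2]
    out$z[sel] <- m3$z + t_off * nrm[3]
    out$r_hill[sel] <- sqrt(px^2 + py^2)
    out$x[sel] <- px + e$origin[1]
    out$y[sel] <- py + e$origin[2]
  }
  out
}
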