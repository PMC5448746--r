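# Shared fixtures: all built in code, no stored data.

# small canopy for fast tests
small_arch <- function(seed = 1L, tillers = 2L, leaves = 2L, ...) {
  generate_architecture(plant_template(tillers_per_hill = tillers,
                                       leaves_per_tiller = leaves,
                                       seed = seed, ...))
}

# a rectangular "leaf": constant half-width hw over [0, L]
rect_leaf <- function(L = 10, hw = 1) {
  ls <- seq(0, L, length.out = 11)
  shp <- leaf_shape_profile(data.frame(l = ls, halfwidth = rep(hw, 11)),
                            c(hw, 0, 0, 0, 0, 0, 0), tip_tol = Inf)
  leaf_record(azimuth = 0, node_image = c(0, 0), shape = shp,
              midrib2d = midrib_curve2d(c(0, 1, 0, 0, 0, 0), L))
}

# a leaf record with arbitrary placement for fragment tests:
# midrib2d fit (a1,b1,c1,a2,b2,c2), constant or polynomial half-width
placed_leaf <- function(fit, L, hw_coef, azimuth = 0, node3d = c(0, 0, 0)) {
  ls <- seq(0, L, length.out = 11)
  shp <- leaf_shape_profile(data.frame(l = ls, halfwidth = poly_eval(hw_coef, ls)),
                            hw_coef, tip_tol = Inf)
  leaf_record(azimuth = azimuth, node_image = c(0, 0), shape = shp,
              midrib2d = midrib_curve2d(fit, L), node3d = node3d)
}

# a vertical stem with axis endpoints populated
vertical_stem <- function(S_l = 40, r = 0.3, x = 0, y = 0) {
  stem_record(S_l, data.frame(z = c(0, S_l), r = c(r, r)),
              axis_bottom = c(x, y, 0), axis_top = c(x, y, S_l))
}

# fragment table for profile tests constructed by hand
hand_fragments <- function(area, mz, incl = 0, az = 0, r_hill = 0) {
  n <- length(area)
  data.frame(hill_rn = 1L, hill_cn = 1L, ox = 0, oy = 0, tiller = 1L,
             leaf = seq_len(n), frag = 1L, l_lo = 0, l_hi = 1,
             area = area, mx = r_hill, my = 0, mz = mz,
             az = rep_len(az, n), incl = rep_len(incl, n),
             r_hill = rep_len(r_hill, n))
}

expect_close <- function(x, y, tol) testthat::expect_lt(max(abs(x - y)), tol)

lanceolate_coef_test <- function(hm, L) riceCanopy:::lanceolate_coef(hm, L)

# true blade area by fine trapezoid integration of the full width
leaf_true_area <- function(shape, L, n = 2000) {
  lg <- seq(0, L, length.out = n + 1)
  w <- 2 * shape_halfwidth(shape, lg)
  sum(diff(lg) * (w[-1] + w[-length(w)]) / 2)
}
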