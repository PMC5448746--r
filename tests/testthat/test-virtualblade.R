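test_that("flat and vertical reference leaves fragment as expected", {
  st <- vertical_stem(40)
  # horizontal rectangular leaf: length 10, full width 2, at z = 15
  flat <- placed_leaf(c(0, 1, 0, 0, 0, 0), 10, c(1, 0, 0, 0, 0, 0, 0),
                      azimuth = 0, node3d = c(0, 0, 15))
  fr <- fragment_leaf(flat, 10, st)
  expect_equal(nrow(fr), 10)
  expect_close(fr$area, 2, 1e-12)
  expect_close(fr$incl, 0, 1e-12)
  expect_close(fr$mz, 15, 1e-12)
  # vertical leaf: midrib straight up
  vert <- placed_leaf(c(0, 0, 0, 0, 1, 0), 10, c(1, 0, 0, 0, 0, 0, 0),
                      azimuth = 0, node3d = c(0.3, 0, 15))
  fv <- fragment_leaf(vert, 5, st)
  expect_close(fv$incl, pi / 2, 1e-12)
  expect_error(fragment_leaf(flat, 0, st), "fnum")
})

test_that("fragment azimuths follow the four-quadrant rule", {
  st <- vertical_stem(40)
  for (th in c(pi / 4, 3 * pi / 4, 7 * pi / 4)) {
    lf <- placed_leaf(c(0, 1, 0, 0, 0, 0), 10, c(1, 0, 0, 0, 0, 0, 0),
                      azimuth = th, node3d = c(0, 0, 15))
    fr <- fragment_leaf(lf, 4, st)
    expect_close(fr$az, th, 1e-12)
  }
})

test_that("interval assignment follows the floor(+1) conventions", {
  expect_equal(assign_planar_z(4, 6, 5), 2L)
  expect_equal(assign_planar_z(0, 0, 5), 1L)
  expect_equal(assign_planar_z(9.9, 10.1, 10), 2L)
  expect_equal(assign_cylindrical(0, 5), 1L)
  expect_equal(assign_cylindrical(7.2, 5), 2L)
  expect_equal(assign_cylindrical(5, 5), 2L)    # boundary falls upward
  expect_error(assign_planar_z(1, 2, 0), "Dns")
})

test_that("area is conserved exactly in every blade mode", {
  arch <- small_arch(seed = 13, tillers = 3, leaves = 3)
  fr <- fragment_canopy(arch, 50)
  tot <- sum(fr$area)
  pz <- area_profile_z(fr, Dns = 5, ctx = arch$context)
  pr <- area_profile_radial(fr, Dns = 5, ctx = arch$context)
  pv <- area_voxel(fr, Dx = 7, Dy = 6, Dz = 5)
  expect_lt(abs(sum(pz$area) - tot) / tot, 1e-9)
  expect_lt(abs(sum(pr$area) - tot) / tot, 1e-9)
  expect_lt(abs(sum(pv$area) - tot) / tot, 1e-9)
  # probability-density normalization of the vertical profile
  sp <- arch$context$spec
  expect_equal(sum(pz$area_pdensity) * 5 * arch$context$pm * sp$rs * sp$ps, 1,
               tolerance = 1e-9)
})

test_that("one horizontal leaf lands entirely in its height interval", {
  st <- vertical_stem(40)
  flat <- placed_leaf(c(0, 1, 0, 0, 0, 0), 10, c(1, 0, 0, 0, 0, 0, 0),
                      azimuth = 0, node3d = c(0, 0, 15))
  fr <- fragment_leaf(flat, 10, st)
  fr$ox <- 0; fr$oy <- 0; fr$r_hill <- sqrt(fr$mx^2 + fr$my^2)
  ctx <- canopy_context(1, 1, 1, 1, planting_spec(20, 20))
  pz <- area_profile_z(fr, Dns = 10, ctx = ctx)
  expect_equal(pz$area, c(0, 20))
})

test_that("halving Dns and re-summing interval pairs reproduces the coarse profile", {
  arch <- small_arch(seed = 14, tillers = 2, leaves = 3)
  fr <- fragment_canopy(arch, 40)
  coarse <- area_profile_z(fr, Dns = 10, ctx = arch$context)
  fine <- area_profile_z(fr, Dns = 5, ctx = arch$context)
  fa <- fine$area
  if (length(fa) %% 2 == 1) fa <- c(fa, 0)
  paired <- fa[seq(1, length(fa), 2)] + fa[seq(2, length(fa), 2)]
  expect_close(paired[seq_along(coarse$area)], coarse$area, 1e-9)
})

test_that("profiles converge in fnum and destabilize for coarse fragments", {
  arch <- small_arch(seed = 15, tillers = 3, leaves = 3)
  p100 <- area_profile_z(arch, 100, Dns = 5)
  p1000 <- area_profile_z(arch, 1000, Dns = 5)
  n <- min(nrow(p100), nrow(p1000))
  scale <- max(p100$area_density)
  expect_lt(max(abs(p100$area_density[1:n] - p1000$area_density[1:n])) / scale,
            0.02)
  # the classic instability: coarse fragments with fine sections
  p10 <- area_profile_z(arch, 10, Dns = 1)
  jump <- function(p) max(abs(diff(p$area_density)))
  expect_gt(jump(p10), jump(p100))
})

test_that("radial densities are constant for a uniform disc of leaf area", {
  # fragments whose area matches their annulus area -> constant density
  Dns <- 5
  rings <- 1:6
  frs <- do.call(rbind, lapply(rings, function(n) {
    ann <- pi * ((n * Dns)^2 - ((n - 1) * Dns)^2)
    k <- 40
    hand_fragments(area = rep(ann / k, k), mz = 10,
                   r_hill = (n - 0.5) * Dns)
  }))
  ctx <- canopy_context(1, 1, 1, 1, planting_spec(20, 20))
  pr <- area_profile_radial(frs, Dns = Dns, ctx = ctx)
  expect_lt(diff(range(pr$area_density)) / mean(pr$area_density), 0.05)
})

test_that("a single vertical on-axis leaf stays in the first annulus", {
  st <- vertical_stem(40)
  vert <- placed_leaf(c(0, 0, 0, 0, 1, 0), 10, c(1, 0, 0, 0, 0, 0, 0),
                      azimuth = 0, node3d = c(0, 0, 15))
  fr <- fragment_leaf(vert, 10, st)
  fr$ox <- 0; fr$oy <- 0; fr$r_hill <- sqrt(fr$mx^2 + fr$my^2)
  ctx <- canopy_context(1, 1, 1, 1, planting_spec(20, 20))
  pr <- area_profile_radial(fr, Dns = 5, ctx = ctx)
  expect_equal(pr$interval[pr$area > 0], 1L)
})

test_that("voxel mode conserves area and marginalizes to the vertical profile", {
  arch <- small_arch(seed = 16, tillers = 2, leaves = 3)
  fr <- fragment_canopy(arch, 100)
  pv <- area_voxel(fr, Dx = 5, Dy = 5, Dz = 5)
  pz <- area_profile_z(fr, Dns = 5, ctx = arch$context)
  marg <- tapply(pv$area, pv$nz, sum)
  for (n in pz$interval[pz$area > 0]) {
    expect_lt(abs(marg[[as.character(n)]] - pz$area[n]) / pz$area[n], 0.02)
  }
  # one flat leaf inside a single voxel-sized box
  st <- vertical_stem(40)
  flat <- placed_leaf(c(0, 1, 0, 0, 0, 0), 10, c(1, 0, 0, 0, 0, 0, 0),
                      azimuth = 0, node3d = c(1, 1, 3))
  f1 <- fragment_leaf(flat, 10, st)
  f1$ox <- 0; f1$oy <- 0; f1$r_hill <- 0
  pv1 <- area_voxel(f1, Dx = 20, Dy = 20, Dz = 20)
  expect_equal(nrow(pv1), 1)
  expect_equal(pv1$area, 20)
  expect_equal(pv1$area_density, 20 / 8000)
})

test_that("azimuth histograms are normalized and bin correctly", {
  st <- vertical_stem(40)
  lf <- placed_leaf(c(0, 1, 0, 0, 0, 0), 10, c(1, 0, 0, 0, 0, 0, 0),
                    azimuth = pi / 4, node3d = c(0, 0, 15))
  fr <- fragment_leaf(lf, 10, st)
  fr$ox <- 0; fr$oy <- 0; fr$r_hill <- 0
  az <- azimuth_distribution(fr, dn = 8)
  expect_equal(sum(az$azimuth_density), 1)
  expect_equal(az$interval[az$area > 0], 2L)

  arch <- small_arch(seed = 17, tillers = 5, leaves = 5)
  azc <- azimuth_distribution(fragment_canopy(arch, 20), dn = 36)
  expect_equal(sum(azc$azimuth_density), 1, tolerance = 1e-12)
})

test_that("leaf azimuth draws are uniform on the circle", {
  arch <- small_arch(seed = 18, tillers = 13, leaves = 5)
  th <- unlist(lapply(arch$hills, function(h)
    lapply(h$tillers, function(t) vapply(t$leaves, `[[`, 0, "azimuth"))))
  expect_gte(length(th), 500)
  # circular mean resultant length near zero for uniform draws
  R <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  expect_lt(R, 0.1)
  counts <- tabulate(pmin(floor(th / (2 * pi) * 8) + 1, 8), nbins = 8)
  expect_gt(chisq.test(counts)$p.value, 0.01)
})

test_that("inclination profiles are area-weighted means with NA for empty intervals", {
  fr <- hand_fragments(area = c(2, 6), mz = c(7, 8), incl = c(0, pi / 2))
  pz <- inclination_profile_z(fr, Dns = 5)
  expect_equal(pz$inclination[2], 3 * pi / 8)
  expect_true(is.na(pz$inclination[1]))

  # all-horizontal and all-vertical canopies
  frh <- hand_fragments(area = rep(1, 5), mz = seq(2, 22, 5), incl = 0)
  expect_true(all(inclination_profile_z(frh, Dns = 5)$inclination %in% c(0, NA)))
  frv <- hand_fragments(area = rep(1, 5), mz = seq(2, 22, 5), incl = pi / 2)
  pv <- inclination_profile_z(frv, Dns = 5)
  expect_true(all(na.omit(pv$inclination) == pi / 2))
})

test_that("radial inclination agrees with a naive per-fragment group-by oracle", {
  arch <- small_arch(seed = 19, tillers = 3, leaves = 3)
  fr <- fragment_canopy(arch, 30)
  prof <- inclination_profile_radial(fr, Dns = 4)
  iv <- floor(fr$r_hill / 4) + 1
  for (n in prof$interval) {
    sel <- iv == n
    if (!any(sel)) { expect_true(is.na(prof$inclination[n])); next }
    expect_equal(prof$inclination[n],
                 sum(fr$area[sel] * fr$incl[sel]) / sum(fr$area[sel]),
                 tolerance = 1e-12)
  }
  expect_equal(sum(prof$area), sum(fr$area), tolerance = 1e-9)
})

test_that("the projection factor matches its printed special cases and the vector oracle", {
  expect_equal(projection_factor(sun_config(0.7, 1.1), 0.7, 1.1), 1)
  expect_equal(projection_factor(sun_config(0.5, 0), 0, 2), cos(0.5))
  expect_equal(projection_factor(sun_config(pi / 4, 0), pi / 4, pi), 0,
               tolerance = 1e-15)
  set.seed(20)
  for (k in 1:200) {
    ts <- runif(1, 0, pi / 2); tl <- runif(1, 0, pi / 2)
    ps <- runif(1, 0, 2 * pi); pl <- runif(1, 0, 2 * pi)
    u <- c(sin(ts) * cos(ps), sin(ts) * sin(ps), cos(ts))
    v <- c(sin(tl) * cos(pl), sin(tl) * sin(pl), cos(tl))
    expect_equal(projection_factor(sun_config(ts, ps), tl, pl), sum(u * v),
                 tolerance = 1e-12)
  }
})

test_that("light profiles attenuate top-down and handle the empty canopy", {
  arch <- small_arch(seed = 20, tillers = 3, leaves = 3)
  lz <- light_profile_z(arch, 50, Dns = 5, sun = sun_config(pi / 3, pi, 100))
  expect_equal(lz$lid[nrow(lz)], 100)           # full radiation at the top
  expect_true(all(diff(lz$lid) >= -1e-12))      # non-increasing downward
  # empty canopy: PAR0 everywhere
  empty <- fragment_canopy(digital_architecture(
    canopy_context(1, 1, 1, 1, planting_spec(20, 20)), list()), 10)
  le <- light_profile_z(empty, Dns = 5, sun = sun_config(pi / 3, 0, 55),
                        ctx = canopy_context(1, 1, 1, 1, planting_spec(20, 20)),
                        n_intervals = 4)
  expect_equal(le$lid, rep(55, 4))
})

test_that("a single opaque layer of half the ground area halves the light below", {
  ctx <- canopy_context(1, 1, 1, 1, planting_spec(20, 20))
  G <- 20 * 20
  fr <- hand_fragments(area = G / 2, mz = 7.5, incl = 0, az = 0)
  lz <- light_profile_z(fr, Dns = 5, sun = sun_config(0, 0, 80), ctx = ctx,
                        n_intervals = 3)
  # sun term |A| = 1 for this geometry: LIC of the layer is 0.5
  expect_equal(lz$lic, c(1, 0.5, 1))
  expect_equal(lz$lid, c(40, 80, 80))
  # an over-dense layer clamps at zero with a warning
  fr2 <- hand_fragments(area = 3 * G, mz = 7.5, incl = 0, az = 0)
  expect_warning(lz2 <- light_profile_z(fr2, Dns = 5, sun = sun_config(0, 0, 1),
                                        ctx = ctx), "clamped")
  expect_equal(lz2$lic[2], 0)
})
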