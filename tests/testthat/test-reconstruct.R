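test_that("stem axis fitting corrects surface points to the axis", {
  ax <- stem_axis_3d(data.frame(r = c(5, 5), a = c(0, 0), h = c(10, 20)),
                     radius_at = 0.5, S_l = 30)
  expect_equal(ax$axis_bottom, c(4.5, 0, 0))
  expect_equal(ax$axis_top, c(4.5, 0, 30))

  # two points already on a known tilted line (zero radius)
  d <- c(0.1, -0.2, 1); d <- d / sqrt(sum(d^2))
  b <- c(2, 1, 0)
  pts <- rbind(b + 12 * d, b + 30 * d)
  cc <- data.frame(r = sqrt(pts[, 1]^2 + pts[, 2]^2),
                   a = atan2(pts[, 2], pts[, 1]), h = pts[, 3])
  ax2 <- stem_axis_3d(cc, radius_at = 0, S_l = 45)
  expect_close(ax2$axis_bottom, b, 1e-9)
  expect_equal(sqrt(sum((ax2$axis_top - ax2$axis_bottom)^2)), 45)

  expect_error(stem_axis_3d(data.frame(r = c(1, 1), a = c(0, 1), h = c(5, 5)),
                            0, 10), "same height")
  expect_error(stem_axis_3d(data.frame(r = 1, a = 0, h = 5), 0, 10), "at least 2")
})

test_that("five noisy surface points recover the axis direction within 1 degree", {
  set.seed(31)
  d <- c(sin(0.1) * cos(1), sin(0.1) * sin(1), cos(0.1))
  b <- c(3, -2, 0)
  hs <- seq(8, 48, length.out = 5)
  for (rep in 1:10) {
    pts <- t(vapply(hs, function(h) b + (h / d[3]) * d, numeric(3)))
    pts[, 1:2] <- pts[, 1:2] + rnorm(10, 0, 0.1)
    cc <- data.frame(r = sqrt(pts[, 1]^2 + pts[, 2]^2),
                     a = atan2(pts[, 2], pts[, 1]), h = hs)
    ax <- stem_axis_3d(cc, radius_at = 0, S_l = 60)
    dir <- (ax$axis_top - ax$axis_bottom) / 60
    expect_lt(acos(min(sum(dir * d), 1)) * 180 / pi, 1)
  }
})

test_that("leaf nodes interpolate along the axis with a radial azimuth offset", {
  st <- vertical_stem(40)
  expect_equal(leaf_node_3d(c(0.4, 20), 0, st), c(0.4, 0, 20))
  expect_close(leaf_node_3d(c(0.4, 20), pi / 2, st), c(0, 0.4, 20), 1e-12)
  tilted <- stem_record(40, data.frame(z = 0, r = 0.3),
                        axis_bottom = c(1, 2, 0),
                        axis_top = c(1, 2, 0) + 40 * c(0.1, 0.2, sqrt(1 - 0.05)))
  nd <- leaf_node_3d(c(0.5, 20), 0, tilted)
  mid <- (tilted$axis_bottom + tilted$axis_top) / 2
  expect_close(nd, mid + c(0.5, 0, 0), 1e-9)
  expect_error(leaf_node_3d(c(0.4, 45), 0, st), "outside")
})

test_that("the midrib lift preserves azimuth and scales heights by stem tilt", {
  st <- vertical_stem(40)
  node <- c(0.3, 0, 20)
  # no radial run: all points on the vertical line through the node
  m0 <- midrib_3d(midrib_curve2d(c(0, 0, 0, 0, 1, 0), 10), 1.2, node, st, 20)
  expect_close(m0$x, node[1], 1e-12)
  expect_close(m0$y, node[2], 1e-12)
  expect_equal(m0$z, node[3] + m0$l)
  # straight 45-degree midrib in the xz-plane
  m45 <- midrib_3d(midrib_curve2d(c(0, sqrt(0.5), 0, 0, sqrt(0.5), 0), 10),
                   0, node, st, 20)
  expect_close(m45$x - node[1], m45$z - node[3], 1e-12)
  expect_close(m45$y, 0, 1e-12)
  # azimuth preservation at every l
  th <- 2.2
  m <- midrib_3d(midrib_curve2d(c(0.004, 0.8, 0, -0.006, 0.6, 0), 15),
                 th, node, st, 30)
  run <- sqrt((m$x - node[1])^2 + (m$y - node[2])^2)
  keep <- run > 1e-9
  expect_close(atan2(m$y - node[2], m$x - node[1])[keep] %% (2 * pi),
               th %% (2 * pi), 1e-9)
  # tilted stem: z offsets scale by z_t / S_l
  st08 <- stem_record(40, data.frame(z = 0, r = 0.3),
                      axis_bottom = c(0, 0, 0),
                      axis_top = c(24, 0, 32))     # z_t = 0.8 * S_l
  mt <- midrib_3d(midrib_curve2d(c(0, 0.6, 0, -0.005, 0.8, 0), 15), 0, node, st08, 30)
  mv <- midrib_3d(midrib_curve2d(c(0, 0.6, 0, -0.005, 0.8, 0), 15), 0, node, st, 30)
  expect_close(mt$z - node[3], 0.8 * (mv$z - node[3]), 1e-12)
})

test_that("blade edges are symmetric about the midrib along the venation normal", {
  st <- vertical_stem(40)
  lf <- placed_leaf(c(0.003, 0.7, 0, -0.008, 0.71, 0), 20,
                    lanceolate_coef_test(0.8, 20), azimuth = 0,
                    node3d = c(0.3, 0, 20))
  m3 <- midrib_3d(lf$midrib2d, 0, lf$node3d, st, 50)
  ed <- leaf_edges_3d(m3, lf$shape)
  hw <- shape_halfwidth(lf$shape, m3$l)
  gap <- sqrt((ed[[1]]$x - ed[[2]]$x)^2 + (ed[[1]]$y - ed[[2]]$y)^2 +
                (ed[[1]]$z - ed[[2]]$z)^2)
  expect_close(gap, 2 * hw, 1e-9)
  # planar midrib in the xz-plane: edges offset purely in y
  expect_close(ed[[1]]$x, ed[[2]]$x, 1e-9)
  expect_close(ed[[1]]$z, ed[[2]]$z, 1e-9)
  # collinear (straight) midrib: horizontal fallback normal, still symmetric
  straight <- midrib_3d(midrib_curve2d(c(0, 0.6, 0, 0, 0.8, 0), 20), 0.5,
                        c(0, 0, 10), st, 20)
  ed2 <- leaf_edges_3d(straight, lf$shape)
  nrm <- c(ed2[[2]]$x[5] - ed2[[1]]$x[5], ed2[[2]]$y[5] - ed2[[1]]$y[5],
           ed2[[2]]$z[5] - ed2[[1]]$z[5])
  expect_equal(nrm[3], 0)                       # horizontal offset
  chord <- c(straight$x[20] - straight$x[1], straight$y[20] - straight$y[1],
             straight$z[20] - straight$z[1])
  expect_lt(abs(sum(nrm * chord)), 1e-9)        # perpendicular to the chord
})

test_that("reconstruction identities hold across a generated canopy", {
  arch <- small_arch(seed = 8)
  for (h in arch$hills) for (tl in h$tillers) {
    st <- tl$stem
    expect_equal(sqrt(sum((st$axis_top - st$axis_bottom)^2)), st$length,
                 tolerance = 1e-12)
    for (lf in tl$leaves) {
      expect_close(as.numeric(lf$midrib3d[1, c("x", "y", "z")]), lf$node3d, 1e-9)
    }
  }
})

test_that("measure-then-reconstruct recovers the generator's 3D midribs", {
  arch <- small_arch(seed = 9, tillers = 2, leaves = 2)
  d <- withr::local_tempdir()
  write_archive(arch, d)
  rec <- reconstruct_architecture(read_archive(d))
  for (hi in seq_along(arch$hills)) {
    for (ti in seq_along(arch$hills[[hi]]$tillers)) {
      t1 <- arch$hills[[hi]]$tillers[[ti]]
      t2 <- rec$hills[[hi]]$tillers[[ti]]
      for (li in seq_along(t1$leaves)) {
        m1 <- t1$leaves[[li]]$midrib3d
        m2 <- t2$leaves[[li]]$midrib3d
        L <- t1$leaves[[li]]$midrib2d$length
        dev <- sqrt((m1$x - m2$x)^2 + (m1$y - m2$y)^2 + (m1$z - m2$z)^2)
        expect_lt(max(dev), 0.02 * L)
      }
    }
  }
})

test_that("scene meshes have the expected topology", {
  st <- vertical_stem(30, 0.4)
  ctx <- canopy_context(1, 1, 1, 1, planting_spec(20, 20))
  arch <- digital_architecture(ctx, list(list(position = hill_position(1, 1),
                                              origin = c(0, 0),
                                              tillers = list(tiller(st)))))
  mesh <- build_scene(arch, cylinder_segments = 8)
  expect_equal(nrow(mesh$faces), 8 * 2 + 8 * 2)          # sides + two caps
  d_ax <- sqrt(mesh$vertices[, 1]^2 + mesh$vertices[, 2]^2)
  expect_true(all(d_ax <= 0.4 + 1e-9))

  lf <- placed_leaf(c(0.002, 0.6, 0, -0.004, 0.8, 0), 15,
                    lanceolate_coef_test(0.7, 15), node3d = c(0.4, 0, 20))
  arch$hills[[1]]$tillers[[1]] <- tiller(st, list(lf))
  arch <- reconstruct_architecture(arch, n_samples = 25)
  mesh2 <- build_scene(arch, cylinder_segments = 8, leaf_samples = 25)
  expect_equal(sum(startsWith(mesh2$labels, "h1.1_t1_leaf")), 2 * (25 - 1))
})

test_that("eight hills of stems sit disjointly on the planting grid", {
  arch <- small_arch(seed = 10, tillers = 3, leaves = 1)
  mesh <- build_scene(arch)
  hids <- unique(sub("_t.*", "", mesh$labels[grepl("_stem", mesh$labels)]))
  boxes <- lapply(hids, function(hid) {
    rows <- grepl(paste0("^", hid, "_"), mesh$labels) & grepl("_stem", mesh$labels)
    sel <- unique(as.vector(mesh$faces[rows, , drop = FALSE]))
    vs <- mesh$vertices[sel, , drop = FALSE]
    rbind(apply(vs, 2, min), apply(vs, 2, max))
  })
  expect_length(boxes, 8)
  for (a in seq_along(boxes)) for (b in seq_along(boxes)) {
    if (a >= b) next
    overlap <- all(boxes[[a]][1, 1:2] <= boxes[[b]][2, 1:2]) &&
      all(boxes[[b]][1, 1:2] <= boxes[[a]][2, 1:2])
    expect_false(overlap)
  }
})

test_that("OBJ and PLY exports round-trip", {
  arch <- small_arch(seed = 10, tillers = 1, leaves = 1)
  mesh <- build_scene(arch, cylinder_segments = 6, leaf_samples = 10)
  f <- withr::local_tempfile(fileext = ".obj")
  export_mesh(mesh, f, "obj")
  back <- read_obj(f)
  expect_equal(nrow(back$vertices), nrow(mesh$vertices))
  expect_equal(back$faces, mesh$faces)
  expect_close(back$vertices, mesh$vertices, 1e-6)

  fply <- withr::local_tempfile(fileext = ".ply")
  export_mesh(mesh, fply, "ply")
  hdr <- readLines(fply, n = 9)
  expect_equal(hdr[1], "ply")
  expect_match(hdr[3], sprintf("element vertex %d", nrow(mesh$vertices)))

  # empty mesh still writes valid files
  empty <- build_scene(digital_architecture(
    canopy_context(1, 1, 1, 1, planting_spec(20, 20)), list()))
  f2 <- withr::local_tempfile(fileext = ".obj")
  export_mesh(empty, f2, "obj")
  expect_equal(nrow(read_obj(f2)$vertices), 0)
  expect_error(export_mesh(mesh, f, "stl"), "arg")
})
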