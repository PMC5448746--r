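test_that("block-adaptive binarization matches global Otsu under flat light", {
  arch <- small_arch(seed = 4, tillers = 1, leaves = 3)
  tl <- arch$hills[[1]]$tillers[[1]]
  r <- render_tiller_image(tl, render_spec(cm_per_px = 0.08))
  g <- gray_plant(r$image)
  m_block <- binarize_tiller(g)
  m_global <- binarize_leaf(g)
  # disagreement confined to a 1-pixel boundary band of the global mask
  band <- EBImage::dilate(m_global * 1, EBImage::makeBrush(3, "box")) > 0 &
    !(EBImage::erode(m_global * 1, EBImage::makeBrush(3, "box")) > 0)
  expect_lt(sum(xor(m_block, m_global) & !band) / sum(m_global), 0.01)
  expect_gt(sum(m_block & r$truth$core) / sum(r$truth$core), 0.99)
})

test_that("under an illumination gradient the block method recovers the plant but global Otsu fails", {
  arch <- small_arch(seed = 4, tillers = 1, leaves = 3)
  tl <- arch$hills[[1]]$tillers[[1]]
  r <- render_tiller_image(tl, render_spec(cm_per_px = 0.08, gradient = 1))
  g <- gray_plant(r$image)
  m_block <- binarize_tiller(g)
  expect_gt(sum(m_block & r$truth$core) / sum(r$truth$core), 0.99)
  expect_lt(sum(m_block & !r$mask) / sum(!r$mask), 0.02)   # few false positives
  m_global <- g > EBImage::otsu(g, range = c(0, 1))
  # the single global threshold swallows a large part of the background
  expect_gt(sum(m_global & !r$mask) / sum(!r$mask), 0.1)
})

test_that("organ separation finds the right leaves, disjoint from the stem", {
  arch <- small_arch(seed = 6, tillers = 1, leaves = 3)
  tl <- arch$hills[[1]]$tillers[[1]]
  r <- render_tiller_image(tl, render_spec(cm_per_px = 0.06))
  mask <- binarize_tiller(gray_plant(r$image))
  org <- separate_tiller_organs(mask)
  expect_length(org$leaves, 3)
  for (lm in org$leaves) {
    expect_false(any(lm & org$stem))
    for (lm2 in org$leaves) if (!identical(lm, lm2)) expect_false(any(lm & lm2))
  }
  # union of organs stays within the input mask
  all_org <- Reduce(`|`, org$leaves, org$stem)
  expect_false(any(all_org & !mask))
  # leaves come back ordered bottom-up by node height
  rows <- vapply(org$leaves, function(m) max(which(rowSums(m) > 0)), 0)
  expect_true(all(diff(rows) <= 0))
})

test_that("a stem-only mask yields no leaves", {
  m <- matrix(FALSE, 400, 120)
  m[40:390, 57:63] <- TRUE
  org <- separate_tiller_organs(m)
  expect_length(org$leaves, 0)
  expect_equal(sum(org$stem), sum(m))
})

test_that("stem extraction recovers length and radius profiles", {
  cpp <- 0.05
  cal <- scale_calibration(cpp)
  # rectangle: 40 cm tall, half-width 0.4 cm
  H <- 900; W <- 100
  m <- matrix(FALSE, H, W)
  ji <- floor(40 / cpp); ri <- floor(0.4 / cpp)
  m[(H - ji):H, (50 - ri):(50 + ri)] <- TRUE
  st <- extract_stem(m, cal)
  expect_close(st$length, 40, 0.1)
  expect_close(st$radius_profile$r, 0.4 + cpp / 2, 0.05)

  # single-pixel column: radius = half a pixel pitch
  m1 <- matrix(FALSE, 200, 40)
  m1[20:180, 20] <- TRUE
  st1 <- extract_stem(m1, cal)
  expect_equal(unique(st1$radius_profile$r), cpp / 2)

  # linear taper: max error below one pixel pitch
  m2 <- matrix(FALSE, H, W)
  for (j in (H - ji):H) {
    z <- (H - j) * cpp
    r <- (0.5 - 0.3 * z / 40) / cpp
    m2[j, max(1, floor(50 - r)):min(W, ceiling(50 + r))] <- TRUE
  }
  st2 <- extract_stem(m2, cal)
  mid <- st2$radius_profile$z > 2 & st2$radius_profile$z < 38
  rp <- st2$radius_profile[mid, ]
  expect_lt(max(abs(rp$r - (0.5 - 0.3 * rp$z / 40))), 2 * cpp)
})

test_that("a horizontal straight leaf gives its node height and a flat midrib", {
  cpp <- 0.05
  cal <- scale_calibration(cpp)
  H <- 700; W <- 500
  m <- matrix(FALSE, H, W)
  m[(H - floor(30 / cpp)):H, 48:52] <- TRUE            # stem, base at bottom
  hrow <- H - floor(20 / cpp)                          # leaf at height 20
  m[(hrow - 3):(hrow + 3), 53:453] <- TRUE             # horizontal blade
  org <- separate_tiller_organs(m)
  expect_length(org$leaves, 1)
  frame <- riceCanopy:::tiller_frame(org$stem, cal)
  res <- extract_leaf_midrib(org$leaves[[1]], cal, frame)
  expect_close(res$node_image[2], 20, 0.3)
  expect_close(res$midrib2d$points$y, 0, 0.3)          # flat after the node shift
  expect_close(res$midrib2d$length, 400 * cpp, 1)
})

test_that("midrib extraction needs at least 3 bins", {
  cal <- scale_calibration(0.05)
  m <- matrix(FALSE, 100, 100)
  m[50:60, 50] <- TRUE
  frame <- function(xy) data.frame(u = xy$x, v = xy$y)
  expect_error(extract_leaf_midrib(m, cal, frame), "3 midrib bins")
})

test_that("known midrib quadratics are recovered from a rendered tiller", {
  # gentle curvature: the quadratic parameter stays close to arc length, so
  # the refit coefficients are directly comparable
  st <- vertical_stem(50, 0.3)
  st$cc_points <- data.frame(r = c(0.3, 0.3), a = c(0, 0), h = c(10, 40))
  fit <- c(0.002, sin(0.6), 0, -0.004, cos(0.6), 0)
  lf <- placed_leaf(fit, 28, lanceolate_coef_test(0.8, 28))
  lf$node_image <- c(0.3, 30)
  tl <- tiller(st, list(lf))
  r <- render_tiller_image(tl, render_spec(cm_per_px = 0.04))
  res <- analyze_tiller_image(r$image, r$cal)
  expect_length(res$leaves, 1)
  got <- res$leaves[[1]]$midrib2d$fit
  for (nm in c("b1", "b2"))
    expect_lt(abs(got[[nm]] - fit[match(nm, c("a1","b1","c1","a2","b2","c2"))]) /
                abs(fit[match(nm, c("a1","b1","c1","a2","b2","c2"))]), 0.05)
  # the measured length is arc length minus the corridor trim; compare with
  # the analytic arc length of the generating curve
  lg <- seq(0, 28, length.out = 2000)
  arc <- sum(sqrt(diff(0.002 * lg^2 + sin(0.6) * lg)^2 +
                    diff(-0.004 * lg^2 + cos(0.6) * lg)^2))
  expect_lt(abs(res$leaves[[1]]$midrib2d$length - arc) / arc, 0.05)
  # base angle against the analytic tangent of the generating curve
  truth <- leaf_angles(lf$midrib2d)
  expect_lt(abs(res$leaves[[1]]$angles[["base"]] - truth[["base"]]) * 180 / pi, 2)
})
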