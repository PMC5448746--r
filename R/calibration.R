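# Pixel -> real-world calibration.
#
# The camera bench is calibrated with a printed grid: each grid intersection
# gives a correspondence between a pixel position (i = column, j = row) and a
# real position (x, y) in cm. A binary-quadratic map per axis,
#
#   x = a1 i^2 + b1 i j + c1 j^2 + d1 i + e1 j + f1
#   y = a2 i^2 + b2 i j + c2 j^2 + d2 i + e2 j + f2
#
# absorbs scale, rotation, offset and mild lens/perspective distortion.

cal_coef_names <- c("a1", "b1", "c1", "d1", "e1", "f1",
                    "a2", "b2", "c2", "d2", "e2", "f2")

#' Fit the pixel-to-real calibration map
#'
#' Least-squares fit of the 12 binary-quadratic coefficients to grid
#' correspondences. The design is centred and scaled internally so the fit is
#' well conditioned even for pixel indices in the thousands; returned
#' coefficients are on the raw pixel scale.
#'
#' @param correspondences data.frame with columns `i`, `j` (pixel column and
#'   row) and `x`, `y` (cm). At least 6 non-degenerate points.
#' @return an object of class `calibration_model`: the named 12-coefficient
#'   vector plus the per-axis and overall residual RMSE (cm).
#' @export
fit_calibration <- function(correspondences) {
  d <- as.data.frame(correspondences)
  if (!all(c("i", "j", "x", "y") %in% names(d)))
    stopf("correspondences need columns i, j, x, y")
  if (nrow(d) < 6) stopf("need at least 6 correspondences, got %d", nrow(d))

  # scale pixels into [-1, 1]-ish for conditioning
  ci <- mean(range(d$i)); cj <- mean(range(d$j))
  si <- max(abs(d$i - ci), 1); sj <- max(abs(d$j - cj), 1)
  u <- (d$i - ci) / si; v <- (d$j - cj) / sj
  X <- cbind(u^2, u * v, v^2, u, v, 1)
  qx <- qr(X)
  if (qx$rank < 6)
    stopf("rank-deficient calibration design: grid points are degenerate/collinear")
  bu_x <- qr.coef(qx, d$x)
  bu_y <- qr.coef(qx, d$y)

  # map scaled-coordinate coefficients back to raw (i, j)
  unscale <- function(b) {
    A <- b[1] / si^2; B <- b[2] / (si * sj); C <- b[3] / sj^2
    Dc <- b[4] / si - 2 * A * ci - B * cj
    E <- b[5] / sj - 2 * C * cj - B * ci
    F0 <- b[6] + A * ci^2 + B * ci * cj + C * cj^2 - b[4] * ci / si - b[5] * cj / sj
    c(A, B, C, Dc, E, F0)
  }
  coef <- c(unscale(bu_x), unscale(bu_y))
  names(coef) <- cal_coef_names
  cal <- structure(list(coef = coef), class = "calibration_model")

  pred <- pixel_to_real(cal, d$i, d$j)
  rmse_x <- sqrt(mean((pred$x - d$x)^2))
  rmse_y <- sqrt(mean((pred$y - d$y)^2))
  cal$rmse <- c(x = rmse_x, y = rmse_y, total = sqrt(mean((pred$x - d$x)^2 + (pred$y - d$y)^2)))

  # injectivity check over the fitted grid: the Jacobian determinant must keep
  # one sign (the map must not fold within the calibrated region)
  jac <- with(as.list(coef), {
    fx_i <- 2 * a1 * d$i + b1 * d$j + d1
    fx_j <- b1 * d$i + 2 * c1 * d$j + e1
    fy_i <- 2 * a2 * d$i + b2 * d$j + d2
    fy_j <- b2 * d$i + 2 * c2 * d$j + e2
    fx_i * fy_j - fx_j * fy_i
  })
  if (any(jac == 0) || length(unique(sign(jac))) > 1)
    warning("calibration map folds within the fitted grid (non-injective)")
  cal
}

#' Build a calibration model from known coefficients
#'
#' @param coef numeric length-12 vector in the order
#'   `a1,b1,c1,d1,e1,f1,a2,b2,c2,d2,e2,f2`.
#' @return a `calibration_model`.
#' @export
calibration_model <- function(coef) {
  coef <- as.numeric(coef)
  if (length(coef) != 12) stopf("calibration needs 12 coefficients")
  names(coef) <- cal_coef_names
  structure(list(coef = coef, rmse = c(x = 0, y = 0, total = 0)),
            class = "calibration_model")
}

#' Identity-scale calibration
#'
#' The axis-aligned special case used by the renderers: `x = cm_per_px * i +
#' x0`, `y = -cm_per_px * j + y0` (pixel rows run downwards, the real frame is
#' y-up).
#'
#' @param cm_per_px pixel pitch (cm).
#' @param x0,y0 real-frame offsets (cm).
#' @param flip_y if `FALSE`, y increases with the pixel row instead.
#' @return a `calibration_model`.
#' @export
scale_calibration <- function(cm_per_px, x0 = 0, y0 = 0, flip_y = TRUE) {
  ey <- if (flip_y) -cm_per_px else cm_per_px
  calibration_model(c(0, 0, 0, cm_per_px, 0, x0, 0, 0, 0, 0, ey, y0))
}

#' Apply the calibration map
#'
#' @param cal a `calibration_model`.
#' @param i,j pixel columns and rows (vectors of equal length).
#' @return data.frame with columns `x`, `y` (cm).
#' @export
pixel_to_real <- function(cal, i, j) {
  stopifnot(inherits(cal, "calibration_model"))
  co <- cal$coef
  data.frame(
    x = co["a1"] * i^2 + co["b1"] * i * j + co["c1"] * j^2 + co["d1"] * i + co["e1"] * j + co["f1"],
    y = co["a2"] * i^2 + co["b2"] * i * j + co["c2"] * j^2 + co["d2"] * i + co["e2"] * j + co["f2"],
    row.names = NULL)
}

#' Pixel pitch of a calibration, in cm per pixel
#'
#' Local scale of the map (mean absolute singular value of the Jacobian) at a
#' reference pixel; used as the natural resolution bound epsilon for the
#' width/height binning operators.
#'
#' @param cal a `calibration_model`.
#' @param i,j reference pixel (defaults to the origin).
#' @return scalar cm-per-pixel estimate.
#' @export
calibration_pitch <- function(cal, i = 0, j = 0) {
  co <- cal$coef
  J <- matrix(c(2 * co["a1"] * i + co["b1"] * j + co["d1"],
                co["b1"] * i + 2 * co["c1"] * j + co["e1"],
                2 * co["a2"] * i + co["b2"] * j + co["d2"],
                co["b2"] * i + 2 * co["c2"] * j + co["e2"]),
              2, 2, byrow = TRUE)
  mean(svd(J)$d)
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("<calibration_model> pixel -> cm binary-quadratic map\n")
  print(signif(x$coef, 6))
  if (!is.null(x$rmse))
    cat(sprintf("fit RMSE: %.3g cm\n", x$rmse[["total"]]))
  invisible(x)
}

#' Write / read a calibration model as CSV
#'
#' Two-column `name,value` CSV holding the 12 coefficients (and the fit RMSE
#' if present).
#'
#' @param cal a `calibration_model`.
#' @param path file path.
#' @return `write_calibration` the path, invisibly; `read_calibration` a
#'   `calibration_model`.
#' @export
write_calibration <- function(cal, path) {
  df <- data.frame(name = names(cal$coef), value = fmt_num(cal$coef))
  if (!is.null(cal$rmse))
    df <- rbind(df, data.frame(name = "rmse", value = fmt_num(cal$rmse[["total"]])))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  df <- utils::read.csv(path, colClasses = c("character", "character"))
  v <- stats::setNames(as.numeric(df$value), df$name)
  if (!all(cal_coef_names %in% names(v)))
    stopf("calibration file '%s' lacks the 12 coefficients", path)
  cal <- calibration_model(v[cal_coef_names])
  if ("rmse" %in% names(v)) cal$rmse <- c(x = NA, y = NA, total = v[["rmse"]])
  cal
}
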