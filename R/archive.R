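# The digital-architecture archive dialect.
#
# Four UTF-8 comma-separated files with one header line, named after the
# deposited archive they mirror:
#
#   SystemData.csv  key,value                  planting/context parameters,
#                                              optional RNG seed and the 12
#                                              calibration coefficients
#   SSP_LCAA.csv    hill_rn,hill_cn,hill_x,hill_y,tiller,record,idx,v1..v7
#                   record = "stem"   : v1 = S_l, v2..v4 axis bottom,
#                                       v5..v7 axis top (NA if not fitted)
#                   record = "radius" : v1 = z, v2 = Sr(z)
#                   record = "cc"     : v1 = r, v2 = a, v3 = h
#                   record = "leaf"   : idx = leaf index, v1 = theta,
#                                       v2,v3 = node_image, v4..v6 = node3d
#   leafvein.csv    hill_rn,hill_cn,tiller,leaf,kind,l,x,y,
#                   a1,b1,c1,a2,b2,c2,length
#                   kind = "fit" rows carry the quadratic coefficients and the
#                   arc length; kind = "point" rows carry binned observations
#   leafshape.csv   hill_rn,hill_cn,tiller,leaf,kind,l,halfwidth,c0..c6
#                   kind = "fit" carries the ascending polynomial
#                   coefficients; kind = "sample" the half-width samples
#
# Angles are radians, lengths cm. Derived 3D curves (midrib3d, edges3d) are
# not stored; reconstruct_architecture() recreates them deterministically.

archive_files <- c("SystemData.csv", "SSP_LCAA.csv", "leafvein.csv", "leafshape.csv")

#' Write a digital architecture archive
#'
#' Serializes an architecture to the four-file CSV dialect documented in this
#' package (mirroring the SystemData / SSP_LCAA / leafvein / leafshape file
#' set). Numeric fields keep 17 significant digits so a round trip is lossless
#' well below 1e-6 cm.
#'
#' @param arch a [digital_architecture()].
#' @param path directory to write into (created if missing).
#' @param extra named list of additional scalars for SystemData.csv
#'   (e.g. `seed`, calibration coefficients as `cal_a1` ...).
#' @return invisibly, the paths of the four files.
#' @export
write_archive <- function(arch, path, extra = list()) {
  validate_architecture(arch)
  if (!dir.exists(path) &&
      !dir.create(path, recursive = TRUE, showWarnings = FALSE))
    stopf("cannot create archive directory '%s'", path)

  ctx <- arch$context
  sys_keys <- c(list(rs = ctx$spec$rs, ps = ctx$spec$ps, pm = ctx$pm,
                     plantnum = ctx$plantnum, rows = ctx$rows, cols = ctx$cols),
                extra)
  sysdat <- data.frame(key = names(sys_keys),
                       value = vapply(sys_keys, fmt_num, ""))

  ssp <- list(); vein <- list(); shape <- list()
  for (h in arch$hills) {
    rn <- h$position$rn; cn <- h$position$cn
    for (ti in seq_along(h$tillers)) {
      tl <- h$tillers[[ti]]
      st <- tl$stem
      row7 <- function(record, idx, v) {
        v <- c(v, rep(NA_real_, 7 - length(v)))
        data.frame(hill_rn = rn, hill_cn = cn, hill_x = h$origin[1],
                   hill_y = h$origin[2], tiller = ti, record = record,
                   idx = idx, v1 = v[1], v2 = v[2], v3 = v[3], v4 = v[4],
                   v5 = v[5], v6 = v[6], v7 = v[7])
      }
      ssp[[length(ssp) + 1L]] <- row7("stem", 0L,
        c(st$length, st$axis_bottom %||% rep(NA_real_, 3),
          st$axis_top %||% rep(NA_real_, 3)))
      for (j in seq_len(nrow(st$radius_profile)))
        ssp[[length(ssp) + 1L]] <-
          row7("radius", j, c(st$radius_profile$z[j], st$radius_profile$r[j]))
      if (!is.null(st$cc_points))
        for (j in seq_len(nrow(st$cc_points)))
          ssp[[length(ssp) + 1L]] <-
            row7("cc", j, c(st$cc_points$r[j], st$cc_points$a[j], st$cc_points$h[j]))
      for (li in seq_along(tl$leaves)) {
        lf <- tl$leaves[[li]]
        ssp[[length(ssp) + 1L]] <- row7("leaf", li,
          c(lf$azimuth, lf$node_image, lf$node3d %||% rep(NA_real_, 3)))
        vrow <- function(kind, l = NA_real_, x = NA_real_, y = NA_real_,
                         fit = rep(NA_real_, 6), len = NA_real_)
          data.frame(hill_rn = rn, hill_cn = cn, tiller = ti, leaf = li,
                     kind = kind, l = l, x = x, y = y,
                     a1 = fit[1], b1 = fit[2], c1 = fit[3],
                     a2 = fit[4], b2 = fit[5], c2 = fit[6], length = len)
        vein[[length(vein) + 1L]] <-
          vrow("fit", fit = lf$midrib2d$fit, len = lf$midrib2d$length)
        if (!is.null(lf$midrib2d$points) && nrow(lf$midrib2d$points) > 0)
          for (j in seq_len(nrow(lf$midrib2d$points)))
            vein[[length(vein) + 1L]] <-
              vrow("point", l = lf$midrib2d$points$l[j] %||% NA_real_,
                   x = lf$midrib2d$points$x[j], y = lf$midrib2d$points$y[j])
        srow <- function(kind, l = NA_real_, hw = NA_real_, coef = rep(NA_real_, 7)) {
          d <- data.frame(hill_rn = rn, hill_cn = cn, tiller = ti, leaf = li,
                          kind = kind, l = l, halfwidth = hw)
          d[paste0("c", 0:6)] <- as.list(coef)
          d
        }
        shape[[length(shape) + 1L]] <- srow("fit", coef = lf$shape$coef)
        for (j in seq_len(nrow(lf$shape$samples)))
          shape[[length(shape) + 1L]] <-
            srow("sample", l = lf$shape$samples$l[j],
                 hw = lf$shape$samples$halfwidth[j])
      }
    }
  }

  empty_ssp <- data.frame(hill_rn = integer(), hill_cn = integer(),
                          hill_x = numeric(), hill_y = numeric(),
                          tiller = integer(), record = character(), idx = integer(),
                          v1 = numeric(), v2 = numeric(), v3 = numeric(),
                          v4 = numeric(), v5 = numeric(), v6 = numeric(),
                          v7 = numeric())
  empty_vein <- data.frame(hill_rn = integer(), hill_cn = integer(),
                           tiller = integer(), leaf = integer(), kind = character(),
                           l = numeric(), x = numeric(), y = numeric(),
                           a1 = numeric(), b1 = numeric(), c1 = numeric(),
                           a2 = numeric(), b2 = numeric(), c2 = numeric(),
                           length = numeric())
  empty_shape <- local({
    d <- data.frame(hill_rn = integer(), hill_cn = integer(), tiller = integer(),
                    leaf = integer(), kind = character(), l = numeric(),
                    halfwidth = numeric())
    for (nm in paste0("c", 0:6)) d[[nm]] <- numeric()
    d
  })
  bind <- function(lst, empty) if (length(lst)) do.call(rbind, lst) else empty

  out <- file.path(path, archive_files)
  write_num_csv(sysdat, out[1])
  write_num_csv(bind(ssp, empty_ssp), out[2])
  write_num_csv(bind(vein, empty_vein), out[3])
  write_num_csv(bind(shape, empty_shape), out[4])
  invisible(out)
}

fmt_num <- function(x) {
  if (is.numeric(x)) format(x, digits = 17, scientific = TRUE, trim = TRUE)
  else as.character(x)
}

write_num_csv <- function(df, path) {
  for (nm in names(df))
    if (is.double(df[[nm]])) df[[nm]] <- vapply(df[[nm]], fmt_num, "")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
}

#' Read a digital architecture archive
#'
#' Reads the four-file CSV dialect written by [write_archive()] from a
#' directory or a zip file, relinks the records and validates every invariant.
#'
#' @param path directory or `.zip` file containing the four archive files.
#' @return a [digital_architecture()]. The SystemData scalars beyond the
#'   context (seed, calibration coefficients, ...) are attached as the
#'   `"system_data"` attribute.
#' @export
read_archive <- function(path) {
  if (!dir.exists(path)) {
    if (file.exists(path) && grepl("\\.zip$", path, ignore.case = TRUE)) {
      exdir <- tempfile("archive")
      utils::unzip(path, exdir = exdir)
      # tolerate a single top-level directory inside the zip
      if (!file.exists(file.path(exdir, archive_files[1]))) {
        sub <- list.dirs(exdir, recursive = FALSE)
        if (length(sub) == 1L) exdir <- sub
      }
      path <- exdir
    } else stopf("archive path '%s' does not exist", path)
  }
  missing <- archive_files[!file.exists(file.path(path, archive_files))]
  if (length(missing))
    stopf("archive is missing file kind(s): %s", paste(missing, collapse = ", "))

  sysdat <- utils::read.csv(file.path(path, "SystemData.csv"),
                            colClasses = c("character", "character"))
  sysv <- stats::setNames(suppressWarnings(as.numeric(sysdat$value)), sysdat$key)
  need <- c("rs", "ps", "pm", "plantnum", "rows", "cols")
  if (any(!need %in% names(sysv)) || any(is.na(sysv[need])))
    stopf("SystemData.csv must define numeric %s", paste(need, collapse = ", "))
  ctx <- canopy_context(sysv["pm"], sysv["plantnum"], sysv["rows"], sysv["cols"],
                        planting_spec(sysv["rs"], sysv["ps"]))

  ssp <- utils::read.csv(file.path(path, "SSP_LCAA.csv"))
  vein <- utils::read.csv(file.path(path, "leafvein.csv"))
  shape <- utils::read.csv(file.path(path, "leafshape.csv"))

  hills <- list()
  if (nrow(ssp)) {
    hk <- unique(ssp[c("hill_rn", "hill_cn", "hill_x", "hill_y")])
    hk <- hk[order(hk$hill_rn, hk$hill_cn), ]
    for (i in seq_len(nrow(hk))) {
      rn <- hk$hill_rn[i]; cn <- hk$hill_cn[i]
      hs <- ssp[ssp$hill_rn == rn & ssp$hill_cn == cn, ]
      tillers <- list()
      for (ti in sort(unique(hs$tiller))) {
        ts <- hs[hs$tiller == ti, ]
        id <- sprintf("hill (%d,%d) tiller %d", rn, cn, ti)
        srow <- ts[ts$record == "stem", ]
        if (nrow(srow) != 1L) stopf("%s: expected exactly one stem row", id)
        rad <- ts[ts$record == "radius", ]
        rad <- rad[order(rad$idx), ]
        if (nrow(rad) > 1 && any(diff(rad$v1) <= 0))
          validation_error("%s: radius profile z grid is not strictly increasing", id)
        cc <- ts[ts$record == "cc", ]
        cc <- if (nrow(cc)) data.frame(r = cc$v1, a = cc$v2, h = cc$v3)[order(cc$idx), ] else NULL
        ab <- unlist(srow[c("v2", "v3", "v4")], use.names = FALSE)
        at <- unlist(srow[c("v5", "v6", "v7")], use.names = FALSE)
        stem <- stem_record(srow$v1, data.frame(z = rad$v1, r = rad$v2), cc,
                            if (!anyNA(ab)) ab else NULL,
                            if (!anyNA(at)) at else NULL)
        leaves <- list()
        lrows <- ts[ts$record == "leaf", ]
        lrows <- lrows[order(lrows$idx), ]
        for (k in seq_len(nrow(lrows))) {
          li <- lrows$idx[k]
          lid <- sprintf("%s leaf %d", id, li)
          vf <- vein[vein$hill_rn == rn & vein$hill_cn == cn &
                       vein$tiller == ti & vein$leaf == li, ]
          sf <- shape[shape$hill_rn == rn & shape$hill_cn == cn &
                        shape$tiller == ti & shape$leaf == li, ]
          fitrow <- vf[vf$kind == "fit", ]
          if (nrow(fitrow) != 1L) stopf("%s: missing midrib fit row", lid)
          pts <- vf[vf$kind == "point", c("l", "x", "y")]
          coefrow <- sf[sf$kind == "fit", ]
          if (nrow(coefrow) != 1L) stopf("%s: missing shape fit row", lid)
          samp <- sf[sf$kind == "sample", c("l", "halfwidth")]
          if (nrow(samp) < 2) stopf("%s: needs >= 2 shape samples", lid)
          if (samp$l[1] < 0 || any(diff(samp$l) <= 0))
            validation_error("%s: shape l grid is not strictly increasing", lid)
          node3d <- unlist(lrows[k, c("v4", "v5", "v6")], use.names = FALSE)
          leaves[[length(leaves) + 1L]] <- leaf_record(
            azimuth = lrows$v1[k],
            node_image = c(lrows$v2[k], lrows$v3[k]),
            shape = leaf_shape_profile(samp, unlist(coefrow[paste0("c", 0:6)])),
            midrib2d = midrib_curve2d(unlist(fitrow[c("a1", "b1", "c1", "a2", "b2", "c2")]),
                                      fitrow$length,
                                      if (nrow(pts)) pts else NULL),
            node3d = if (!anyNA(node3d)) node3d else NULL)
        }
        tillers[[length(tillers) + 1L]] <- tiller(stem, leaves)
      }
      hills[[length(hills) + 1L]] <- list(position = hill_position(rn, cn),
                                          origin = c(hk$hill_x[i], hk$hill_y[i]),
                                          tillers = tillers)
    }
  }
  arch <- digital_architecture(ctx, hills)
  validate_architecture(arch)
  attr(arch, "system_data") <- sysv[setdiff(names(sysv), need)]
  arch
}
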