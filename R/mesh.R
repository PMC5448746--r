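# Renderable scene geometry: stems as closed cylinders, leaves as quad-strip
# wireframe surfaces between the two blade margins.

canopy_mesh <- function(vertices, faces, labels) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(faces) && (min(faces) < 1 || max(faces) > nrow(vertices)))
    stopf("mesh face indices out of range")
  structure(list(vertices = vertices, faces = faces, labels = labels),
            class = "canopy_mesh")
}

#' @export
print.canopy_mesh <- function(x, ...) {
  cat(sprintf("<canopy_mesh> %d vertices, %d triangles, %d parts\n",
              nrow(x$vertices), nrow(x$faces), length(unique(x$labels))))
  invisible(x)
}

# orthonormal basis perpendicular to a unit axis
perp_basis <- function(d) {
  a <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- a - sum(a * d) * d
  u <- u / norm3(u)
  v <- c(d[2] * u[3] - d[3] * u[2], d[3] * u[1] - d[1] * u[3],
         d[1] * u[2] - d[2] * u[1])
  list(u = u, v = v)
}

cylinder_mesh <- function(bottom, top, radius, segments) {
  d <- unit3(top - bottom)
  b <- perp_basis(d)
  ang <- 2 * pi * (seq_len(segments) - 1) / segments
  ring <- t(vapply(ang, function(a) radius * (cos(a) * b$u + sin(a) * b$v),
                   numeric(3)))
  verts <- rbind(sweep(ring, 2, bottom, `+`), sweep(ring, 2, top, `+`),
                 bottom, top)
  cb <- 2L * segments + 1L; ct <- 2L * segments + 2L
  fac <- NULL
  for (k in seq_len(segments)) {
    k2 <- if (k == segments) 1L else k + 1L
    fac <- rbind(fac,
                 c(k, k2, segments + k),             # side
                 c(k2, segments + k2, segments + k), # side
                 c(cb, k2, k),                       # bottom cap
                 c(ct, segments + k, segments + k2)) # top cap
  }
  list(vertices = verts, faces = fac)
}

leaf_strip_mesh <- function(edges3d) {
  e1 <- edges3d[[1]]; e2 <- edges3d[[2]]
  n <- nrow(e1)
  verts <- rbind(as.matrix(e1[c("x", "y", "z")]), as.matrix(e2[c("x", "y", "z")]))
  fac <- NULL
  for (k in seq_len(n - 1)) {
    fac <- rbind(fac,
                 c(k, k + 1L, n + k),
                 c(k + 1L, n + k + 1L, n + k))
  }
  list(vertices = verts, faces = fac)
}

#' Build a renderable scene from a reconstructed architecture
#'
#' One closed cylinder per stem (radius = mean of the radius profile) and one
#' triangulated quad strip per leaf, hills placed on the planting grid.
#'
#' @param arch a reconstructed [digital_architecture()] (see
#'   [reconstruct_architecture()]).
#' @param cylinder_segments segments around each stem cylinder.
#' @param leaf_samples midrib samples per leaf if edges must be (re)sampled.
#' @return a `canopy_mesh` with part labels like `"h1.1_t2_stem"` /
#'   `"h1.1_t2_leaf3"`.
#' @export
build_scene <- function(arch, cylinder_segments = 12L, leaf_samples = 100L) {
  verts <- NULL; faces <- NULL; labels <- character()
  add_part <- function(part, label) {
    off <- if (is.null(verts)) 0L else nrow(verts)
    verts <<- rbind(verts, part$vertices)
    faces <<- rbind(faces, part$faces + off)
    labels <<- c(labels, rep(label, nrow(part$faces)))
  }
  for (h in arch$hills) {
    o3 <- c(h$origin, 0)
    hid <- sprintf("h%d.%d", h$position$rn, h$position$cn)
    for (ti in seq_along(h$tillers)) {
      tl <- h$tillers[[ti]]
      st <- tl$stem
      if (is.null(st$axis_bottom) || is.null(st$axis_top))
        stopf("%s tiller %d has no 3D axis; run reconstruct_architecture first", hid, ti)
      cyl <- cylinder_mesh(st$axis_bottom + o3, st$axis_top + o3,
                           mean(st$radius_profile$r), cylinder_segments)
      add_part(cyl, sprintf("%s_t%d_stem", hid, ti))
      for (li in seq_along(tl$leaves)) {
        lf <- tl$leaves[[li]]
        ed <- lf$edges3d
        if (is.null(ed)) {
          if (is.null(lf$node3d))
            stopf("%s tiller %d leaf %d not reconstructed; run reconstruct_architecture first",
                  hid, ti, li)
          m3 <- midrib_3d(lf$midrib2d, lf$azimuth, lf$node3d, st, leaf_samples)
          ed <- leaf_edges_3d(m3, lf$shape)
        }
        ed <- lapply(ed, function(e) {
          e$x <- e$x + o3[1]; e$y <- e$y + o3[2]; e
        })
        add_part(leaf_strip_mesh(ed), sprintf("%s_t%d_leaf%d", hid, ti, li))
      }
    }
  }
  if (is.null(verts)) verts <- matrix(numeric(), ncol = 3)
  if (is.null(faces)) faces <- matrix(integer(), ncol = 3)
  canopy_mesh(verts, faces, labels)
}

#' Export a mesh to Wavefront OBJ or ASCII PLY
#'
#' @param mesh a `canopy_mesh`.
#' @param path output file.
#' @param format `"obj"` or `"ply"`.
#' @return invisibly, `path`.
#' @export
export_mesh <- function(mesh, path, format = c("obj", "ply")) {
  format <- match.arg(format)
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(x) format(x, digits = 10, trim = TRUE, scientific = FALSE)
  if (format == "obj") {
    writeLines("# riceCanopy scene", con)
    if (nrow(v))
      writeLines(paste("v", fmt(v[, 1]), fmt(v[, 2]), fmt(v[, 3])), con)
    if (nrow(f)) {
      lab <- mesh$labels
      for (g in unique(lab)) {
        writeLines(paste("g", g), con)
        ff <- f[lab == g, , drop = FALSE]
        writeLines(paste("f", ff[, 1], ff[, 2], ff[, 3]), con)
      }
    }
  } else {
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(v)),
                 "property float x", "property float y", "property float z",
                 sprintf("element face %d", nrow(f)),
                 "property list uchar int vertex_indices", "end_header"), con)
    if (nrow(v))
      writeLines(paste(fmt(v[, 1]), fmt(v[, 2]), fmt(v[, 3])), con)
    if (nrow(f))
      writeLines(paste(3, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  }
  invisible(path)
}

#' Read back a Wavefront OBJ file
#'
#' Minimal reader for the v/f/g subset written by [export_mesh()]; intended
#' for round-trip checks and quick inspection.
#'
#' @param path OBJ file.
#' @return a `canopy_mesh`.
#' @export
read_obj <- function(path) {
  lines <- readLines(path)
  vl <- grep("^v ", lines, value = TRUE)
  fl <- grep("^f ", lines, value = TRUE)
  verts <- if (length(vl))
    do.call(rbind, lapply(strsplit(vl, "\\s+"), function(p) as.numeric(p[2:4])))
  else matrix(numeric(), ncol = 3)
  faces <- if (length(fl))
    do.call(rbind, lapply(strsplit(fl, "\\s+"), function(p)
      as.integer(sub("/.*", "", p[2:4]))))
  else matrix(integer(), ncol = 3)
  gl <- grep("^(g|f) ", lines, value = TRUE)
  labels <- character(0)
  cur <- "default"
  for (ln in gl) {
    if (startsWith(ln, "g ")) cur <- sub("^g ", "", ln)
    else labels <- c(labels, cur)
  }
  canopy_mesh(verts, faces, labels)
}
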