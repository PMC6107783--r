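# Triangulated closed surface of the lumen: tube wall swept along the
# centerline frames plus fan-capped inlet/outlet discs. Stand-in for a
# segmented arterial surface.

#' Triangulate the lumen surface
#'
#' Builds a watertight, outward-oriented triangulation of the vessel
#' surface: circumferential rings of `circumferential_n` vertices at axial
#' stations spaced by `axial_spacing`, closed by fan caps at both ends.
#' Cross-sections are circles of the local radius profile.
#'
#' @param geometry a `vessel_geometry`
#' @param circumferential_n vertices per ring (>= 8)
#' @param axial_spacing target axial distance between rings (mm)
#' @return object of class `surface_mesh` with `vertices` (n x 3, mm) and
#'   `faces` (m x 3 vertex indices, outward orientation)
#' @export
surface_mesh <- function(geometry, circumferential_n = 32,
                         axial_spacing = 0.5) {
  nc <- as.integer(circumferential_n)
  if (nc < 8) stop("circumferential_n must be >= 8")
  L <- geometry$total_length
  if (!is.finite(axial_spacing) || axial_spacing <= 0 || axial_spacing >= L) {
    stop("axial_spacing must be in (0, vessel length)")
  }
  ns <- max(2L, as.integer(ceiling(L / axial_spacing)) + 1L)
  s <- seq(0, L, length.out = ns)
  fr <- centerline_at(geometry, s)
  r <- radius_at(geometry, s)
  th <- 2 * pi * (seq_len(nc) - 1) / nc

  verts <- matrix(0, ns * nc + 2, 3)
  for (i in seq_len(ns)) {
    ring <- fr$position[rep(i, nc), , drop = FALSE] +
      r[i] * (cos(th) %o% fr$normal[i, ] + sin(th) %o% fr$binormal[i, ])
    verts[(i - 1) * nc + seq_len(nc), ] <- ring
  }
  c_in <- ns * nc + 1L   # inlet cap center
  c_out <- ns * nc + 2L  # outlet cap center
  verts[c_in, ] <- fr$position[1, ]
  verts[c_out, ] <- fr$position[ns, ]

  idx <- function(i, j) (i - 1L) * nc + ((j - 1L) %% nc) + 1L
  faces <- vector("list", (ns - 1) * nc * 2 + 2 * nc)
  k <- 0L
  for (i in seq_len(ns - 1L)) {
    for (j in seq_len(nc)) {
      a <- idx(i, j); b <- idx(i, j + 1L)
      c2 <- idx(i + 1L, j); d <- idx(i + 1L, j + 1L)
      k <- k + 1L; faces[[k]] <- c(a, b, d)
      k <- k + 1L; faces[[k]] <- c(a, d, c2)
    }
  }
  for (j in seq_len(nc)) {  # inlet cap, normal pointing upstream
    k <- k + 1L; faces[[k]] <- c(c_in, idx(1L, j + 1L), idx(1L, j))
  }
  for (j in seq_len(nc)) {  # outlet cap, normal pointing downstream
    k <- k + 1L; faces[[k]] <- c(c_out, idx(ns, j), idx(ns, j + 1L))
  }
  faces <- do.call(rbind, faces)
  sm <- structure(list(vertices = verts, faces = faces),
                  class = "surface_mesh")
  if (surface_volume(sm) < 0) sm$faces <- sm$faces[, c(1, 3, 2)]
  sm
}

#' Enclosed volume of a closed triangulated surface
#'
#' Divergence-theorem volume: sum of signed tetrahedron volumes spanned by
#' the origin and each outward-oriented face. Positive for an
#' outward-oriented closed surface.
#'
#' @param surface a `surface_mesh`
#' @return volume (mm^3)
#' @export
surface_volume <- function(surface) {
  v <- surface$vertices; f <- surface$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c2 <- v[f[, 3], , drop = FALSE]
  cr <- cbind(b[, 2] * c2[, 3] - b[, 3] * c2[, 2],
              b[, 3] * c2[, 1] - b[, 1] * c2[, 3],
              b[, 1] * c2[, 2] - b[, 2] * c2[, 1])
  sum(rowSums(a * cr)) / 6
}

#' Euler characteristic of a triangulated surface
#'
#' `V - E + F`; 2 for any closed surface of sphere topology (a watertight
#' tube with caps).
#'
#' @param surface a `surface_mesh`
#' @return integer Euler characteristic
#' @export
euler_characteristic <- function(surface) {
  f <- surface$faces
  edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  edges <- unique(cbind(pmin(edges[, 1], edges[, 2]),
                        pmax(edges[, 1], edges[, 2])))
  nrow(unique(matrix(surface$vertices[unique(as.vector(f)), ], ncol = 3))) -
    nrow(edges) + nrow(f)
}

#' Export a surface to STL
#'
#' @param surface a `surface_mesh`
#' @param path output `.stl` file
#' @param binary write binary STL (default `FALSE` = ASCII)
#' @return `path`, invisibly
#' @export
write_stl <- function(surface, path, binary = FALSE) {
  v <- surface$vertices; f <- surface$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c2 <- v[f[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c2 - a
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
  nrm <- nrm / len
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(c(nrm[i, ], a[i, ], b[i, ], c2[i, ])), con,
               size = 4, endian = "little")
      writeBin(as.integer(0), con, size = 2, endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid vessel", con)
    tri <- sprintf(
      "facet normal %e %e %e\n outer loop\n  vertex %e %e %e\n  vertex %e %e %e\n  vertex %e %e %e\n endloop\nendfacet",
      nrm[, 1], nrm[, 2], nrm[, 3], a[, 1], a[, 2], a[, 3],
      b[, 1], b[, 2], b[, 3], c2[, 1], c2[, 2], c2[, 3])
    writeLines(tri, con)
    writeLines("endsolid vessel", con)
  }
  invisible(path)
}

#' Export a surface to legacy VTK PolyData (ASCII)
#'
#' @param surface a `surface_mesh`
#' @param path output `.vtk` file
#' @return `path`, invisibly
#' @export
write_vtk_polydata <- function(surface, path) {
  v <- surface$vertices; f <- surface$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "stenoflow surface", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d double", nrow(v))), con)
  writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("POLYGONS %d %d", nrow(f), 4L * nrow(f)), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L),
             con)
  invisible(path)
}
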