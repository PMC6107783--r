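# Volumetric meshing of the vessel lumen. Strategy: a boundary-fitted
# structured template swept along the centerline (polar cross-sections with
# radially graded near-wall rings emulating prismatic boundary layers),
# extruded into triangular prisms and subdivided into tetrahedra with the
# minimal-global-index diagonal rule, which makes neighbouring prisms share
# quad-face diagonals and hence yields a conforming tetrahedral mesh.

# Radial ring fractions in (0, 1]: uniform core plus n_layers graded
# boundary-layer rings whose thickness shrinks toward the wall by
# 1/growth_ratio per layer (thinnest at the wall).
.ring_fractions <- function(m_core, n_layers, growth_ratio, bl_fraction) {
  if (n_layers == 0) return(seq_len(m_core) / m_core)
  core <- seq_len(m_core) / m_core * (1 - bl_fraction)
  g <- growth_ratio
  t_wall <- if (g == 1) bl_fraction / n_layers else
    bl_fraction * (g - 1) / (g^n_layers - 1)
  thick <- t_wall * g^((n_layers - 1):0)  # from core side toward the wall
  c(core, (1 - bl_fraction) + cumsum(thick))
}

# Cross-section triangulation shared by every axial station: local node 1 is
# the centerline node, then ring r (1..m) node j (1..nc) at index
# 1 + (r-1)*nc + j. Returns a T x 3 matrix of local indices.
.cross_section_triangles <- function(nc, m) {
  jj <- seq_len(nc)
  jn <- jj %% nc + 1L
  fan <- cbind(1L, 1L + jj, 1L + jn)
  tris <- list(fan)
  for (r in seq_len(m - 1)) {
    a <- 1L + (r - 1L) * nc + jj
    b <- 1L + (r - 1L) * nc + jn
    c2 <- 1L + r * nc + jj
    d <- 1L + r * nc + jn
    tris[[r + 1L]] <- rbind(cbind(a, b, d), cbind(a, d, c2))
  }
  do.call(rbind, tris)
}

# Split triangular prisms (columns v1..v6, v_{i+3} above v_i) into 3 tets
# each with the minimal-index diagonal rule. Vectorized over prisms.
.split_prisms <- function(P) {
  # rotations bringing vertex k to slot 1 while preserving the prism
  rot <- rbind(c(1, 2, 3, 4, 5, 6),
               c(2, 3, 1, 5, 6, 4),
               c(3, 1, 2, 6, 4, 5),
               c(4, 6, 5, 1, 3, 2),
               c(5, 4, 6, 2, 1, 3),
               c(6, 5, 4, 3, 2, 1))
  k <- max.col(-P, ties.method = "first")
  n <- nrow(P)
  V <- matrix(0L, n, 6)
  for (r in 1:6) {
    sel <- k == r
    if (any(sel)) V[sel, ] <- P[sel, rot[r, ], drop = FALSE]
  }
  # remaining free quad (V2,V3,V6,V5): diagonal through its smallest vertex
  caseA <- pmin(V[, 2], V[, 6]) < pmin(V[, 3], V[, 5])
  tets <- matrix(0L, 3L * n, 4)
  ia <- which(caseA); ib <- which(!caseA)
  if (length(ia)) {
    tets[3 * ia - 2, ] <- V[ia, c(1, 2, 3, 6), drop = FALSE]
    tets[3 * ia - 1, ] <- V[ia, c(1, 2, 6, 5), drop = FALSE]
    tets[3 * ia, ]     <- V[ia, c(1, 5, 6, 4), drop = FALSE]
  }
  if (length(ib)) {
    tets[3 * ib - 2, ] <- V[ib, c(1, 2, 3, 5), drop = FALSE]
    tets[3 * ib - 1, ] <- V[ib, c(1, 5, 3, 6), drop = FALSE]
    tets[3 * ib, ]     <- V[ib, c(1, 5, 6, 4), drop = FALSE]
  }
  tets
}

# Signed volumes of tets (columns of `cells` index rows of `nodes`).
.tet_volumes <- function(nodes, cells) {
  a <- nodes[cells[, 1], , drop = FALSE]
  b <- nodes[cells[, 2], , drop = FALSE] - a
  c2 <- nodes[cells[, 3], , drop = FALSE] - a
  d <- nodes[cells[, 4], , drop = FALSE] - a
  (b[, 1] * (c2[, 2] * d[, 3] - c2[, 3] * d[, 2]) -
     b[, 2] * (c2[, 1] * d[, 3] - c2[, 3] * d[, 1]) +
     b[, 3] * (c2[, 1] * d[, 2] - c2[, 2] * d[, 1])) / 6
}

#' Analytic lumen volume of a vessel geometry
#'
#' \eqn{\pi \int_0^L r(s)^2 \, ds} by composite Simpson quadrature on a
#' dense grid; the reference against which mesh density is measured.
#'
#' @param geometry a `vessel_geometry`
#' @return volume (mm^3)
#' @export
lumen_volume <- function(geometry) {
  n <- 4001L
  s <- seq(0, geometry$total_length, length.out = n)
  r2 <- radius_at(geometry, s)^2
  h <- s[2] - s[1]
  w <- rep(c(2, 4), length.out = n); w[1] <- 1; w[n] <- 1
  pi * sum(w * r2) * h / 3
}

#' Generate a tetrahedral volume mesh of the lumen
#'
#' Produces a conforming tetrahedral mesh with labelled `inlet`, `outlet`
#' and `wall` boundary patches and `n_wall_layers` radially graded rings of
#' cells adjacent to the wall (thinnest at the wall, growing inward by
#' `growth_ratio`). Resolution is chosen so that the achieved density
#' (cell count / analytic lumen volume) approximates `target_density`.
#'
#' @param geometry a `vessel_geometry`
#' @param target_density target average element density (elements per mm^3),
#'   default 200
#' @param n_wall_layers number of graded near-wall cell layers (default 5)
#' @param growth_ratio radial growth ratio of successive layer thicknesses
#'   away from the wall (default 1.2)
#' @param bl_fraction fraction of the local radius occupied by the graded
#'   near-wall band (default 0.3)
#' @param axial_aspect axial element length as a multiple of the transverse
#'   size (default 1.5)
#' @param resolution optional explicit resolution (a mesh's `$resolution`
#'   list with `nc`, `m_core`, `n_ax`), overriding the density search so a
#'   family of geometries shares one mesh topology (warm starts, sweeps)
#' @param axial_grading concentrate axial stations where the lumen narrows
#'   and through the post-stenotic recovery zone, emulating octree-style
#'   local refinement; uniform spacing for an unobstructed vessel
#'   (default `TRUE`)
#' @return an object of class `volume_mesh`
#' @export
generate_volume_mesh <- function(geometry, target_density = 200,
                                 n_wall_layers = 5, growth_ratio = 1.2,
                                 bl_fraction = 0.3, axial_aspect = 1.5,
                                 resolution = NULL, axial_grading = TRUE) {
  if (!inherits(geometry, "vessel_geometry")) stop("need a vessel_geometry")
  if (!is.finite(target_density) || target_density <= 0) {
    stop("target_density must be > 0")
  }
  n_wall_layers <- as.integer(n_wall_layers)
  if (n_wall_layers < 0) stop("n_wall_layers must be >= 0")
  L <- geometry$total_length
  sg <- seq(0, L, length.out = 801L)
  rg <- radius_at(geometry, sg)
  if (any(rg <= 0)) stop("geometry has non-positive radius")
  V <- lumen_volume(geometry)
  n_target <- target_density * V
  rbar <- mean(rg)

  counts <- function(h) {
    nc <- max(8L, as.integer(round(2 * pi * rbar / h)))
    m_core <- max(2L, as.integer(round((1 - bl_fraction) * rbar / h)))
    n_ax <- max(2L, as.integer(round(L / (axial_aspect * h))))
    m <- m_core + n_wall_layers
    list(nc = nc, m_core = m_core, m = m, n_ax = n_ax,
         cells = 3 * nc * (2L * m - 1L) * n_ax)
  }
  # minimum feasible mesh
  min_cells <- counts(1e9)$cells
  if (n_target < min_cells / 3) {
    stop("infeasible target density: ", target_density,
         " elements/mm^3 implies fewer cells than one coarse cross-section")
  }
  if (!is.null(resolution)) {
    best <- list(nc = as.integer(resolution$nc),
                 m_core = as.integer(resolution$m_core),
                 n_ax = as.integer(resolution$n_ax))
    best$m <- best$m_core + n_wall_layers
    best$cells <- 3L * best$nc * (2L * best$m - 1L) * best$n_ax
  } else {
    # continuous estimate then local scan for the closest integer realization
    h0 <- (8 * pi * (1 - bl_fraction) * rbar^2 * L /
             (axial_aspect * max(n_target, min_cells)))^(1 / 3)
    hs <- h0 * exp(seq(log(0.5), log(2), length.out = 121L))
    cand <- lapply(hs, counts)
    dev <- abs(vapply(cand, `[[`, numeric(1), "cells") - n_target)
    best <- cand[[which.min(dev)]]
  }

  nc <- best$nc; m <- best$m; n_ax <- best$n_ax
  n_st <- n_ax + 1L
  frac <- .ring_fractions(best$m_core, n_wall_layers, growth_ratio,
                          bl_fraction)
  s_st <- if (axial_grading) .axial_stations(geometry, n_st)
          else seq(0, L, length.out = n_st)
  fr <- centerline_at(geometry, s_st)
  r_st <- radius_at(geometry, s_st)
  th <- 2 * pi * (seq_len(nc) - 1) / nc
  npps <- 1L + m * nc  # nodes per station

  nodes <- matrix(0, n_st * npps, 3)
  node_station <- rep(seq_len(n_st), each = npps)
  node_ring <- rep(c(0L, rep(seq_len(m), each = nc)), n_st)
  node_s <- rep(s_st, each = npps)
  cs_unit <- rbind(c(0, 0),
                   cbind(rep(cos(th), m) * rep(frac, each = nc),
                         rep(sin(th), m) * rep(frac, each = nc)))
  for (i in seq_len(n_st)) {
    off <- (i - 1L) * npps
    nodes[off + seq_len(npps), ] <-
      fr$position[rep(i, npps), , drop = FALSE] +
      r_st[i] * (cs_unit[, 1] %o% fr$normal[i, ] +
                   cs_unit[, 2] %o% fr$binormal[i, ])
  }

  tri_cs <- .cross_section_triangles(nc, m)
  ntri <- nrow(tri_cs)
  prisms <- matrix(0L, ntri * n_ax, 6)
  for (i in seq_len(n_ax)) {
    off_b <- (i - 1L) * npps; off_t <- i * npps
    prisms[(i - 1L) * ntri + seq_len(ntri), ] <-
      cbind(tri_cs + off_b, tri_cs + off_t)
  }
  cells <- .split_prisms(prisms)
  vol <- .tet_volumes(nodes, cells)
  neg <- vol < 0
  if (any(neg)) {
    cells[neg, c(3, 4)] <- cells[neg, c(4, 3)]
    vol[neg] <- -vol[neg]
  }
  if (any(vol <= 0)) stop("mesh generation produced degenerate cells")

  patches <- .boundary_patches(nodes, cells, node_station, n_st)
  g <- growth_ratio
  t_wall <- if (n_wall_layers == 0) NA_real_ else if (g == 1)
    bl_fraction / n_wall_layers else bl_fraction * (g - 1) / (g^n_wall_layers - 1)
  structure(list(
    nodes = nodes, cells = cells,
    patches = patches,
    node_station = node_station, node_ring = node_ring, node_s = node_s,
    n_stations = n_st, nodes_per_station = npps,
    ring_fractions = frac,
    layer_grading = list(n_wall_layers = n_wall_layers,
                         growth_ratio = growth_ratio,
                         bl_fraction = bl_fraction,
                         wall_layer_fraction = t_wall),
    geometry = geometry,
    analytic_volume = V,
    target_density = target_density,
    resolution = list(nc = nc, m = m, m_core = best$m_core, n_ax = n_ax)
  ), class = "volume_mesh")
}

# Axial station positions from an inverse-CDF of a refinement weight:
# proportional to the local area contraction through the constriction and
# carried (with linear decay over `recovery` mm) into the post-stenotic
# zone where the jet and pressure recovery live. Uniform when the vessel
# is unobstructed.
.axial_stations <- function(geometry, n_st, gamma = 1, recovery = 10) {
  L <- geometry$total_length
  sg <- seq(0, L, length.out = 2001L)
  r <- radius_at(geometry, sg)
  R <- geometry$reference_diameter / 2
  w <- (R / r)^gamma
  if (max(w) <= 1 + 1e-12) return(seq(0, L, length.out = n_st))
  ds <- sg[2] - sg[1]
  decay <- ds / recovery * (max(w) - 1)
  carry <- w
  for (i in 2:length(w)) {
    carry[i] <- max(w[i], carry[i - 1] - decay)
  }
  cdf <- cumsum(carry) - carry[1]
  cdf <- cdf / cdf[length(cdf)]
  s_st <- stats::approx(cdf, sg, xout = seq(0, 1, length.out = n_st),
                        ties = "ordered")$y
  s_st[1] <- 0; s_st[n_st] <- L
  s_st
}

# Boundary facets = faces appearing in exactly one tet, oriented outward,
# classified by the axial station of their nodes.
.boundary_patches <- function(nodes, cells, node_station, n_st) {
  M <- nrow(cells)
  fidx <- rbind(cells[, c(2, 3, 4)], cells[, c(1, 4, 3)],
                cells[, c(1, 2, 4)], cells[, c(1, 3, 2)])
  opp <- c(cells[, 1], cells[, 2], cells[, 3], cells[, 4])
  srt <- cbind(pmin(fidx[, 1], fidx[, 2], fidx[, 3]),
               pmax(fidx[, 1], fidx[, 2], fidx[, 3]))
  mid <- fidx[, 1] + fidx[, 2] + fidx[, 3] - srt[, 1] - srt[, 2]
  K <- as.double(nrow(nodes) + 1L)
  key <- srt[, 1] + K * (mid + K * srt[, 2])
  ord <- order(key)
  k2 <- key[ord]
  same_prev <- c(FALSE, diff(k2) == 0)
  same_next <- c(same_prev[-1], FALSE)
  sel <- ord[!same_prev & !same_next]  # faces appearing exactly once
  f <- fidx[sel, , drop = FALSE]
  o <- opp[sel]
  # orient outward: normal of (a,b,c) must point away from the opposite node
  a <- nodes[f[, 1], , drop = FALSE]
  e1 <- nodes[f[, 2], , drop = FALSE] - a
  e2 <- nodes[f[, 3], , drop = FALSE] - a
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  dvec <- nodes[o, , drop = FALSE] - a
  flip <- rowSums(nrm * dvec) > 0
  f[flip, c(2, 3)] <- f[flip, c(3, 2)]
  st <- matrix(node_station[f], ncol = 3)
  is_in <- st[, 1] == 1L & st[, 2] == 1L & st[, 3] == 1L
  is_out <- st[, 1] == n_st & st[, 2] == n_st & st[, 3] == n_st
  list(inlet = f[is_in, , drop = FALSE],
       outlet = f[is_out, , drop = FALSE],
       wall = f[!is_in & !is_out, , drop = FALSE])
}

#' Mesh quality summary
#'
#' Deterministic summary of cell volumes, minimum dihedral angle, achieved
#' element density against the analytic lumen volume, and near-wall layer
#' grading; flags inverted cells.
#'
#' @param mesh a `volume_mesh`
#' @return a list of class `mesh_quality_report`
#' @export
mesh_quality_report <- function(mesh) {
  vol <- .tet_volumes(mesh$nodes, mesh$cells)
  # min dihedral angle per tet from inward face normals
  cells <- mesh$cells; nodes <- mesh$nodes
  fn <- vector("list", 4)
  face_of <- list(c(2, 3, 4), c(1, 4, 3), c(1, 2, 4), c(1, 3, 2))
  for (k in 1:4) {
    f <- face_of[[k]]
    a <- nodes[cells[, f[1]], , drop = FALSE]
    e1 <- nodes[cells[, f[2]], , drop = FALSE] - a
    e2 <- nodes[cells[, f[3]], , drop = FALSE] - a
    nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                 e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                 e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    fn[[k]] <- nrm / sqrt(rowSums(nrm^2))
  }
  min_dihedral <- rep(pi, nrow(cells))
  for (i in 1:3) for (j in (i + 1):4) {
    cosang <- pmin(1, pmax(-1, -rowSums(fn[[i]] * fn[[j]])))
    min_dihedral <- pmin(min_dihedral, acos(cosang))
  }
  # mean radial thickness of each near-wall cell layer (outermost rings)
  lg <- mesh$layer_grading
  layer_thickness <- NULL
  if (lg$n_wall_layers > 0) {
    frac <- c(0, mesh$ring_fractions)
    m <- length(mesh$ring_fractions)
    idx <- (m - lg$n_wall_layers + 1):m
    dfrac <- frac[idx + 1] - frac[idx]
    rbar <- mean(radius_at(mesh$geometry,
                           seq(0, mesh$geometry$total_length,
                               length.out = 201)))
    layer_thickness <- rev(dfrac * rbar)  # wall-adjacent first
  }
  structure(list(
    n_cells = nrow(mesh$cells),
    n_nodes = nrow(mesh$nodes),
    min_cell_volume = min(vol),
    mean_cell_volume = mean(vol),
    n_inverted = sum(vol <= 0),
    min_dihedral_deg = min(min_dihedral) * 180 / pi,
    density = nrow(mesh$cells) / mesh$analytic_volume,
    target_density = mesh$target_density,
    n_wall_layers = lg$n_wall_layers,
    growth_ratio = lg$growth_ratio,
    layer_thickness_mm = layer_thickness
  ), class = "mesh_quality_report")
}

#' @export
print.mesh_quality_report <- function(x, ...) {
  cat(sprintf(
    "mesh: %d cells / %d nodes | density %.1f el/mm^3 (target %.1f)\n",
    x$n_cells, x$n_nodes, x$density, x$target_density))
  cat(sprintf("  cell volume [mm^3]: min %.3e mean %.3e | inverted: %d\n",
              x$min_cell_volume, x$mean_cell_volume, x$n_inverted))
  cat(sprintf("  min dihedral angle: %.1f deg | %d wall layers (ratio %.2f)\n",
              x$min_dihedral_deg, x$n_wall_layers, x$growth_ratio))
  invisible(x)
}

#' @export
print.volume_mesh <- function(x, ...) {
  cat(sprintf(
    "volume_mesh: %d nodes, %d tets | patches: inlet %d, outlet %d, wall %d\n",
    nrow(x$nodes), nrow(x$cells), nrow(x$patches$inlet),
    nrow(x$patches$outlet), nrow(x$patches$wall)))
  invisible(x)
}

#' Export a volume mesh to legacy VTK UnstructuredGrid (ASCII)
#'
#' Optionally attaches nodal fields (e.g. `velocity`, `pressure`) as point
#' data arrays and patch labels as a cell array on boundary triangles is not
#' representable in the legacy tet-only file, so patches are exported as a
#' node label array (0 interior, 1 inlet, 2 outlet, 3 wall).
#'
#' @param mesh a `volume_mesh`
#' @param path output `.vtk` file
#' @param point_data optional named list of nodal arrays (vector per node or
#'   n x 3 matrix)
#' @return `path`, invisibly
#' @export
write_vtk_mesh <- function(mesh, path, point_data = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- mesh$nodes
  cl <- mesh$cells
  writeLines(c("# vtk DataFile Version 3.0", "stenoflow mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(v))), con)
  writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("CELLS %d %d", nrow(cl), 5L * nrow(cl)), con)
  writeLines(sprintf("4 %d %d %d %d", cl[, 1] - 1L, cl[, 2] - 1L,
                     cl[, 3] - 1L, cl[, 4] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", nrow(cl)), con)
  writeLines(rep("10", nrow(cl)), con)
  lab <- integer(nrow(v))
  lab[unique(as.vector(mesh$patches$wall))] <- 3L
  lab[unique(as.vector(mesh$patches$inlet))] <- 1L
  lab[unique(as.vector(mesh$patches$outlet))] <- 2L
  writeLines(sprintf("POINT_DATA %d", nrow(v)), con)
  writeLines(c("SCALARS patch int 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%d", lab), con)
  for (nm in names(point_data)) {
    arr <- point_data[[nm]]
    if (is.matrix(arr) && ncol(arr) == 3) {
      writeLines(sprintf("VECTORS %s double", nm), con)
      writeLines(sprintf("%.9g %.9g %.9g", arr[, 1], arr[, 2], arr[, 3]),
                 con)
    } else {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.9g", arr), con)
    }
  }
  invisible(path)
}
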