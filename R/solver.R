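# Steady incompressible Navier-Stokes solve on the tetrahedral lumen mesh.
# Stabilized equal-order P1-P1 elements (SUPG/PSPG), Picard linearization
# with pseudo-time damping, sparse direct linear solves. Internal units are
# SI: the mesh (mm) is converted to metres on ingestion.

#' Solver parameters
#'
#' @param nonlinear_tolerance relative steady-residual tolerance for the
#'   Picard loop (default 1e-5)
#' @param max_nonlinear_iterations maximum Picard iterations (default 200)
#' @param under_relaxation solution update relaxation in (0, 1] (default 0.7)
#' @param pseudo_cfl initial pseudo-time damping strength (local CFL
#'   number); the loop grows it while the residual contracts and cuts it
#'   back when a step is rejected; `Inf` disables damping (default 5)
#' @param pseudo_cfl_max upper bound for the adaptive CFL (default 1e4)
#' @param lsic_scale grad-div (least-squares incompressibility)
#'   stabilization scale; 0 disables (default 0)
#' @param dc_scale residual-based discontinuity-capturing scale: adds an
#'   artificial viscosity proportional to the local momentum residual
#'   (capped at first-order upwind level) that vanishes on smooth resolved
#'   flow; stabilizes under-resolved stenotic jets (default 0.5)
#' @param lu_refresh retained control knob for factorization reuse; the
#'   loop refactorizes whenever the per-iteration residual contraction is
#'   poorer than 0.6, otherwise the previous factorization is reused as a
#'   quasi-Newton preconditioner on the current residual
#' @param newton_start switch from Picard to Newton linearization once the
#'   relative residual falls below this value; 0 keeps pure Picard
#'   (default 0.1)
#' @param newton_pure drop pseudo-time damping entirely (pure Newton steps)
#'   once the residual falls below this value (default 3e-3)
#' @param dc_freeze freeze the discontinuity-capturing viscosity field once
#'   the residual falls below this value, so the endgame solves a fixed
#'   eddy-viscosity system on which Newton converges quadratically
#'   (default 1e-2)
#' @param linearization `"picard"` or `"newton"` (Newton still starts from
#'   Picard steps until `newton_start` is reached)
#' @param verbose print per-iteration residuals
#' @return object of class `solver_params`
#' @export
solver_params <- function(nonlinear_tolerance = 1e-5,
                          max_nonlinear_iterations = 200,
                          under_relaxation = 0.7,
                          pseudo_cfl = 5,
                          pseudo_cfl_max = 1e4,
                          lsic_scale = 0,
                          dc_scale = 0.5,
                          lu_refresh = 4,
                          newton_start = 0.1,
                          newton_pure = 3e-3,
                          dc_freeze = 1e-2,
                          linearization = "newton",
                          verbose = FALSE) {
  if (nonlinear_tolerance <= 0) stop("nonlinear_tolerance must be > 0")
  if (max_nonlinear_iterations < 1) stop("need at least one iteration")
  if (under_relaxation <= 0 || under_relaxation > 1) {
    stop("under_relaxation must be in (0, 1]")
  }
  linearization <- match.arg(linearization, c("newton", "picard"))
  structure(list(nonlinear_tolerance = nonlinear_tolerance,
                 max_nonlinear_iterations = as.integer(max_nonlinear_iterations),
                 under_relaxation = under_relaxation,
                 pseudo_cfl = pseudo_cfl,
                 pseudo_cfl_max = pseudo_cfl_max,
                 lsic_scale = lsic_scale,
                 dc_scale = dc_scale,
                 lu_refresh = as.integer(lu_refresh),
                 newton_start = newton_start,
                 newton_pure = newton_pure,
                 dc_freeze = dc_freeze,
                 linearization = linearization,
                 verbose = isTRUE(verbose)), class = "solver_params")
}

# Facet areas and outward unit normals of a boundary patch (nodes in
# metres). Facets are oriented outward by the mesher.
.patch_geometry <- function(nodes, facets) {
  a <- nodes[facets[, 1], , drop = FALSE]
  e1 <- nodes[facets[, 2], , drop = FALSE] - a
  e2 <- nodes[facets[, 3], , drop = FALSE] - a
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area2 <- sqrt(rowSums(cr^2))
  list(area = area2 / 2, normal = cr / area2)
}

# Outward volumetric flux (m^3/s) of a nodal P1 velocity field through a
# patch: exact for linear fields (facet mean of nodal velocities).
.patch_flux <- function(nodes, facets, u) {
  pg <- .patch_geometry(nodes, facets)
  um <- (u[facets[, 1], , drop = FALSE] + u[facets[, 2], , drop = FALSE] +
           u[facets[, 3], , drop = FALSE]) / 3
  sum(pg$area * rowSums(um * pg$normal))
}

#' Solve the steady incompressible Navier-Stokes equations
#'
#' Newtonian fluid, rigid wall (no-slip), plug velocity on the inlet patch
#' directed along the inward centerline tangent, and either a fixed
#' pressure or a peripheral-resistance condition (`P_out = P_ref + R * Q`,
#' updated every Picard iteration) applied weakly on the outlet.
#'
#' @param mesh a `volume_mesh` (millimetres; converted internally)
#' @param case a `flow_case`
#' @param params a `solver_params`
#' @param initial optional warm start: a `flow_solution` on a mesh with the
#'   same node layout (e.g. the previous case of a severity sweep)
#' @return object of class `flow_solution` with nodal `velocity` (m/s),
#'   `pressure` (Pa), `residual_history`, `converged`, `inlet_flow`,
#'   `outlet_flow` (m^3/s) and the final `outlet_pressure` (Pa)
#' @export
solve_steady_flow <- function(mesh, case, params = solver_params(),
                              initial = NULL) {
  if (!inherits(mesh, "volume_mesh")) stop("need a volume_mesh")
  if (!inherits(case, "flow_case")) stop("need a flow_case")
  nodes <- mesh$nodes * 1e-3  # mm -> m
  cells <- mesh$cells
  if (any(.tet_volumes(nodes, cells) <= 0)) {
    stop("mesh contains inverted cells; refusing to assemble")
  }
  N <- nrow(nodes)
  mu <- case$fluid$viscosity
  rho <- case$fluid$density

  wall_nodes <- sort(unique(as.vector(mesh$patches$wall)))
  inlet_nodes <- setdiff(sort(unique(as.vector(mesh$patches$inlet))),
                         wall_nodes)  # rim nodes keep no-slip
  # plug velocity along the inward tangent, magnitude Q / (pi r_in^2)
  fr0 <- centerline_at(mesh$geometry, 0)
  r_in <- radius_at(mesh$geometry, 0) * 1e-3
  U <- plug_inlet_velocity(case$inlet$flow_rate, pi * r_in^2)
  u_plug <- as.numeric(fr0$tangent)

  # Dirichlet table over velocity dofs (interleaved layout: node k owns
  # dofs 4(k-1)+1..3 velocity, 4(k-1)+4 pressure)
  dir_dof <- c(rbind(4 * (wall_nodes - 1) + 1, 4 * (wall_nodes - 1) + 2,
                     4 * (wall_nodes - 1) + 3),
               rbind(4 * (inlet_nodes - 1) + 1, 4 * (inlet_nodes - 1) + 2,
                     4 * (inlet_nodes - 1) + 3))
  dir_val <- c(rep(0, 3 * length(wall_nodes)),
               rep(U * u_plug, times = length(inlet_nodes)))
  ndof <- 4L * N

  # outlet weak pressure term: rhs_d(i) -= P_out * n_d * A/3 per facet node
  out_pg <- .patch_geometry(nodes, mesh$patches$outlet)
  out_f <- mesh$patches$outlet
  out_rows <- c(4 * (as.vector(out_f) - 1) + 1,
                4 * (as.vector(out_f) - 1) + 2,
                4 * (as.vector(out_f) - 1) + 3)
  out_unit <- c(rep(out_pg$area * out_pg$normal[, 1] / 3, 3),
                rep(out_pg$area * out_pg$normal[, 2] / 3, 3),
                rep(out_pg$area * out_pg$normal[, 3] / 3, 3))

  # reference (cold) initial guess: plug profile carried along the
  # centerline, scaled by local area ratio; zero at walls
  u_cold <- matrix(0, N, 3)
  s_nodes <- mesh$node_s
  fr_n <- centerline_at(mesh$geometry, s_nodes)
  r_loc <- radius_at(mesh$geometry, s_nodes) * 1e-3
  scale <- (r_in / r_loc)^2
  free_nodes <- setdiff(seq_len(N), wall_nodes)
  u_cold[free_nodes, ] <- fr_n$tangent[free_nodes, , drop = FALSE] *
    (U * scale[free_nodes])
  u_cold[inlet_nodes, ] <- rep(U * u_plug, each = length(inlet_nodes))
  p_cold <- rep(case$outlet$reference_pressure, N)
  if (!is.null(initial)) {
    if (nrow(initial$velocity) != N) {
      stop("warm start has a different node count than the mesh")
    }
    u <- initial$velocity
    p <- initial$pressure
    u[wall_nodes, ] <- 0
    u[inlet_nodes, ] <- rep(U * u_plug, each = length(inlet_nodes))
  } else {
    u <- u_cold
    p <- p_cold
  }
  x <- as.vector(t(cbind(u, p)))

  P_out <- if (case$outlet$mode == "fixed_pressure") {
    case$outlet$reference_pressure
  } else if (!is.null(initial$outlet_pressure)) {
    initial$outlet_pressure
  } else {
    case$outlet$reference_pressure +
      case$outlet$resistance * case$inlet$flow_rate
  }

  # convergence is judged relative to the residual of the cold reference
  # guess, so warm starts tighten the start, not the stopping criterion
  ref_floor <- 0
  if (!is.null(initial)) {
    tr0 <- assemble_ns_system(nodes, cells, u_cold, p_cold, mu, rho, Inf,
                              params$lsic_scale, params$dc_scale, 0L,
                              numeric(0))
    b0c <- numeric(ndof)
    accc <- rowsum(-P_out * out_unit, out_rows)
    b0c[as.integer(rownames(accc))] <- accc[, 1]
    keep0 <- !(tr0$i %in% dir_dof)
    A0 <- Matrix::sparseMatrix(
      i = c(tr0$i[keep0], dir_dof), j = c(tr0$j[keep0], dir_dof),
      x = c(tr0$x[keep0], rep(1, length(dir_dof))), dims = c(ndof, ndof))
    b0c[dir_dof] <- dir_val
    x_cold <- as.vector(t(cbind(u_cold, p_cold)))
    ref_floor <- sqrt(sum((as.numeric(A0 %*% x_cold) - b0c)^2))
  }

  res_hist <- numeric(0)
  converged <- FALSE
  omega <- params$under_relaxation
  fct <- NULL
  last_lu <- -1L
  cfl <- params$pseudo_cfl
  cfl_cap <- params$pseudo_cfl_max
  mu_frozen <- numeric(0)
  res_acc <- Inf     # residual of the last accepted iterate
  x_acc <- x
  P_acc <- P_out
  for (it in seq_len(params$max_nonlinear_iterations)) {
    use_newton <- params$linearization == "newton" && it > 1L &&
      res_acc < params$newton_start
    trip <- assemble_ns_system(nodes, cells, u, p, mu, rho, cfl,
                               params$lsic_scale, params$dc_scale,
                               as.integer(use_newton), mu_frozen)
    b0 <- numeric(ndof)
    acc <- rowsum(-P_out * out_unit, out_rows)
    b0[as.integer(rownames(acc))] <- acc[, 1]
    b <- b0 + trip$rhs_pseudo + trip$rhs_newton
    keep <- !(trip$i %in% dir_dof)
    A <- Matrix::sparseMatrix(
      i = c(trip$i[keep], dir_dof),
      j = c(trip$j[keep], dir_dof),
      x = c(trip$x[keep], rep(1, length(dir_dof))),
      dims = c(ndof, ndof))
    b[dir_dof] <- dir_val

    # steady residual of the current iterate (pseudo-time parts cancel)
    rvec <- as.numeric(A %*% x) - b
    if (it == 1L) {
      res_ref <- max(sqrt(sum(b0^2)), sqrt(sum(rvec^2)), ref_floor, 1e-30)
    }
    res <- sqrt(sum(rvec^2)) / res_ref
    res_hist <- c(res_hist, res)
    if (params$verbose) {
      message(sprintf("  picard %3d: residual %.3e  cfl %.3g  P_out %.1f Pa",
                      it, res, cfl, P_out))
    }
    if (res <= params$nonlinear_tolerance) {
      converged <- TRUE
      break
    }
    if (res > 1.5 * res_acc) {
      # diverging step: restore the last accepted iterate, damp harder and
      # remember the CFL level that failed (trust-region style)
      x <- x_acc
      P_out <- P_acc
      X4 <- matrix(x, nrow = 4L)
      u <- t(X4[1:3, , drop = FALSE])
      p <- X4[4, ]
      cfl_cap <- if (is.finite(cfl)) max(cfl / 2, 1) else 100
      cfl <- max(cfl_cap / 2, 0.5)
      fct <- NULL
      next
    }
    contraction <- if (it > 1L) res / res_hist[it - 1L] else 0
    x_acc <- x; P_acc <- P_out; res_acc <- res
    if (length(mu_frozen) == 0L && params$dc_scale > 0 &&
        res < params$dc_freeze) {
      mu_frozen <- trip$mu_el
    }
    # grow the damping CFL while the iteration behaves (SER-style), but
    # only slowly past a level that previously failed
    cfl_cap <- min(cfl_cap * 1.1, params$pseudo_cfl_max)
    cfl <- min(cfl * 1.6, cfl_cap)
    # endgame: near the solution, Newton without damping converges
    # quadratically even for steady states that are unstable in time
    if (use_newton && res_acc < params$newton_pure) cfl <- Inf
    # refactorize when the frozen factorization stops giving good
    # contraction; natural ordering exploits the banded station-major
    # dof layout
    if (is.null(fct) || contraction > 0.6) {
      fct <- tryCatch(Matrix::lu(A, order = 0L),
                      error = function(e) Matrix::lu(A, order = 1L))
      last_lu <- it
    }
    # with a fresh factorization this is the exact relaxed Picard update;
    # undamped Newton endgame takes full steps
    omega_it <- if (use_newton && !is.finite(cfl)) 1 else omega
    x <- x - omega_it * as.numeric(Matrix::solve(fct, rvec))
    X4 <- matrix(x, nrow = 4L)
    u <- t(X4[1:3, , drop = FALSE])
    p <- X4[4, ]
    if (case$outlet$mode == "resistance") {
      Qo <- .patch_flux(nodes, mesh$patches$outlet, u)
      P_out <- omega * (case$outlet$reference_pressure +
                          case$outlet$resistance * Qo) +
        (1 - omega) * P_out
    }
  }
  X4 <- matrix(x, nrow = 4L)
  u <- t(X4[1:3, , drop = FALSE])
  p <- X4[4, ]
  Qi <- -.patch_flux(nodes, mesh$patches$inlet, u)
  Qo <- .patch_flux(nodes, mesh$patches$outlet, u)
  if (!converged) {
    warning(sprintf(
      "Picard iteration did not reach tolerance %.1e (final residual %.3e after %d iterations)",
      params$nonlinear_tolerance, res_hist[length(res_hist)],
      length(res_hist)))
  }
  structure(list(
    velocity = u, pressure = p,
    residual_history = res_hist, converged = converged,
    inlet_flow = Qi, outlet_flow = Qo,
    outlet_pressure = P_out,
    case = case, params = params, mesh = mesh
  ), class = "flow_solution")
}

#' @export
print.flow_solution <- function(x, ...) {
  cat(sprintf(
    "flow_solution: %s after %d iterations (residual %.2e)\n",
    if (x$converged) "converged" else "NOT converged",
    length(x$residual_history),
    x$residual_history[length(x$residual_history)]))
  cat(sprintf("  Q_in %.4g mL/min | Q_out %.4g mL/min | P_out %.1f Pa\n",
              x$inlet_flow * 6e7, x$outlet_flow * 6e7, x$outlet_pressure))
  invisible(x)
}

#' Reynolds number of a flow case
#'
#' `Re = rho * U * D / mu` with `U` the plug inlet speed `Q / (pi D^2 / 4)`.
#' Emits a warning when the laminar-pipe-flow assumption becomes doubtful
#' (`Re > 2000`).
#'
#' @param case a `flow_case`
#' @param diameter vessel diameter (m)
#' @return dimensionless Reynolds number
#' @export
reynolds_number <- function(case, diameter) {
  if (diameter <= 0) stop("diameter must be > 0")
  U <- plug_inlet_velocity(case$inlet$flow_rate, pi * diameter^2 / 4)
  Re <- case$fluid$density * U * diameter / case$fluid$viscosity
  if (Re > 2000) {
    warning(sprintf(
      "Re = %.0f exceeds 2000: the laminar steady assumption may not hold",
      Re))
  }
  Re
}

#' Area-averaged pressure and net flux on a cross-sectional plane
#'
#' Slices the tetrahedral mesh with the plane, builds the polygonal
#' intersection inside every crossing cell, and integrates the linear
#' nodal fields exactly over the polygons: area-weighted mean pressure and
#' the velocity flux through the plane (positive along `normal`).
#'
#' @param solution a `flow_solution`
#' @param point a point on the plane (mm, geometry coordinates)
#' @param normal plane normal (any length, mm coordinates)
#' @return list with `pressure` (Pa), `flux` (m^3/s), `area` (m^2)
#' @export
probe_plane <- function(solution, point, normal) {
  mesh <- solution$mesh
  nodes <- mesh$nodes * 1e-3
  point <- as.numeric(point) * 1e-3
  n <- as.numeric(normal); n <- n / sqrt(sum(n^2))
  d <- as.numeric(nodes %*% n) - sum(point * n)
  cells <- mesh$cells
  dc <- matrix(d[cells], ncol = 4)
  crossing <- which(rowSums(dc < 0) > 0 & rowSums(dc >= 0) > 0)
  if (length(crossing) == 0) stop("plane does not intersect the lumen")

  edges <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  tot_area <- 0; tot_p <- 0; tot_q <- 0
  u <- solution$velocity; p <- solution$pressure
  for (ci in crossing) {
    vid <- cells[ci, ]
    dd <- d[vid]
    pts <- matrix(0, 0, 3); pv <- numeric(0); uv <- matrix(0, 0, 3)
    for (k in 1:6) {
      i1 <- edges[k, 1]; i2 <- edges[k, 2]
      if ((dd[i1] < 0) != (dd[i2] < 0)) {
        t <- dd[i1] / (dd[i1] - dd[i2])
        pts <- rbind(pts, (1 - t) * nodes[vid[i1], ] + t * nodes[vid[i2], ])
        pv <- c(pv, (1 - t) * p[vid[i1]] + t * p[vid[i2]])
        uv <- rbind(uv, (1 - t) * u[vid[i1], ] + t * u[vid[i2], ])
      }
    }
    if (nrow(pts) < 3) next
    # order polygon vertices by angle about the centroid in the plane
    ctr <- colMeans(pts)
    ref <- pts[1, ] - ctr
    ref <- ref - sum(ref * n) * n
    if (sum(ref^2) < 1e-30) next
    ref <- ref / sqrt(sum(ref^2))
    ref2 <- c(n[2] * ref[3] - n[3] * ref[2],
              n[3] * ref[1] - n[1] * ref[3],
              n[1] * ref[2] - n[2] * ref[1])
    rel <- sweep(pts, 2, ctr)
    ang <- atan2(rel %*% ref2, rel %*% ref)
    ord <- order(ang)
    pts <- pts[ord, , drop = FALSE]
    pv <- pv[ord]; uv <- uv[ord, , drop = FALSE]
    m <- nrow(pts)
    for (k in 2:(m - 1)) {
      tri <- c(1, k, k + 1)
      e1 <- pts[tri[2], ] - pts[tri[1], ]
      e2 <- pts[tri[3], ] - pts[tri[1], ]
      cr <- c(e1[2] * e2[3] - e1[3] * e2[2],
              e1[3] * e2[1] - e1[1] * e2[3],
              e1[1] * e2[2] - e1[2] * e2[1])
      area <- sqrt(sum(cr^2)) / 2
      # fields are linear on the polygon (single tet): vertex mean is exact
      tot_area <- tot_area + area
      tot_p <- tot_p + area * mean(pv[tri])
      un <- as.numeric(uv[tri, , drop = FALSE] %*% n)
      tot_q <- tot_q + area * mean(un)
    }
  }
  if (tot_area <= 0) stop("plane does not intersect the lumen")
  list(pressure = tot_p / tot_area, flux = tot_q, area = tot_area)
}

#' Export a flow solution to legacy VTK (ASCII)
#'
#' Writes the mesh with nodal `velocity` (m/s) and `pressure` (Pa) arrays.
#'
#' @param solution a `flow_solution`
#' @param path output `.vtk` file
#' @return `path`, invisibly
#' @export
write_vtk_solution <- function(solution, path) {
  write_vtk_mesh(solution$mesh, path,
                 point_data = list(velocity = solution$velocity,
                                   pressure = solution$pressure))
}

#' Transfer a solution between structured meshes of the same vessel
#'
#' Interpolates nodal velocity and pressure from a solution on one
#' swept-template mesh onto another resolution of the same (or a similar)
#' geometry, using the shared structured parameterization: arc length,
#' radial ring fraction and circumferential angle. Intended to warm-start
#' grid-refinement studies.
#'
#' @param solution a `flow_solution` on a coarse `volume_mesh`
#' @param mesh the target `volume_mesh`
#' @return list with `velocity`, `pressure`, `outlet_pressure` usable as
#'   the `initial` argument of [solve_steady_flow()]
#' @export
interpolate_solution <- function(solution, mesh) {
  src <- solution$mesh
  # structured coordinates of a mesh's nodes
  coords <- function(m) {
    frac <- c(0, m$ring_fractions)[m$node_ring + 1L]
    nc <- m$resolution$nc
    within <- (seq_len(nrow(m$nodes)) - 1L) %% m$nodes_per_station
    j <- (within - 1L) %% nc  # 0-based angular index (centers: ring 0)
    theta <- ifelse(m$node_ring == 0L, 0, 2 * pi * j / nc)
    list(s = m$node_s, frac = frac, theta = theta,
         s_st = unique(m$node_s), fr = m$ring_fractions, nc = nc)
  }
  cs <- coords(src)
  ct <- coords(mesh)
  fields <- cbind(solution$velocity, solution$pressure)
  # source lookup tables: station x (center + rings x angle)
  ns <- length(cs$s_st); m_src <- length(cs$fr); nc_s <- cs$nc
  out <- matrix(0, nrow(mesh$nodes), 4)
  # indices into the source node vector
  src_id <- function(ist, ring, jang) {
    (ist - 1L) * src$nodes_per_station + ifelse(ring == 0L, 1L,
      1L + (ring - 1L) * nc_s + (jang %% nc_s) + 1L)
  }
  # locate target stations / rings in the source grids
  ist <- findInterval(ct$s, cs$s_st, rightmost.closed = TRUE)
  ist <- pmin(pmax(ist, 1L), ns - 1L)
  ws <- (ct$s - cs$s_st[ist]) / pmax(cs$s_st[ist + 1L] - cs$s_st[ist],
                                     1e-12)
  ws <- pmin(pmax(ws, 0), 1)
  fr_grid <- c(0, cs$fr)
  irad <- findInterval(ct$frac, fr_grid, rightmost.closed = TRUE)
  irad <- pmin(pmax(irad, 1L), m_src)  # rings irad-1 .. irad (0 = center)
  wr <- (ct$frac - fr_grid[irad]) / pmax(fr_grid[irad + 1L] -
                                           fr_grid[irad], 1e-12)
  wr <- pmin(pmax(wr, 0), 1)
  ja <- ct$theta / (2 * pi) * nc_s
  j0 <- floor(ja)
  wa <- ja - j0
  for (ds in 0:1) for (dr in 0:1) for (da in 0:1) {
    ring <- irad - 1L + dr
    id <- src_id(ist + ds, ring, j0 + da)
    w <- (if (ds == 1) ws else 1 - ws) *
         (if (dr == 1) wr else 1 - wr) *
         ifelse(ring == 0L, if (da == 1) 0 else 1,
                if (da == 1) wa else 1 - wa)
    out <- out + w * fields[id, , drop = FALSE]
  }
  list(velocity = out[, 1:3, drop = FALSE], pressure = out[, 4],
       outlet_pressure = solution$outlet_pressure)
}
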