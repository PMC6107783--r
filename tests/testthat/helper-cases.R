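# Shared helpers: small geometries, fake field constructors and rotation
# utilities used across the suite. Everything is generated in code.

# straight unobstructed tube (mm)
straight_tube <- function(d = 4, l = 40) build_stenosed_vessel(d, l)

# straight tube with a mid-vessel stenosis, handy for extraction tests
straight_stenosed <- function(severity = 50, d = 5, l = 40,
                              center = 12, len = 6) {
  build_stenosed_vessel(d, l, list(stenosis_spec(center, len, severity)))
}

# a flow_solution-shaped object carrying analytic nodal fields on a mesh,
# for probing/extraction tests that need no solve
fake_solution <- function(mesh, pressure_fun, velocity_fun = NULL) {
  nodes <- mesh$nodes  # mm
  p <- pressure_fun(nodes)
  u <- if (is.null(velocity_fun)) matrix(0, nrow(nodes), 3)
       else velocity_fun(nodes)
  structure(list(velocity = u, pressure = p, mesh = mesh,
                 converged = TRUE,
                 residual_history = 0,
                 inlet_flow = NA_real_, outlet_flow = NA_real_),
            class = "flow_solution")
}

# flow case for a target inlet Reynolds number on diameter d_m (metres)
case_at_reynolds <- function(re, d_m, mu = 0.0035, rho = 1066,
                             outlet_mode = "fixed_pressure",
                             reference_pressure = 0, resistance = 0) {
  U <- re * mu / (rho * d_m)
  flow_case(inlet_flow = U * pi * d_m^2 / 4, outlet_mode = outlet_mode,
            reference_pressure = reference_pressure,
            resistance = resistance, viscosity = mu, density = rho)
}

# rigidly rotate a vessel geometry (frames and hence any mesh built on it)
rotate_geometry <- function(geom, rotation) {
  fr <- geom$frames
  for (nm in c("X", "T", "N", "B")) fr[[nm]] <- fr[[nm]] %*% t(rotation)
  geom$frames <- fr
  geom
}

rotation_matrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# quick coarse solve wrapper used by several solver tests
quick_solve <- function(geometry, case, density = 12, tol = 1e-6,
                        max_it = 60) {
  mesh <- generate_volume_mesh(geometry, target_density = density)
  solve_steady_flow(mesh, case,
                    solver_params(nonlinear_tolerance = tol,
                                  max_nonlinear_iterations = max_it))
}
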