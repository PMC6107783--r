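test_that("zero inflow with a fixed outlet pressure gives hydrostatics", {
  g <- straight_tube(4, 20)
  mesh <- generate_volume_mesh(g, target_density = 8)
  case <- flow_case(0, "fixed_pressure", reference_pressure = 5000)
  sol <- solve_steady_flow(mesh, case,
                           solver_params(nonlinear_tolerance = 1e-10,
                                         max_nonlinear_iterations = 5))
  expect_true(sol$converged)
  expect_lt(max(abs(sol$pressure - 5000)), 1e-6)
  expect_lt(max(abs(sol$velocity)), 1e-9)
})

test_that("the stenotic pressure drop is linear in flow at the Stokes limit", {
  g <- straight_stenosed(50, d = 4, l = 24, center = 10, len = 6)
  mesh <- generate_volume_mesh(g, target_density = 10)
  dp <- function(q) {
    sol <- solve_steady_flow(mesh, flow_case(q, "fixed_pressure"),
                             solver_params(nonlinear_tolerance = 1e-8,
                                           max_nonlinear_iterations = 40))
    expect_true(sol$converged)
    p1 <- probe_plane(sol, centerline_at(g, 4)$position,
                      centerline_at(g, 4)$tangent)
    p2 <- probe_plane(sol, centerline_at(g, 20)$position,
                      centerline_at(g, 20)$tangent)
    p1$pressure - p2$pressure
  }
  q0 <- 2e-9  # Re of order 0.1: inertia negligible
  expect_equal(dp(2 * q0) / dp(q0), 2, tolerance = 0.01)
})

test_that("converged solutions conserve mass globally", {
  g <- straight_stenosed(40, d = 4, l = 24, center = 10, len = 6)
  mesh <- generate_volume_mesh(g, target_density = 10)
  sol <- solve_steady_flow(mesh, flow_case(2e-7, "fixed_pressure"),
                           solver_params(nonlinear_tolerance = 1e-7,
                                         max_nonlinear_iterations = 40))
  expect_true(sol$converged)
  expect_lt(abs(sol$inlet_flow - sol$outlet_flow) / sol$inlet_flow, 1e-3)
  # and the residual history is recorded and ends below tolerance
  expect_lte(tail(sol$residual_history, 1), 1e-7)
})

test_that("the resistance outlet closes the loop P_out = P_ref + R Q", {
  g <- straight_tube(4, 24)
  mesh <- generate_volume_mesh(g, target_density = 10)
  R <- 5e8
  case <- flow_case(5e-7, "resistance", resistance = R,
                    reference_pressure = 2000)
  sol <- solve_steady_flow(mesh, case,
                           solver_params(nonlinear_tolerance = 1e-7,
                                         max_nonlinear_iterations = 60))
  expect_true(sol$converged)
  expect_equal(sol$outlet_pressure, 2000 + R * sol$outlet_flow,
               tolerance = 0.005)
})

test_that("Reynolds number follows rho U D / mu and warns past 2000", {
  case <- flow_case(8e-6, "fixed_pressure")
  expect_equal(reynolds_number(case, 0.005),
               1066 * plug_inlet_velocity(8e-6, pi * 0.0025^2) * 0.005 /
                 0.0035)
  expect_equal(reynolds_number(case, 0.005), 620, tolerance = 0.01)
  expect_identical(reynolds_number(flow_case(0, "fixed_pressure"), 0.005),
                   0)
  expect_warning(reynolds_number(flow_case(8e-5, "fixed_pressure"), 0.005),
                 "laminar")
  expect_error(reynolds_number(case, 0), "diameter")
})

test_that("probe_plane integrates linear nodal fields exactly", {
  g <- straight_tube(4, 20)
  mesh <- generate_volume_mesh(g, target_density = 10)
  # uniform pressure: recovered exactly
  fs <- fake_solution(mesh, function(n) rep(13000, nrow(n)))
  pr <- probe_plane(fs, c(10, 0, 0), c(1, 0, 0))
  expect_equal(pr$pressure, 13000, tolerance = 1e-12)
  # linear pressure: plane average equals the value at the plane
  fs2 <- fake_solution(mesh, function(n) 5000 - 100 * n[, 1])
  pr2 <- probe_plane(fs2, c(7.3, 0, 0), c(1, 0, 0))
  expect_equal(pr2$pressure, 5000 - 100 * 7.3, tolerance = 1e-9)
  # uniform axial velocity: flux = U times the polygonal section area
  fs3 <- fake_solution(mesh, function(n) rep(0, nrow(n)),
                       function(n) cbind(rep(0.3, nrow(n)), 0, 0))
  pr3 <- probe_plane(fs3, c(10, 0, 0), c(1, 0, 0))
  expect_equal(pr3$flux, 0.3 * pr3$area, tolerance = 1e-12)
  expect_equal(pr3$area, pi * 0.002^2, tolerance = 0.02)
  expect_error(probe_plane(fs, c(100, 0, 0), c(1, 0, 0)), "intersect")
})

test_that("interior planes of a converged flow agree with each other", {
  g <- straight_tube(4, 24)
  mesh <- generate_volume_mesh(g, target_density = 12)
  sol <- solve_steady_flow(mesh, flow_case(5e-7, "fixed_pressure"),
                           solver_params(nonlinear_tolerance = 1e-7,
                                         max_nonlinear_iterations = 40))
  f1 <- probe_plane(sol, c(8, 0, 0), c(1, 0, 0))$flux
  f2 <- probe_plane(sol, c(16, 0, 0), c(1, 0, 0))$flux
  expect_equal(f1 / f2, 1, tolerance = 0.005)
})

test_that("the solve is equivariant under rigid rotation of the vessel", {
  g <- straight_stenosed(50, d = 4, l = 36, center = 10, len = 6)
  rot <- rotation_matrix(c(1, 2, 3), 0.7)
  gr <- rotate_geometry(g, rot)
  params <- solver_params(nonlinear_tolerance = 1e-9,
                          max_nonlinear_iterations = 40)
  case <- flow_case(2e-7, "fixed_pressure", reference_pressure = 1000)
  v1 <- extract_pd_pa(solve_steady_flow(
    generate_volume_mesh(g, target_density = 10), case, params), g)
  v2 <- extract_pd_pa(solve_steady_flow(
    generate_volume_mesh(gr, target_density = 10), case, params), gr)
  expect_equal(v1$vPdPa, v2$vPdPa, tolerance = 1e-6)
})

test_that("solver rejects broken meshes and bad parameters", {
  g <- straight_tube(4, 20)
  mesh <- generate_volume_mesh(g, target_density = 8)
  bad <- mesh
  bad$cells[1, ] <- bad$cells[1, c(2, 1, 3, 4)]  # invert one cell
  expect_error(solve_steady_flow(bad, flow_case(1e-7, "fixed_pressure")),
               "inverted")
  expect_error(solver_params(nonlinear_tolerance = 0), "tolerance")
  expect_error(solver_params(under_relaxation = 0), "under_relaxation")
  expect_error(solver_params(max_nonlinear_iterations = 0), "iteration")
})
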