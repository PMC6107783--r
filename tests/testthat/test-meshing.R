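test_that("achieved density tracks the target on a cylinder", {
  g <- straight_tube(5, 40)
  for (dens in c(20, 40)) {
    m <- generate_volume_mesh(g, target_density = dens)
    achieved <- nrow(m$cells) / m$analytic_volume
    expect_lt(abs(achieved / dens - 1), 0.2)
  }
})

test_that("doubling the target density roughly doubles the cell count", {
  g <- straight_tube(5, 40)
  n1 <- nrow(generate_volume_mesh(g, target_density = 25)$cells)
  n2 <- nrow(generate_volume_mesh(g, target_density = 50)$cells)
  expect_gt(n2 / n1, 2 * 0.8)
  expect_lt(n2 / n1, 2 * 1.2)
})

test_that("meshes are conforming with positive volumes and closed patches", {
  g <- renal_vessel_template(60, seed = 4)
  m <- generate_volume_mesh(g, target_density = 15)
  vol <- stenoflow:::.tet_volumes(m$nodes, m$cells)
  expect_true(all(vol > 0))
  # total tet volume approximates the analytic lumen volume
  expect_equal(sum(vol), m$analytic_volume, tolerance = 0.05)
  # every interior face appears exactly twice, boundary faces once, and
  # the boundary is fully classified into the three patches
  f <- rbind(m$cells[, c(2, 3, 4)], m$cells[, c(1, 4, 3)],
             m$cells[, c(1, 2, 4)], m$cells[, c(1, 3, 2)])
  key <- paste(pmin(f[, 1], f[, 2], f[, 3]),
               f[, 1] + f[, 2] + f[, 3] - pmin(f[, 1], f[, 2], f[, 3]) -
                 pmax(f[, 1], f[, 2], f[, 3]),
               pmax(f[, 1], f[, 2], f[, 3]))
  mult <- table(table(key))
  expect_true(all(names(mult) %in% c("1", "2")))
  n_boundary <- sum(table(key) == 1)
  expect_identical(
    n_boundary,
    nrow(m$patches$inlet) + nrow(m$patches$outlet) + nrow(m$patches$wall))
})

test_that("near-wall layers grade by the configured ratio", {
  g <- straight_tube(5, 40)
  m <- generate_volume_mesh(g, target_density = 30, n_wall_layers = 5,
                            growth_ratio = 1.2)
  q <- mesh_quality_report(m)
  expect_identical(q$n_wall_layers, 5L)
  th <- q$layer_thickness_mm   # wall-adjacent first
  expect_length(th, 5)
  expect_equal(th[-1] / th[-5], rep(1.2, 4), tolerance = 1e-10)
  expect_identical(q$n_inverted, 0L)
  expect_gt(q$min_cell_volume, 0)
  expect_equal(q$density, q$n_cells / m$analytic_volume, tolerance = 1e-12)
})

test_that("inlet and outlet patches are planar and correctly oriented", {
  g <- renal_vessel_template(40)
  m <- generate_volume_mesh(g, target_density = 15)
  fr <- centerline_at(g, c(0, g$total_length))
  for (patch in c("inlet", "outlet")) {
    pg <- stenoflow:::.patch_geometry(m$nodes, m$patches[[patch]])
    tang <- fr$tangent[if (patch == "inlet") 1 else 2, ]
    # outward normals: anti-parallel to the tangent at the inlet,
    # parallel at the outlet
    sgn <- if (patch == "inlet") -1 else 1
    align <- pg$normal %*% tang * sgn
    expect_true(all(align > 0.999))
    # planarity: all patch nodes on the cross-section plane
    nodes <- m$nodes[unique(as.vector(m$patches[[patch]])), , drop = FALSE]
    ctr <- fr$position[if (patch == "inlet") 1 else 2, ]
    d <- abs(sweep(nodes, 2, ctr) %*% tang)
    expect_lt(max(d), 1e-9)
  }
})

test_that("axial grading concentrates stations around the constriction", {
  g <- renal_vessel_template(72)
  m <- generate_volume_mesh(g, target_density = 15)
  s <- unique(m$node_s)
  ds <- diff(sort(s))
  near <- sort(s)[-1] > 2 & sort(s)[-1] < 9    # lesion zone
  far <- sort(s)[-1] > 30
  expect_lt(mean(ds[near]), mean(ds[far]))
  # uniform for an unobstructed vessel
  m0 <- generate_volume_mesh(straight_tube(5, 40), target_density = 15)
  expect_lt(diff(range(diff(sort(unique(m0$node_s))))), 1e-9)
})

test_that("a hand-built regular tetrahedron reports its closed-form volume", {
  # edge length 1 mm: V = 1/(6 sqrt(2))
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
                 c(0.5, sqrt(3) / 6, sqrt(2 / 3)))
  vol <- stenoflow:::.tet_volumes(nodes, matrix(1:4, 1))
  expect_equal(abs(vol), 1 / (6 * sqrt(2)), tolerance = 1e-12)
})

test_that("degenerate meshing inputs error early", {
  expect_error(build_stenosed_vessel(5, 0), "length")
  g <- straight_tube(5, 40)
  expect_error(generate_volume_mesh(g, target_density = 0),
               "target_density")
  expect_error(generate_volume_mesh(g, target_density = 1e-4),
               "infeasible")
  bad <- g
  bad$stenoses <- list(structure(list(center = 20, length = 10,
                                      severity = 150),
                                 class = "stenosis_spec"))
  expect_error(generate_volume_mesh(bad, target_density = 20),
               "non-positive radius")
})

test_that("mesh VTK export is well-formed", {
  g <- straight_tube(4, 10)
  m <- generate_volume_mesh(g, target_density = 10)
  f <- withr::local_tempfile(fileext = ".vtk")
  write_vtk_mesh(m, f, point_data = list(pressure = rep(1, nrow(m$nodes))))
  txt <- readLines(f)
  expect_identical(txt[4], "DATASET UNSTRUCTURED_GRID")
  cells_hdr <- txt[grep("^CELLS ", txt)]
  expect_identical(cells_hdr, sprintf("CELLS %d %d", nrow(m$cells),
                                      5L * nrow(m$cells)))
  expect_true(any(grepl("SCALARS pressure", txt)))
})
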