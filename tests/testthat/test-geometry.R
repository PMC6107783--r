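test_that("severity round-trips through the radius profile", {
  # includes the hand-arithmetic case: reference diameter 6 mm with minimum
  # diameter 2.1 mm is a 65% diameter stenosis
  for (sev in c(seq(10, 90, by = 10), 65)) {
    g <- build_stenosed_vessel(6, 40, list(stenosis_spec(20, 8, sev)))
    expect_equal(percent_diameter_stenosis(g), sev, tolerance = 0.1 / sev)
  }
  g72 <- build_stenosed_vessel(5, 40, list(stenosis_spec(12, 8, 72)))
  expect_equal(2 * min(radius_at(g72, seq(0, 40, length.out = 10000))),
               5 * (1 - 0.72), tolerance = 1e-3)
})

test_that("an unobstructed vessel is a uniform cylinder", {
  g <- build_stenosed_vessel(5, 40)
  s <- seq(0, 40, length.out = 500)
  expect_true(all(abs(radius_at(g, s) - 2.5) < 1e-12))
  expect_equal(percent_diameter_stenosis(g), 0, tolerance = 1e-8)
})

test_that("two stenoses give two local minima at the specified centers", {
  g <- build_stenosed_vessel(5, 40, list(stenosis_spec(10, 8, 40),
                                         stenosis_spec(25, 8, 60)))
  s <- seq(0, 40, length.out = 10000)
  r <- radius_at(g, s)
  locmin <- which(diff(sign(diff(r))) > 0) + 1L
  expect_length(locmin, 2)
  expect_equal(s[locmin], c(10, 25), tolerance = 0.01)
  # radius equals the reference outside all constriction supports
  outside <- s < 6 | (s > 14 & s < 21) | s > 29
  expect_true(all(abs(r[outside] - 2.5) < 1e-12))
})

test_that("invalid stenosis specifications are rejected", {
  expect_error(stenosis_spec(10, 8, 100), "severity")
  expect_error(stenosis_spec(10, 8, -1), "severity")
  expect_error(stenosis_spec(10, 0, 50), "length")
  expect_error(build_stenosed_vessel(5, 40,
                                     list(stenosis_spec(10, 8, 40),
                                          stenosis_spec(14, 8, 40))),
               "overlap")
  expect_error(build_stenosed_vessel(5, 40, list(stenosis_spec(2, 8, 40))),
               "outside")
  expect_error(build_stenosed_vessel(-5, 40), "reference_diameter")
})

test_that("the radius profile is C1 (no kinks for the mesher)", {
  g <- build_stenosed_vessel(5, 40, list(stenosis_spec(12, 8, 72)))
  s <- seq(0.1, 39.9, length.out = 8000)
  h <- s[2] - s[1]
  dr <- diff(radius_at(g, s)) / h
  # second difference of a C1 function stays bounded as h -> 0
  expect_lt(max(abs(diff(dr))), 20 * h)
})

test_that("geometry generation is deterministic in the seed", {
  g1 <- build_stenosed_vessel(5, 40, list(stenosis_spec(12, 8, 50)),
                              bend_radius = 76, seed = 7)
  g2 <- build_stenosed_vessel(5, 40, list(stenosis_spec(12, 8, 50)),
                              bend_radius = 76, seed = 7)
  g3 <- build_stenosed_vessel(5, 40, list(stenosis_spec(12, 8, 50)),
                              bend_radius = 76, seed = 8)
  expect_identical(g1$frames, g2$frames)
  expect_false(isTRUE(all.equal(g1$frames$X, g3$frames$X)))
  # the tortuous centerline is still arc-length parameterized
  fr <- centerline_at(g1, c(0, 10, 20, 30, 40))
  seg <- sqrt(rowSums(diff(fr$position)^2))
  expect_true(all(seg < 10 + 0.05))  # chord <= arc
  expect_true(all(abs(sqrt(rowSums(fr$tangent^2)) - 1) < 1e-10))
})

test_that("geometry specs survive YAML and JSON round trips", {
  g <- build_stenosed_vessel(5, 40, list(stenosis_spec(12, 8, 53)),
                             bend_radius = 76, seed = 3)
  for (ext in c("yaml", "json")) {
    f <- withr::local_tempfile(fileext = paste0(".", ext))
    write_geometry_spec(g, f)
    g2 <- read_geometry_spec(f)
    expect_equal(g2$reference_diameter, g$reference_diameter)
    expect_equal(g2$total_length, g$total_length)
    expect_equal(g2$stenoses[[1]]$severity, 53)
    expect_identical(g2$frames, g$frames)
  }
})

test_that("the renal template matches its documented anatomy", {
  g <- renal_vessel_template(72)
  expect_equal(g$reference_diameter, 5)
  expect_equal(g$total_length, 40)
  expect_equal(g$stenoses[[1]]$center, 5)
  expect_equal(percent_diameter_stenosis(g), 72, tolerance = 1e-3)
  # 30 degree total bend: end tangents differ by 30 degrees
  fr <- centerline_at(g, c(0, 40))
  ang <- acos(sum(fr$tangent[1, ] * fr$tangent[2, ]))
  expect_equal(ang, 30 * pi / 180, tolerance = 1e-3)
  # severity 0 keeps the plane-defining (inactive) stenosis
  g0 <- renal_vessel_template(0)
  expect_length(g0$stenoses, 1)
  expect_equal(percent_diameter_stenosis(g0), 0, tolerance = 1e-8)
})
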