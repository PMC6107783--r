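test_that("time_average is the trapezoidal cycle mean", {
  # constant waveform, irregular sampling
  w <- waveform(c(0, 0.13, 0.4, 0.55, 0.8), rep(500, 5))
  expect_equal(time_average(w), 500)
  # offset sinusoid over exactly one period -> the offset
  t <- seq(0, 0.8, length.out = 400)
  w2 <- waveform(t, 7 + 3 * sin(2 * pi * t / 0.8))
  expect_equal(time_average(w2), 7, tolerance = 1e-3)
  # irregular ramp: trapezoid is exact for linear data, so the coarse
  # irregular samples must match a dense-quadrature oracle
  set.seed(42)
  ti <- sort(c(0, runif(15), 1))
  ramp <- function(x) 2 + 5 * x
  dense <- seq(0, 1, length.out = 200001)
  oracle <- sum(diff(dense) * (ramp(dense)[-1] + ramp(dense)[-200001]) / 2)
  expect_equal(time_average(waveform(ti, ramp(ti))), oracle,
               tolerance = 1e-10)
})

test_that("time_average is linear in the waveform", {
  set.seed(7)
  t <- sort(runif(30, 0, 0.8))
  v1 <- rnorm(30); v2 <- rnorm(30)
  for (ab in list(c(1, 1), c(2, -3), c(0.5, 10))) {
    lhs <- time_average(waveform(t, ab[1] * v1 + ab[2] * v2))
    rhs <- ab[1] * time_average(waveform(t, v1)) +
      ab[2] * time_average(waveform(t, v2))
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("malformed waveforms are rejected", {
  expect_error(waveform(0.5, 1), "2 samples")
  expect_error(waveform(c(0, 0.2, 0.2), c(1, 2, 3)), "increasing")
  expect_error(waveform(c(0, 0.2), c(1, 2, 3)), "length")
})

test_that("peripheral resistance is pressure drop over flow", {
  expect_equal(peripheral_resistance(10000, 1e-5), 1e9)
  expect_equal(peripheral_resistance(0, 1e-5), 0)
  expect_error(peripheral_resistance(10000, 0), "mean_flow")
  expect_error(peripheral_resistance(10000, -1e-5), "mean_flow")
})

test_that("plug inlet velocity is Q over A", {
  A <- pi * 0.0025^2
  expect_equal(plug_inlet_velocity(8e-6, A), 8e-6 / A)
  expect_equal(plug_inlet_velocity(8e-6, A), 0.4074, tolerance = 1e-3)
  expect_equal(plug_inlet_velocity(0, A), 0)
  expect_error(plug_inlet_velocity(8e-6, 0), "inlet_area")
})

test_that("the packaged resting conditions have physiological magnitudes", {
  gen <- generic_renal_conditions()
  expect_equal(gen$mean_flow * 6e7, 500, tolerance = 0.01)    # mL/min
  expect_equal(gen$mean_pressure, 13100, tolerance = 0.01)    # Pa
  expect_equal(gen$resistance, gen$mean_pressure / gen$mean_flow)
})

test_that("outlet-pressure tuning solves a linear flow-pressure relation", {
  # analytic resistive vessel: Q = (P_in - P_out) / R_pois
  mu <- 0.0035; L <- 0.04; R <- 0.002
  R_pois <- 8 * mu * L / (pi * R^4)
  P_in <- 13000
  solver <- function(p_out) (P_in - p_out) / R_pois
  target <- 6e-6
  p_true <- P_in - target * R_pois
  fit <- tune_outlet_pressure(solver, target, p_init = 8000, p_step = 2000,
                              tolerance = 1e-6)
  expect_equal(fit$pressure, p_true, tolerance = 1e-4)
  # bracketing walk plus at most 3 secant evaluations on a linear map
  expect_lte(fit$iterations, 5)
  expect_named(fit$trajectory, c("pressure", "flow"))
})

test_that("tuning returns immediately when the guess already satisfies", {
  solver <- function(p) 6e-6
  fit <- tune_outlet_pressure(solver, 6e-6, p_init = 1000)
  expect_identical(fit$iterations, 1L)
  expect_equal(fit$pressure, 1000)
})

test_that("an unreachable target errors and reports the best iterate", {
  solver <- function(p) 1e-6  # constant: target can never be met
  expect_error(
    tune_outlet_pressure(solver, 6e-6, p_init = 1000, max_iterations = 8),
    "best iterate")
})

test_that("tuning converges for any strictly decreasing map", {
  set.seed(11)
  for (k in 1:5) {
    slope <- -exp(rnorm(1))        # dQ/dP < 0
    q0 <- runif(1, 5e-6, 2e-5)
    solver <- function(p) q0 + slope * 1e-10 * p
    target <- q0 * runif(1, 0.3, 0.9)
    fit <- tune_outlet_pressure(solver, target, p_init = 500,
                                p_step = 4000, tolerance = 1e-4,
                                max_iterations = 20)
    expect_equal(fit$flow, target, tolerance = 1e-3)
  }
})
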