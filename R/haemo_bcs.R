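# Steady boundary conditions from pulsatile reference data: cycle-averaged
# inlet flow, peripheral-resistance (or fixed-pressure) outlet, and the
# outlet-pressure tuning loop used to hit a target flow.

#' Construct a waveform
#'
#' One heart cycle of flow or pressure samples. Units are whatever the
#' caller uses; [time_average()] preserves them.
#'
#' @param times sample times (s), strictly increasing
#' @param values sampled values (flow m^3/s or pressure Pa)
#' @return object of class `waveform`
#' @export
waveform <- function(times, values) {
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values)) stop("times and values differ in length")
  if (length(times) < 2) stop("a waveform needs at least 2 samples")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(list(times = times, values = values), class = "waveform")
}

#' Read a waveform from a two-column CSV
#'
#' Expected columns: time (s) then value; extra columns are ignored.
#'
#' @param path CSV file path
#' @return a `waveform`
#' @export
read_waveform <- function(path) {
  d <- utils::read.csv(path)
  waveform(d[[1]], d[[2]])
}

#' Time-average of a waveform over its cycle
#'
#' Time-weighted (trapezoidal) mean, \eqn{\frac{1}{T}\int w\,dt} — not a
#' plain sample mean, so irregular sampling is handled correctly.
#'
#' @param wave a `waveform`
#' @return steady scalar in the waveform's units
#' @export
time_average <- function(wave) {
  if (!inherits(wave, "waveform")) wave <- do.call(waveform, wave)
  t <- wave$times; v <- wave$values
  dt <- diff(t)
  sum(dt * (v[-1] + v[-length(v)]) / 2) / (t[length(t)] - t[1])
}

#' Peripheral resistance from mean pressure drop and mean flow
#'
#' The lumped resistance of the downstream microcirculation: ratio of the
#' pressure drop from the measurement point to the capillary level to the
#' flow through that point.
#'
#' @param mean_pressure_drop Pa
#' @param mean_flow m^3/s, must be > 0
#' @return resistance (Pa s / m^3)
#' @export
peripheral_resistance <- function(mean_pressure_drop, mean_flow) {
  if (!is.finite(mean_flow) || mean_flow <= 0) {
    stop("mean_flow must be > 0")
  }
  mean_pressure_drop / mean_flow
}

#' Plug inlet velocity magnitude
#'
#' Uniform ("plug") inlet speed `U = Q / A`, applied along the inward
#' normal of the inlet patch.
#'
#' @param flow_rate volumetric flow (m^3/s)
#' @param inlet_area inlet cross-sectional area (m^2), must be > 0
#' @return velocity magnitude (m/s)
#' @export
plug_inlet_velocity <- function(flow_rate, inlet_area) {
  if (!is.finite(inlet_area) || inlet_area <= 0) stop("inlet_area must be > 0")
  flow_rate / inlet_area
}

#' Assemble a flow case
#'
#' Fluid constants plus the boundary-condition set: blood as a Newtonian
#' fluid (defaults mu = 0.0035 Pa s, rho = 1066 kg/m^3), a plug inlet at a
#' prescribed flow rate, and either a peripheral-resistance outlet
#' (`P_out = reference_pressure + R * Q`) or a fixed outlet pressure.
#'
#' @param inlet_flow inlet volumetric flow rate (m^3/s)
#' @param outlet_mode `"resistance"` or `"fixed_pressure"`
#' @param resistance peripheral resistance (Pa s / m^3), resistance mode
#' @param reference_pressure distal reference pressure added to `R * Q`
#'   (Pa); also the fixed outlet pressure in `fixed_pressure` mode
#' @param viscosity dynamic viscosity (Pa s)
#' @param density fluid density (kg/m^3)
#' @return object of class `flow_case`
#' @export
flow_case <- function(inlet_flow,
                      outlet_mode = c("resistance", "fixed_pressure"),
                      resistance = 0, reference_pressure = 0,
                      viscosity = 0.0035, density = 1066) {
  outlet_mode <- match.arg(outlet_mode)
  if (viscosity <= 0 || density <= 0) stop("fluid constants must be > 0")
  if (inlet_flow < 0) stop("inlet_flow must be >= 0")
  if (outlet_mode == "resistance" && resistance < 0) {
    stop("resistance must be >= 0")
  }
  structure(list(
    fluid = list(viscosity = viscosity, density = density),
    inlet = list(flow_rate = inlet_flow, profile = "plug"),
    outlet = list(mode = outlet_mode, resistance = resistance,
                  reference_pressure = reference_pressure)
  ), class = "flow_case")
}

#' Representative resting renal boundary values
#'
#' The packaged synthetic resting waveforms (one heart cycle of renal
#' inflow and distal pressure, generic healthy-state values) reduced to
#' their cycle averages, plus the peripheral resistance they imply.
#' Defaults represent a resting single-kidney inflow of about 500 mL/min
#' and a mean distal pressure of about 13.1 kPa (~98 mmHg).
#'
#' @return list with `mean_flow` (m^3/s), `mean_pressure` (Pa),
#'   `resistance` (Pa s / m^3), and the two `waveform` objects
#' @export
generic_renal_conditions <- function() {
  qf <- read_waveform(system.file("extdata", "renal_flow_rest_synthetic.csv",
                                  package = "stenoflow", mustWork = TRUE))
  pf <- read_waveform(system.file("extdata",
                                  "renal_pressure_rest_synthetic.csv",
                                  package = "stenoflow", mustWork = TRUE))
  qm <- time_average(qf)
  pm <- time_average(pf)
  list(mean_flow = qm, mean_pressure = pm,
       resistance = peripheral_resistance(pm, qm),
       flow_waveform = qf, pressure_waveform = pf)
}

#' Tune the outlet pressure to reach a target flow
#'
#' Bracketed secant iteration with bisection fallback on the map
#' outlet pressure -> solved inlet flow (strictly decreasing for a
#' resistive vessel). Converges when the solved flow is within a relative
#' `tolerance` of `target_flow`.
#'
#' @param case_solver function taking an outlet pressure (Pa) and returning
#'   the solved flow (m^3/s)
#' @param target_flow desired flow (m^3/s), > 0
#' @param p_init initial outlet pressure guess (Pa)
#' @param p_step initial step used to build a bracket (Pa)
#' @param tolerance relative flow tolerance (default 0.01)
#' @param max_iterations maximum solver evaluations (default 20)
#' @return list with `pressure`, `flow`, `iterations`, `trajectory`
#'   (data.frame of evaluated pressure/flow pairs)
#' @export
tune_outlet_pressure <- function(case_solver, target_flow,
                                 p_init = 13000, p_step = 2000,
                                 tolerance = 0.01, max_iterations = 20) {
  if (!is.function(case_solver)) stop("case_solver must be a function")
  if (!is.finite(target_flow) || target_flow <= 0) {
    stop("target_flow must be > 0")
  }
  traj_p <- numeric(0); traj_q <- numeric(0)
  evals <- 0L
  f <- function(p) {
    evals <<- evals + 1L
    q <- case_solver(p)
    traj_p <<- c(traj_p, p); traj_q <<- c(traj_q, q)
    q - target_flow
  }
  done <- function(q) abs(q - target_flow) / target_flow <= tolerance
  result <- function(p, q) list(
    pressure = p, flow = q, iterations = evals,
    trajectory = data.frame(pressure = traj_p, flow = traj_q))

  r0 <- f(p_init)
  if (done(r0 + target_flow)) return(result(p_init, r0 + target_flow))
  # walk to bracket the root (flow decreases with outlet pressure)
  dir <- if (r0 > 0) +1 else -1
  p_lo <- p_init; r_lo <- r0
  p_hi <- NA; r_hi <- NA
  step <- p_step
  while (evals < max_iterations) {
    p_try <- p_lo + dir * step
    r_try <- f(p_try)
    if (done(r_try + target_flow)) return(result(p_try, r_try + target_flow))
    if (sign(r_try) != sign(r_lo)) {
      p_hi <- p_try; r_hi <- r_try
      break
    }
    p_lo <- p_try; r_lo <- r_try
    step <- step * 2
  }
  if (is.na(p_hi)) {
    best <- which.min(abs(traj_q - target_flow))
    stop("tune_outlet_pressure: no bracket found within ", max_iterations,
         " evaluations; best iterate P = ", signif(traj_p[best], 6),
         " Pa giving Q = ", signif(traj_q[best], 6), " m^3/s")
  }
  # secant within the bracket, bisection fallback
  while (evals < max_iterations) {
    denom <- r_hi - r_lo
    p_new <- if (abs(denom) > 0) p_lo - r_lo * (p_hi - p_lo) / denom
             else (p_lo + p_hi) / 2
    # keep strictly inside the bracket, else bisect
    lo <- min(p_lo, p_hi); hi <- max(p_lo, p_hi)
    if (!is.finite(p_new) || p_new <= lo || p_new >= hi) {
      p_new <- (p_lo + p_hi) / 2
    }
    r_new <- f(p_new)
    if (done(r_new + target_flow)) return(result(p_new, r_new + target_flow))
    if (sign(r_new) == sign(r_lo)) {
      p_lo <- p_new; r_lo <- r_new
    } else {
      p_hi <- p_new; r_hi <- r_new
    }
  }
  best <- which.min(abs(traj_q - target_flow))
  stop("tune_outlet_pressure: no convergence within ", max_iterations,
       " evaluations; best iterate P = ", signif(traj_p[best], 6),
       " Pa giving Q = ", signif(traj_q[best], 6), " m^3/s")
}
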