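# End-to-end orchestration: validated configuration, the single-case
# geometry -> mesh -> solve -> extract chain, the validation study against
# paired measured/virtual data, and the severity sweep.

.default_config <- function() {
  list(
    geometry = list(
      reference_diameter_mm = 5,
      length_mm = 40,
      bend_angle_deg = 30,
      stenoses = list(list(center_mm = 5, length_mm = 6, severity = 72)),
      seed = NULL
    ),
    mesh = list(
      target_density_per_mm3 = 200,
      n_wall_layers = 5,
      growth_ratio = 1.2
    ),
    fluid = list(viscosity_pa_s = 0.0035, density_kg_m3 = 1066),
    boundary_conditions = list(
      inlet_flow_ml_min = NULL,   # NULL: cycle average of packaged waveform
      outlet = list(mode = "resistance",
                    reference_pressure_pa = 0,
                    resistance_pa_s_m3 = NULL)  # NULL: from packaged values
    ),
    solver = list(nonlinear_tolerance = 1e-5,
                  max_nonlinear_iterations = 200),
    extraction = list(downstream_offsets_mm = c(10, 15, 20),
                      threshold = 0.9),
    seed = 1L,
    output_dir = "stenoflow-out"
  )
}

# recursive defaults merge: user values override package defaults
.merge_config <- function(defaults, user) {
  if (is.null(user)) return(defaults)
  for (nm in names(user)) {
    if (nm %in% names(defaults) && is.list(defaults[[nm]]) &&
        is.list(user[[nm]]) && nm != "stenoses") {
      defaults[[nm]] <- .merge_config(defaults[[nm]], user[[nm]])
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

.check_num <- function(x, name, lower = -Inf, upper = Inf,
                       allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    stop("config field '", name, "' is required")
  }
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    stop("config field '", name, "' must be a single finite number")
  }
  if (x < lower || x > upper) {
    stop("config field '", name, "' = ", x, " outside [", lower, ", ",
         upper, "]")
  }
  invisible(NULL)
}

#' Build and validate a pipeline configuration
#'
#' Merges user settings over the package defaults and schema-validates all
#' physical quantities (each field name carries its unit) before any
#' compute. Geometry defaults describe the renal-like template; boundary
#' defaults are completed from the packaged resting waveforms when left
#' `NULL`.
#'
#' @param config named list of overrides (possibly nested), or `NULL` for
#'   pure defaults
#' @return validated list of class `pipeline_config`
#' @export
pipeline_config <- function(config = NULL) {
  cfg <- .merge_config(.default_config(), config)
  g <- cfg$geometry
  .check_num(g$reference_diameter_mm, "geometry.reference_diameter_mm",
             lower = 1e-6)
  .check_num(g$length_mm, "geometry.length_mm", lower = 1e-6)
  .check_num(g$bend_angle_deg, "geometry.bend_angle_deg", lower = 0,
             upper = 180, allow_null = TRUE)
  if (!is.null(g$stenoses)) {
    if (is.data.frame(g$stenoses)) {
      g$stenoses <- split(g$stenoses, seq_len(nrow(g$stenoses)))
      cfg$geometry$stenoses <- g$stenoses
    }
    for (s in g$stenoses) {
      .check_num(s$center_mm, "stenosis center_mm", lower = 0,
                 upper = g$length_mm)
      .check_num(s$length_mm, "stenosis length_mm", lower = 1e-6)
      .check_num(s$severity, "stenosis severity", lower = 0, upper = 99.999)
    }
  }
  .check_num(cfg$mesh$target_density_per_mm3, "mesh.target_density_per_mm3",
             lower = 1e-9)
  .check_num(cfg$mesh$n_wall_layers, "mesh.n_wall_layers", lower = 0)
  .check_num(cfg$mesh$growth_ratio, "mesh.growth_ratio", lower = 1)
  .check_num(cfg$fluid$viscosity_pa_s, "fluid.viscosity_pa_s", lower = 1e-9)
  .check_num(cfg$fluid$density_kg_m3, "fluid.density_kg_m3", lower = 1e-9)
  bc <- cfg$boundary_conditions
  .check_num(bc$inlet_flow_ml_min, "boundary_conditions.inlet_flow_ml_min",
             lower = 0, allow_null = TRUE)
  if (!bc$outlet$mode %in% c("resistance", "fixed_pressure")) {
    stop("outlet mode must be 'resistance' or 'fixed_pressure'")
  }
  .check_num(bc$outlet$reference_pressure_pa,
             "outlet.reference_pressure_pa")
  .check_num(bc$outlet$resistance_pa_s_m3, "outlet.resistance_pa_s_m3",
             lower = 0, allow_null = TRUE)
  .check_num(cfg$solver$nonlinear_tolerance, "solver.nonlinear_tolerance",
             lower = 1e-300)
  .check_num(cfg$extraction$threshold, "extraction.threshold", lower = 0,
             upper = 1)
  .check_num(cfg$seed, "seed")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration file
#'
#' @param path YAML or JSON configuration
#' @return a validated `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::read_json(path,
                                                     simplifyVector = TRUE)
         else stop("unsupported config extension: ", ext)
  pipeline_config(raw)
}

# geometry object from the config block
.config_geometry <- function(cfg, severity_override = NULL) {
  g <- cfg$geometry
  stenoses <- lapply(g$stenoses, function(s) {
    sev <- if (is.null(severity_override)) s$severity else severity_override
    stenosis_spec(s$center_mm, s$length_mm, sev)
  })
  bend <- if (!is.null(g$bend_angle_deg) && g$bend_angle_deg > 0) {
    g$length_mm / (g$bend_angle_deg * pi / 180)
  } else {
    NULL
  }
  build_stenosed_vessel(g$reference_diameter_mm, g$length_mm, stenoses,
                        bend_radius = bend, seed = g$seed)
}

# flow case from the config block, falling back to the packaged resting
# waveform averages for unset flow / resistance
.config_case <- function(cfg) {
  bc <- cfg$boundary_conditions
  gen <- NULL
  Q <- if (is.null(bc$inlet_flow_ml_min)) {
    gen <- generic_renal_conditions()
    gen$mean_flow
  } else {
    bc$inlet_flow_ml_min / 6e7
  }
  R <- bc$outlet$resistance_pa_s_m3
  if (is.null(R) && bc$outlet$mode == "resistance") {
    if (is.null(gen)) gen <- generic_renal_conditions()
    R <- peripheral_resistance(
      gen$mean_pressure - bc$outlet$reference_pressure_pa, Q)
  }
  flow_case(inlet_flow = Q, outlet_mode = bc$outlet$mode,
            resistance = if (is.null(R)) 0 else R,
            reference_pressure = bc$outlet$reference_pressure_pa,
            viscosity = cfg$fluid$viscosity_pa_s,
            density = cfg$fluid$density_kg_m3)
}

.config_solver_params <- function(cfg) {
  solver_params(nonlinear_tolerance = cfg$solver$nonlinear_tolerance,
                max_nonlinear_iterations =
                  cfg$solver$max_nonlinear_iterations)
}

# provenance record: configuration digest + versions + seed
.provenance <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  list(config_md5 = unname(tools::md5sum(tmp)),
       package_version = as.character(utils::packageVersion("stenoflow")),
       r_version = paste(R.version$major, R.version$minor, sep = "."),
       seed = cfg$seed)
}

#' Run one virtual pressure-ratio case end to end
#'
#' Chains geometry synthesis, volume meshing, the steady Navier-Stokes
#' solve and the pressure-ratio extraction, writing all intermediate
#' artifacts (geometry spec, surface STL, solution fields, result and
#' provenance JSON) under the configured output directory. Deterministic
#' given the configuration (including its seed).
#'
#' @param config a `pipeline_config`, or a list of overrides
#' @param write_fields also export the solved fields as a legacy VTK file
#'   (can be large; default `TRUE`)
#' @return list with `geometry`, `mesh`, `solution`, `result`
#'   (a `pressure_ratio_result`), `significant`, and `artifact` paths
#' @export
run_virtual_case <- function(config = NULL, write_fields = TRUE) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else pipeline_config(config)
  set.seed(cfg$seed %% .Machine$integer.max)
  out <- cfg$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  step <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  geometry <- step("geometry", .config_geometry(cfg))
  mesh <- step("mesh", generate_volume_mesh(
    geometry,
    target_density = cfg$mesh$target_density_per_mm3,
    n_wall_layers = cfg$mesh$n_wall_layers,
    growth_ratio = cfg$mesh$growth_ratio))
  case <- step("boundary_conditions", .config_case(cfg))
  solution <- step("solve",
                   solve_steady_flow(mesh, case, .config_solver_params(cfg)))
  result <- step("extract", extract_pd_pa(
    solution, geometry,
    downstream_offsets = cfg$extraction$downstream_offsets_mm))

  artifacts <- list(
    geometry = file.path(out, "geometry.json"),
    surface = file.path(out, "surface.stl"),
    result = file.path(out, "result.json"),
    residuals = file.path(out, "residuals.csv"),
    provenance = file.path(out, "provenance.json")
  )
  write_geometry_spec(geometry, artifacts$geometry)
  write_stl(surface_mesh(geometry), artifacts$surface)
  write_pd_pa_result(result, artifacts$result)
  utils::write.csv(data.frame(iteration =
                                seq_along(solution$residual_history),
                              residual = solution$residual_history),
                   artifacts$residuals, row.names = FALSE)
  jsonlite::write_json(.provenance(cfg), artifacts$provenance,
                       auto_unbox = TRUE, digits = NA)
  if (write_fields) {
    artifacts$fields <- file.path(out, "solution.vtk")
    write_vtk_solution(solution, artifacts$fields)
  }
  list(geometry = geometry, mesh = mesh, solution = solution,
       result = result,
       significant = classify_physiological_significance(
         result$vPdPa, cfg$extraction$threshold),
       artifacts = artifacts)
}

#' Run the validation study on paired measured/virtual ratios
#'
#' Computes the full agreement report for a pairs file (columns `case_id`,
#' `mPdPa`, `vPdPa`) and writes the report JSON, the per-case table and the
#' figure data under `output_dir`. With `pairs_file = NULL` the packaged
#' validation cohort is used.
#'
#' @param pairs_file CSV path, or `NULL` for the packaged cohort
#' @param config optional `pipeline_config` (threshold, output directory)
#' @return the `agreement_report`, invisibly; printed when interactive
#' @export
run_validation_study <- function(pairs_file = NULL, config = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else pipeline_config(config)
  pairs <- if (is.null(pairs_file)) validation_cohort()
           else read_paired_series(pairs_file)
  report <- agreement_report(pairs, threshold = cfg$extraction$threshold)
  out <- file.path(cfg$output_dir, "validation")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write_agreement_report(report, file.path(out, "agreement_report.json"))
  utils::write.csv(report$diagnostic$per_case,
                   file.path(out, "per_case.csv"), row.names = FALSE)
  export_validation_figures(pairs, report, out)
  jsonlite::write_json(.provenance(cfg),
                       file.path(out, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}

#' Sweep stenosis severity on the configured template
#'
#' Solves one case per severity on a fixed mesh topology (so fields can be
#' warm-started from the previous severity) and tabulates severity, the
#' virtual pressure ratio, the inlet Reynolds number and convergence
#' diagnostics. A non-converged case is recorded and the sweep continues.
#'
#' @param config a `pipeline_config` or list of overrides
#' @param severities percent diameter stenoses in `[0, 95]`
#' @return data.frame with columns `severity`, `vPdPa`, `Re`, `Pa`,
#'   `Pd_mean`, `Pd_sd`, `converged`, `iterations`; written to
#'   `severity_sweep.csv` under the output directory
#' @export
run_severity_sweep <- function(config = NULL,
                               severities = c(0, 20, 40, 60, 72)) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else pipeline_config(config)
  if (any(severities < 0 | severities > 95)) {
    stop("severities must lie in [0, 95]")
  }
  set.seed(cfg$seed %% .Machine$integer.max)
  case <- .config_case(cfg)
  params <- .config_solver_params(cfg)
  # fixed topology from the first severity so solutions can be reused
  g0 <- .config_geometry(cfg, severity_override = severities[1])
  resolution <- generate_volume_mesh(
    g0, target_density = cfg$mesh$target_density_per_mm3,
    n_wall_layers = cfg$mesh$n_wall_layers,
    growth_ratio = cfg$mesh$growth_ratio)$resolution

  rows <- vector("list", length(severities))
  for (i in seq_along(severities)) {
    sev <- severities[i]
    rows[[i]] <- tryCatch({
      g <- .config_geometry(cfg, severity_override = sev)
      m <- generate_volume_mesh(
        g, target_density = cfg$mesh$target_density_per_mm3,
        n_wall_layers = cfg$mesh$n_wall_layers,
        growth_ratio = cfg$mesh$growth_ratio,
        resolution = resolution)
      # each severity is solved from the standard cold start: the jet
      # structure changes qualitatively between severities, and a field
      # transferred from a different lesion tends to start the iteration
      # in the basin of an oscillatory state rather than the steady one
      sol <- solve_steady_flow(m, case, params)
      pr <- extract_pd_pa(sol, g,
                          downstream_offsets =
                            cfg$extraction$downstream_offsets_mm)
      data.frame(severity = sev, vPdPa = pr$vPdPa,
                 Re = reynolds_number(case,
                                      g$reference_diameter * 1e-3),
                 Pa = pr$Pa_value, Pd_mean = pr$Pd_mean, Pd_sd = pr$Pd_sd,
                 converged = sol$converged,
                 iterations = length(sol$residual_history))
    }, error = function(e) {
      warning(sprintf("severity %g failed: %s", sev, conditionMessage(e)))
      data.frame(severity = sev, vPdPa = NA_real_, Re = NA_real_,
                 Pa = NA_real_, Pd_mean = NA_real_, Pd_sd = NA_real_,
                 converged = FALSE, iterations = NA_integer_)
    })
  }
  tab <- do.call(rbind, rows)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(tab, file.path(cfg$output_dir, "severity_sweep.csv"),
                   row.names = FALSE)
  tab
}
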