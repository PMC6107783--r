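# Virtual pressure-ratio protocol: area-averaged pressure on one upstream
# ("Bernoulli-safe") plane and three downstream planes within the
# catheter-measurement range, combined into vPd/Pa.

#' Extract the virtual Pd/Pa ratio from a flow solution
#'
#' Mirrors the catheter protocol: the distal pressure is sampled on three
#' cross-sectional planes 10-20 mm downstream of the stenosis end (by
#' default at +10, +15, +20 mm, compressed proportionally with a warning if
#' the vessel is shorter) and averaged arithmetically; the proximal plane
#' is placed at least two reference diameters upstream of the throat and at
#' least one diameter from the inlet, avoiding the pressure extremes of the
#' Bernoulli acceleration zone around the constriction. All planes are
#' cross-sections normal to the centerline.
#'
#' @param solution a converged `flow_solution`
#' @param geometry the `vessel_geometry` that was meshed (defaults to the
#'   geometry carried by the solution's mesh)
#' @param downstream_offsets distances past the stenosis end for the three
#'   distal planes (mm)
#' @return object of class `pressure_ratio_result` with fields `Pa_value`,
#'   `Pd_mean`, `Pd_sd` (Pa), `vPdPa`, `plane_locations` (arc length mm)
#' @export
extract_pd_pa <- function(solution, geometry = NULL,
                          downstream_offsets = c(10, 15, 20)) {
  if (is.null(geometry)) geometry <- solution$mesh$geometry
  if (length(geometry$stenoses) == 0) {
    stop("geometry has no stenosis; Pd/Pa extraction needs one")
  }
  L <- geometry$total_length
  D <- geometry$reference_diameter
  # most distal stenosis defines the measurement range
  ends <- vapply(geometry$stenoses, function(s) s$center + s$length / 2,
                 numeric(1))
  throats <- vapply(geometry$stenoses, function(s) s$center, numeric(1))
  sten_end <- max(ends)
  avail <- L - sten_end
  off <- sort(downstream_offsets)
  if (avail <= 0) stop("no vessel downstream of the stenosis")
  margin <- 0.5  # keep planes off the outlet boundary (mm)
  if (avail - margin < max(off)) {
    off <- off * (avail - margin) / max(off)
    warning(sprintf(
      "only %.1f mm of vessel downstream of the stenosis; downstream planes compressed to +%s mm",
      avail, paste(sprintf("%.1f", off), collapse = ", +")))
  }
  s_down <- sten_end + off
  # upstream plane: prefer 2 D upstream of the first throat but at least
  # 1 D from the inlet; for very proximal (ostial) lesions fall back to a
  # plane just before the constriction support, clear of the inlet boundary
  starts <- vapply(geometry$stenoses, function(s) s$center - s$length / 2,
                   numeric(1))
  preferred <- min(throats) - 2 * D
  s_up <- if (preferred >= D) preferred
          else max(min(0.8 * min(starts), D), 0.3 * D)
  if (s_up <= 0 || s_up >= min(throats)) {
    stop("no admissible upstream plane before the stenosis")
  }

  planes <- c(s_up, s_down)
  fr <- centerline_at(geometry, planes)
  pr <- lapply(seq_along(planes), function(i) {
    probe_plane(solution, fr$position[i, ], fr$tangent[i, ])
  })
  Pa_value <- pr[[1]]$pressure
  Pd <- vapply(pr[-1], `[[`, numeric(1), "pressure")
  res <- structure(list(
    Pa_value = Pa_value,
    Pd_mean = mean(Pd),
    Pd_sd = stats::sd(Pd),
    Pd_planes = Pd,
    vPdPa = mean(Pd) / Pa_value,
    plane_locations = list(upstream = s_up, downstream = s_down)
  ), class = "pressure_ratio_result")
  res
}

#' @export
print.pressure_ratio_result <- function(x, ...) {
  cat(sprintf("vPd/Pa = %.3f  (Pa %.0f Pa | Pd %.0f +/- %.0f Pa)\n",
              x$vPdPa, x$Pa_value, x$Pd_mean, x$Pd_sd))
  cat(sprintf("  planes: upstream %.1f mm, downstream %s mm\n",
              x$plane_locations$upstream,
              paste(sprintf("%.1f", x$plane_locations$downstream),
                    collapse = ", ")))
  invisible(x)
}

#' Classify physiological significance of a pressure ratio
#'
#' A stenosis is physiologically significant when the translesional
#' pressure ratio, rounded to two decimals as reported clinically, is at or
#' below the threshold (default 0.9). The rounding convention matters at
#' the boundary: a ratio of 0.903 rounds to 0.90 and is significant.
#'
#' @param vPdPa pressure ratio (> 0), vectorized
#' @param threshold significance threshold (default 0.9)
#' @return logical vector: `TRUE` = significant
#' @export
classify_physiological_significance <- function(vPdPa, threshold = 0.9) {
  if (any(vPdPa <= 0)) stop("pressure ratios must be > 0")
  round(vPdPa, 2) <= threshold + 1e-12
}

#' Serialize a pressure-ratio result
#'
#' @param result a `pressure_ratio_result`
#' @param path output `.json` or `.csv` file
#' @param case_id optional identifier stored with the record
#' @return `path`, invisibly
#' @export
write_pd_pa_result <- function(result, path, case_id = NA_character_) {
  rec <- list(case_id = case_id,
              Pa = result$Pa_value,
              Pd_mean = result$Pd_mean,
              Pd_sd = result$Pd_sd,
              vPdPa = result$vPdPa,
              plane_upstream_mm = result$plane_locations$upstream,
              planes_downstream_mm = result$plane_locations$downstream)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  } else if (ext == "csv") {
    df <- data.frame(case_id = case_id, Pa = result$Pa_value,
                     Pd_mean = result$Pd_mean, Pd_sd = result$Pd_sd,
                     vPdPa = result$vPdPa,
                     plane_upstream_mm = result$plane_locations$upstream,
                     planes_downstream_mm = paste(
                       sprintf("%.2f", result$plane_locations$downstream),
                       collapse = ";"))
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    stop("unsupported result extension: ", ext)
  }
  invisible(path)
}
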