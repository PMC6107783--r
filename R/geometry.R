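# Parametric stenosed-vessel geometry: analytic centerline + radius profile.
# All geometric quantities are in millimetres; SI conversion happens only
# inside the flow solver.

#' Describe a single stenosis
#'
#' A stenosis is a smooth axisymmetric constriction of the lumen, placed on
#' the vessel centerline by arc length. Severity follows the clinical
#' "diameter stenosis (%)" convention: percent reduction of lumen diameter
#' relative to the healthy reference diameter, so severity 72 leaves a
#' minimum diameter of 28% of the reference.
#'
#' @param center arc-length position of the throat along the centerline (mm)
#' @param length axial extent (support) of the constriction (mm)
#' @param severity percent diameter reduction, in `[0, 100)`
#' @return an object of class `stenosis_spec`
#' @examples
#' stenosis_spec(center = 5, length = 10, severity = 72)
#' @export
stenosis_spec <- function(center, length, severity) {
  stopifnot(is.numeric(center), is.numeric(length), is.numeric(severity))
  if (length <= 0) stop("stenosis length must be > 0")
  if (severity < 0 || severity >= 100) {
    stop("severity must be in [0, 100): got ", severity)
  }
  structure(list(center = as.numeric(center), length = as.numeric(length),
                 severity = as.numeric(severity)),
            class = "stenosis_spec")
}

# Cosine-bell constriction shape on [-1, 1]: 1 at the throat, C1-smoothly 0
# at the edges of the support. Pluggable through the `shape` argument of
# build_stenosed_vessel().
cosine_bell <- function(u) {
  out <- numeric(length(u))
  inside <- abs(u) < 1
  out[inside] <- 0.5 * (1 + cos(pi * u[inside]))
  out
}

#' Build a parametric stenosed vessel
#'
#' Constructs a smooth tubular geometry emulating a reconstructed renal
#' artery: a centerline (straight, circularly bent, or bent plus a seeded
#' tortuosity perturbation) and a radius profile combining the healthy
#' reference radius with cosine-bell constrictions, one per stenosis.
#' Stenoses must not overlap and must lie fully inside the vessel extent.
#'
#' @param reference_diameter healthy lumen diameter (mm)
#' @param length total vessel arc length (mm)
#' @param stenoses list of [stenosis_spec()] objects (possibly empty)
#' @param bend_radius optional radius (mm) of a planar circular bend of the
#'   centerline; `NULL` gives a straight vessel
#' @param seed optional integer; when given, a small smooth 3-D tortuosity
#'   perturbation is added deterministically from this seed
#' @param tortuosity_amplitude amplitude of the perturbation as a fraction of
#'   the reference radius (default 0.15; ignored when `seed` is `NULL`)
#' @param shape constriction shape function on `[-1, 1]` (default cosine bell)
#' @return an object of class `vessel_geometry`
#' @examples
#' g <- build_stenosed_vessel(5, 40, list(stenosis_spec(5, 10, 72)))
#' percent_diameter_stenosis(g)
#' @export
build_stenosed_vessel <- function(reference_diameter, length,
                                  stenoses = list(),
                                  bend_radius = NULL, seed = NULL,
                                  tortuosity_amplitude = 0.15,
                                  shape = cosine_bell) {
  if (!is.numeric(reference_diameter) || reference_diameter <= 0) {
    stop("reference_diameter must be > 0")
  }
  if (!is.numeric(length) || length <= 0) stop("length must be > 0")
  if (inherits(stenoses, "stenosis_spec")) stenoses <- list(stenoses)
  stenoses <- lapply(stenoses, function(s) {
    if (!inherits(s, "stenosis_spec")) {
      s <- do.call(stenosis_spec, as.list(s)[c("center", "length", "severity")])
    }
    s
  })
  # constriction support fully inside the vessel
  for (s in stenoses) {
    if (s$center - s$length / 2 < 0 || s$center + s$length / 2 > length) {
      stop("stenosis support [", s$center - s$length / 2, ", ",
           s$center + s$length / 2, "] mm extends outside the vessel [0, ",
           length, "] mm")
    }
  }
  # non-overlap of supports
  if (base::length(stenoses) > 1) {
    ord <- order(vapply(stenoses, `[[`, numeric(1), "center"))
    ss <- stenoses[ord]
    for (i in seq_len(base::length(ss) - 1)) {
      hi <- ss[[i]]$center + ss[[i]]$length / 2
      lo <- ss[[i + 1]]$center - ss[[i + 1]]$length / 2
      if (hi > lo) stop("stenoses overlap near s = ", round(hi, 2), " mm")
    }
  }
  if (!is.null(bend_radius) && bend_radius <= 0) stop("bend_radius must be > 0")

  geom <- structure(list(
    reference_diameter = as.numeric(reference_diameter),
    total_length = as.numeric(length),
    stenoses = stenoses,
    bend_radius = if (is.null(bend_radius)) NULL else as.numeric(bend_radius),
    seed = if (is.null(seed)) NULL else as.integer(seed),
    tortuosity_amplitude = as.numeric(tortuosity_amplitude),
    shape = shape
  ), class = "vessel_geometry")
  geom$frames <- .centerline_frames(geom)
  geom
}

#' Local lumen radius along the vessel
#'
#' @param geometry a `vessel_geometry`
#' @param s arc-length positions (mm), vectorized
#' @return local radii (mm)
#' @export
radius_at <- function(geometry, s) {
  r0 <- geometry$reference_diameter / 2
  red <- numeric(length(s))
  for (st in geometry$stenoses) {
    u <- (s - st$center) / (st$length / 2)
    red <- red + (st$severity / 100) * geometry$shape(u)
  }
  r0 * (1 - red)
}

# Dense centerline polyline with parallel-transport frames, reparameterized
# by true arc length so that radius_at() and centerline_at() share the same
# coordinate. Deterministic given the seed.
.centerline_frames <- function(geom, n = 1201L) {
  L <- geom$total_length
  t <- seq(0, 1, length.out = n)
  if (is.null(geom$bend_radius)) {
    P <- cbind(L * t, 0, 0)
  } else {
    Rb <- geom$bend_radius
    th <- L * t / Rb
    P <- cbind(Rb * sin(th), Rb * (1 - cos(th)), 0)
  }
  if (!is.null(geom$seed)) {
    amp <- geom$tortuosity_amplitude * geom$reference_diameter / 2
    rng <- .seeded_rng(geom$seed)
    # 3 low-frequency modes per transverse direction, zero at both ends
    for (dim in 2:3) {
      for (k in 1:3) {
        a <- amp / k * (2 * rng() - 1)
        P[, dim] <- P[, dim] + a * sin(pi * k * t)
      }
    }
  }
  seg <- sqrt(rowSums(diff(P)^2))
  sl <- c(0, cumsum(seg))
  # rescale so the total arc length equals the requested length exactly
  P <- P * (L / sl[n])
  sl <- sl * (L / sl[n])
  # resample uniformly in arc length via splines
  s_out <- seq(0, L, length.out = n)
  X <- vapply(1:3, function(d) stats::spline(sl, P[, d], xout = s_out)$y,
              numeric(n))
  # tangents from central differences on the uniform grid
  Tn <- apply(X, 2, function(col) {
    c(col[2] - col[1], (col[3:n] - col[1:(n - 2)]) / 2, col[n] - col[n - 1])
  })
  Tn <- Tn / sqrt(rowSums(Tn^2))
  # parallel transport of an initial normal
  N <- matrix(0, n, 3)
  t0 <- Tn[1, ]
  ref <- if (abs(t0[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  n0 <- ref - sum(ref * t0) * t0
  N[1, ] <- n0 / sqrt(sum(n0^2))
  for (i in 2:n) {
    v <- N[i - 1, ] - sum(N[i - 1, ] * Tn[i, ]) * Tn[i, ]
    N[i, ] <- v / sqrt(sum(v^2))
  }
  B <- cbind(Tn[, 2] * N[, 3] - Tn[, 3] * N[, 2],
             Tn[, 3] * N[, 1] - Tn[, 1] * N[, 3],
             Tn[, 1] * N[, 2] - Tn[, 2] * N[, 1])
  list(s = s_out, X = X, T = Tn, N = N, B = B)
}

# Small deterministic RNG (linear congruential) so geometry generation does
# not disturb R's global .Random.seed.
.seeded_rng <- function(seed) {
  state <- as.double(seed %% 2147483647)
  if (state <= 0) state <- state + 2147483646
  function() {
    state <<- (state * 16807) %% 2147483647
    state / 2147483647
  }
}

#' Centerline position and frame at given arc lengths
#'
#' Returns interpolated centerline points with unit tangent and a
#' parallel-transport normal/binormal pair (no torsion-induced twist), the
#' frame used to place mesh cross-sections.
#'
#' @param geometry a `vessel_geometry`
#' @param s arc-length positions (mm), vectorized
#' @return list with matrices `position`, `tangent`, `normal`, `binormal`
#'   (one row per entry of `s`)
#' @export
centerline_at <- function(geometry, s) {
  fr <- geometry$frames
  if (any(s < -1e-9 | s > geometry$total_length + 1e-9)) {
    stop("arc length outside [0, total_length]")
  }
  s <- pmin(pmax(s, 0), geometry$total_length)
  interp <- function(M) {
    matrix(vapply(1:3, function(d) stats::spline(fr$s, M[, d], xout = s)$y,
                  numeric(length(s))), ncol = 3)
  }
  pos <- interp(fr$X)
  tan <- interp(fr$T); tan <- tan / sqrt(rowSums(tan^2))
  nor <- interp(fr$N)
  nor <- nor - rowSums(nor * tan) * tan
  nor <- nor / sqrt(rowSums(nor^2))
  bin <- cbind(tan[, 2] * nor[, 3] - tan[, 3] * nor[, 2],
               tan[, 3] * nor[, 1] - tan[, 1] * nor[, 3],
               tan[, 1] * nor[, 2] - tan[, 2] * nor[, 1])
  list(position = pos, tangent = tan, normal = nor, binormal = bin)
}

#' Percent diameter stenosis of a geometry
#'
#' Inverse of the severity convention: `100 * (1 - min diameter / reference
#' diameter)`, with the minimum located by dense sampling plus local
#' refinement.
#'
#' @param geometry a `vessel_geometry`
#' @return percent diameter reduction (0 for an unobstructed vessel)
#' @export
percent_diameter_stenosis <- function(geometry) {
  s <- seq(0, geometry$total_length, length.out = 10000L)
  r <- radius_at(geometry, s)
  i <- which.min(r)
  lo <- s[max(1L, i - 2L)]; hi <- s[min(length(s), i + 2L)]
  opt <- stats::optimize(function(x) radius_at(geometry, x),
                         interval = c(lo, hi))
  rmin <- min(opt$objective, r[i])
  100 * (1 - 2 * rmin / geometry$reference_diameter)
}

#' Default renal-like vessel template
#'
#' A desk-scale stand-in for a reconstructed stenosed renal artery:
#' reference diameter 5 mm, length 40 mm, a single ostial stenosis centered
#' 5 mm from the inlet (renal stenoses cluster near the ostium) with a 6 mm
#' constriction support so a short healthy segment remains for the proximal
#' pressure plane, and a gentle 30 degree planar bend over the vessel
#' length to mimic tortuosity.
#'
#' @param severity percent diameter stenosis (default 72); 0 gives an
#'   unobstructed bent tube
#' @param stenosis_length axial support of the constriction (mm, default 6)
#' @param seed optional tortuosity seed forwarded to
#'   [build_stenosed_vessel()]
#' @return a `vessel_geometry`
#' @export
renal_vessel_template <- function(severity = 72, stenosis_length = 6,
                                  seed = NULL) {
  L <- 40
  bend <- L / (30 * pi / 180)  # total turn of 30 degrees
  # severity 0 keeps the (inactive) stenosis spec so the pressure-ratio
  # planes stay defined for unobstructed reference runs
  sten <- list(stenosis_spec(center = 5, length = stenosis_length,
                             severity = severity))
  build_stenosed_vessel(reference_diameter = 5, length = L, stenoses = sten,
                        bend_radius = bend, seed = seed)
}

#' @export
print.vessel_geometry <- function(x, ...) {
  cat("vessel_geometry: D_ref =", x$reference_diameter, "mm, L =",
      x$total_length, "mm,", length(x$stenoses), "stenosis/es",
      if (!is.null(x$bend_radius)) sprintf("(bend radius %.1f mm)",
                                           x$bend_radius) else "(straight)",
      "\n")
  for (s in x$stenoses) {
    cat(sprintf("  - severity %.1f%% at s = %.1f mm (length %.1f mm)\n",
                s$severity, s$center, s$length))
  }
  invisible(x)
}

#' Write / read a geometry specification
#'
#' Serializes the parametric description (not the discretized frames) to
#' YAML or JSON, chosen by file extension.
#'
#' @param geometry a `vessel_geometry`
#' @param path output file (`.yaml`, `.yml` or `.json`)
#' @return `path`, invisibly
#' @export
write_geometry_spec <- function(geometry, path) {
  spec <- list(
    reference_diameter_mm = geometry$reference_diameter,
    length_mm = geometry$total_length,
    bend_radius_mm = geometry$bend_radius,
    seed = geometry$seed,
    tortuosity_amplitude = geometry$tortuosity_amplitude,
    stenoses = lapply(geometry$stenoses, function(s) {
      list(center_mm = s$center, length_mm = s$length, severity = s$severity)
    })
  )
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(spec, path)
  } else if (ext == "json") {
    jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else {
    stop("unsupported geometry spec extension: ", ext)
  }
  invisible(path)
}

#' @rdname write_geometry_spec
#' @param path input file
#' @export
read_geometry_spec <- function(path) {
  ext <- tolower(tools::file_ext(path))
  spec <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported geometry spec extension: ", ext)
  }
  sl <- spec$stenoses
  if (is.data.frame(sl)) sl <- split(sl, seq_len(nrow(sl)))
  stenoses <- lapply(sl, function(s) {
    stenosis_spec(s$center_mm, s$length_mm, s$severity)
  })
  build_stenosed_vessel(
    reference_diameter = spec$reference_diameter_mm,
    length = spec$length_mm,
    stenoses = stenoses,
    bend_radius = spec$bend_radius_mm,
    seed = spec$seed,
    tortuosity_amplitude = if (is.null(spec$tortuosity_amplitude)) 0.15
                           else spec$tortuosity_amplitude
  )
}
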