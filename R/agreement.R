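# Agreement and diagnostic-accuracy statistics for paired measured/virtual
# translesional pressure ratios: Bland-Altman quantities, correlation, and
# threshold-based diagnostic metrics with exact binomial confidence
# intervals.

#' Paired measured/virtual pressure-ratio series
#'
#' @param case_ids identifiers (character or factor)
#' @param measured invasively measured Pd/Pa values
#' @param virtual CFD-derived vPd/Pa values
#' @return object of class `paired_series`
#' @export
paired_series <- function(case_ids, measured, virtual) {
  measured <- as.numeric(measured); virtual <- as.numeric(virtual)
  if (length(measured) != length(virtual)) {
    stop("measured and virtual series differ in length")
  }
  if (length(measured) < 2) stop("need at least 2 pairs")
  if (any(!is.finite(measured)) || any(!is.finite(virtual)) ||
      any(measured <= 0) || any(virtual <= 0)) {
    stop("all pressure ratios must be finite and > 0")
  }
  if (missing(case_ids) || is.null(case_ids)) {
    case_ids <- as.character(seq_along(measured))
  }
  structure(list(case_ids = as.character(case_ids),
                 measured = measured, virtual = virtual),
            class = "paired_series")
}

#' Read paired pressure ratios from CSV
#'
#' Expected columns: `case_id`, `mPdPa`, `vPdPa`.
#'
#' @param path CSV file
#' @return a `paired_series`
#' @export
read_paired_series <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", "mPdPa", "vPdPa")
  if (!all(need %in% names(d))) {
    stop("pairs file must have columns: ", paste(need, collapse = ", "))
  }
  paired_series(d$case_id, d$mPdPa, d$vPdPa)
}

#' The packaged validation cohort
#'
#' Seven stenosed renal arteries (six patients, one bilateral) with
#' invasively measured resting Pd/Pa and the CFD-derived vPd/Pa of the
#' validation study, as printed in the study report.
#'
#' @return a `paired_series` of 7 pairs
#' @export
validation_cohort <- function() {
  read_paired_series(system.file("extdata", "measured_virtual_pdpa.csv",
                                 package = "stenoflow", mustWork = TRUE))
}

#' Bland-Altman agreement quantities
#'
#' Differences are `measured - virtual`. The SD uses the n-1 denominator;
#' the 95% CI of the mean difference uses the Student t quantile with n-1
#' degrees of freedom; the limits of agreement are mean +/- 2 SD.
#'
#' @param pairs a `paired_series`
#' @param level confidence level for the CI of the mean difference
#' @return list with `mean_difference`, `sd_differences`,
#'   `ci_halfwidth`, `limits` (lower, upper), `n`
#' @export
bland_altman <- function(pairs, level = 0.95) {
  d <- pairs$measured - pairs$virtual
  n <- length(d)
  m <- mean(d)
  s <- stats::sd(d)
  tq <- stats::qt(1 - (1 - level) / 2, df = n - 1)
  list(mean_difference = m,
       sd_differences = s,
       ci_halfwidth = tq * s / sqrt(n),
       limits = c(lower = m - 2 * s, upper = m + 2 * s),
       n = n)
}

#' Mean absolute error of paired ratios
#'
#' @param pairs a `paired_series`
#' @return mean of `|measured - virtual|`
#' @export
mean_absolute_error <- function(pairs) {
  mean(abs(pairs$measured - pairs$virtual))
}

#' Percentage-error summaries of paired ratios
#'
#' Two common conventions are reported side by side: the mean absolute
#' error normalized by the mean measured value, and the mean of case-wise
#' relative absolute errors. They differ on real data; both are returned
#' rather than privileging either.
#'
#' @param pairs a `paired_series`
#' @return list with `mae_over_mean_measured_pct` and
#'   `mean_relative_error_pct`
#' @export
percentage_error <- function(pairs) {
  d <- abs(pairs$measured - pairs$virtual)
  list(mae_over_mean_measured_pct = 100 * mean(d) / mean(pairs$measured),
       mean_relative_error_pct = 100 * mean(d / pairs$measured))
}

#' Pearson correlation of paired ratios
#'
#' @param pairs a `paired_series`
#' @return sample product-moment correlation coefficient
#' @export
pearson_r <- function(pairs) {
  if (length(pairs$measured) < 3) stop("need at least 3 pairs")
  if (stats::sd(pairs$measured) == 0 || stats::sd(pairs$virtual) == 0) {
    stop("zero variance in one of the series")
  }
  stats::cor(pairs$measured, pairs$virtual)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' The "binomial test" interval: lower bound is the Beta quantile
#' `qbeta(alpha/2, x, n - x + 1)` (0 when x = 0), upper
#' `qbeta(1 - alpha/2, x + 1, n - x)` (1 when x = n).
#'
#' @param successes number of successes (0..trials)
#' @param trials number of trials (>= 1)
#' @param level confidence level (default 0.95)
#' @return numeric vector `c(lower, upper)`
#' @export
binomial_ci <- function(successes, trials, level = 0.95) {
  if (trials < 1) stop("trials must be >= 1")
  if (successes < 0 || successes > trials) {
    stop("successes must be in [0, trials]")
  }
  alpha <- 1 - level
  lower <- if (successes == 0) 0 else
    stats::qbeta(alpha / 2, successes, trials - successes + 1)
  upper <- if (successes == trials) 1 else
    stats::qbeta(1 - alpha / 2, successes + 1, trials - successes)
  c(lower = lower, upper = upper)
}

# proportion + exact CI helper; NA counts give an "undefined" record
.prop_ci <- function(x, n, level) {
  if (n == 0) {
    return(list(estimate = NA_real_, lower = NA_real_, upper = NA_real_,
                x = 0L, n = 0L))
  }
  ci <- binomial_ci(x, n, level)
  list(estimate = x / n, lower = unname(ci[1]), upper = unname(ci[2]),
       x = as.integer(x), n = as.integer(n))
}

#' Diagnostic accuracy of the virtual ratio against the measured reference
#'
#' Both series are classified as physiologically significant when the
#' value rounded to two decimals is at or below `threshold` (measured =
#' reference standard, virtual = index test). Returns the confusion matrix
#' and sensitivity, specificity, PPV, NPV and overall accuracy, each with
#' its exact Clopper-Pearson 95% CI; metrics with an empty denominator are
#' reported as undefined (`NA`) rather than erroring.
#'
#' @param pairs a `paired_series`
#' @param threshold significance threshold on Pd/Pa (default 0.9)
#' @param level confidence level (default 0.95)
#' @return list with `confusion` (TP, FP, TN, FN) and `metrics`
#' @export
diagnostic_accuracy <- function(pairs, threshold = 0.9, level = 0.95) {
  ref <- classify_physiological_significance(pairs$measured, threshold)
  test <- classify_physiological_significance(pairs$virtual, threshold)
  TP <- sum(ref & test); FN <- sum(ref & !test)
  FP <- sum(!ref & test); TN <- sum(!ref & !test)
  n <- length(ref)
  metrics <- list(
    sensitivity = .prop_ci(TP, TP + FN, level),
    specificity = .prop_ci(TN, TN + FP, level),
    ppv = .prop_ci(TP, TP + FP, level),
    npv = .prop_ci(TN, TN + FN, level),
    accuracy = .prop_ci(TP + TN, n, level)
  )
  list(confusion = c(TP = TP, FP = FP, TN = TN, FN = FN),
       per_case = data.frame(
         case_id = pairs$case_ids,
         measured = pairs$measured, virtual = pairs$virtual,
         reference_positive = ref, test_positive = test,
         outcome = ifelse(ref & test, "true positive",
                   ifelse(!ref & !test, "true negative",
                   ifelse(!ref & test, "false positive", "false negative"))),
         stringsAsFactors = FALSE),
       metrics = metrics, threshold = threshold, n = n)
}

#' Full agreement report for a paired series
#'
#' Combines Bland-Altman agreement, mean absolute error, percentage-error
#' variants, Pearson correlation and diagnostic accuracy into one record.
#'
#' @param pairs a `paired_series`
#' @param threshold significance threshold (default 0.9)
#' @return object of class `agreement_report`
#' @export
agreement_report <- function(pairs, threshold = 0.9) {
  ba <- bland_altman(pairs)
  structure(list(
    n = ba$n,
    bland_altman = ba,
    mean_absolute_error = mean_absolute_error(pairs),
    percentage_error = percentage_error(pairs),
    pearson_r = pearson_r(pairs),
    diagnostic = diagnostic_accuracy(pairs, threshold),
    pairs = pairs
  ), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  ba <- x$bland_altman
  cat(sprintf("agreement over %d stenoses (measured vs virtual Pd/Pa)\n",
              x$n))
  cat(sprintf("  mean difference %.3f (95%% CI +/- %.2f), SD %.3f\n",
              ba$mean_difference, ba$ci_halfwidth, ba$sd_differences))
  cat(sprintf("  limits of agreement [%.3f, %.3f] (mean +/- 2 SD)\n",
              ba$limits[1], ba$limits[2]))
  cat(sprintf("  mean absolute error %.3f | Pearson r %.3f\n",
              x$mean_absolute_error, x$pearson_r))
  pe <- x$percentage_error
  cat(sprintf("  percentage error: %.1f%% (MAE/mean measured) / %.1f%% (mean case-wise)\n",
              pe$mae_over_mean_measured_pct, pe$mean_relative_error_pct))
  cf <- x$diagnostic$confusion
  cat(sprintf("  confusion at Pd/Pa <= %.2g: TP %d FP %d TN %d FN %d\n",
              x$diagnostic$threshold, cf["TP"], cf["FP"], cf["TN"],
              cf["FN"]))
  for (nm in names(x$diagnostic$metrics)) {
    m <- x$diagnostic$metrics[[nm]]
    if (is.na(m$estimate)) {
      cat(sprintf("  %-12s undefined (0 denominator)\n", nm))
    } else {
      cat(sprintf("  %-12s %.2f (95%% CI %.2f-%.2f) [%d/%d]\n", nm,
                  m$estimate, m$lower, m$upper, m$x, m$n))
    }
  }
  invisible(x)
}

#' Export an agreement report as JSON
#'
#' @param report an `agreement_report`
#' @param path output `.json` path
#' @return `path`, invisibly
#' @export
write_agreement_report <- function(report, path) {
  out <- report
  out$pairs <- data.frame(case_id = report$pairs$case_ids,
                          mPdPa = report$pairs$measured,
                          vPdPa = report$pairs$virtual)
  class(out) <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Plot data and figures for the validation study
#'
#' Writes deterministic CSV plot data (side-by-side bar series, the
#' Bland-Altman points with center and +/- 2 SD lines, and the
#' measured-vs-virtual scatter with identity and ordinary-least-squares
#' best-fit lines), plus rendered SVG figures when the graphics device is
#' available.
#'
#' @param pairs a `paired_series`
#' @param report the corresponding `agreement_report`
#' @param dir output directory (created if missing)
#' @param render also render SVG figures (default `TRUE`)
#' @return invisibly, a list with the OLS fit (`intercept`, `slope`) and
#'   the file paths written
#' @export
export_validation_figures <- function(pairs, report, dir,
                                      render = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)

  # bar-plot series: measured and virtual side by side per case
  bars <- data.frame(case_id = pairs$case_ids,
                     mPdPa = pairs$measured, vPdPa = pairs$virtual)
  f <- file.path(dir, "pdpa_bars.csv")
  utils::write.csv(bars, f, row.names = FALSE); files <- c(files, f)

  # Bland-Altman points and reference lines
  ba <- report$bland_altman
  bad <- data.frame(case_id = pairs$case_ids,
                    mean_of_pair = (pairs$measured + pairs$virtual) / 2,
                    difference = pairs$measured - pairs$virtual)
  f <- file.path(dir, "bland_altman_points.csv")
  utils::write.csv(bad, f, row.names = FALSE); files <- c(files, f)
  lines <- data.frame(line = c("mean", "upper_2sd", "lower_2sd"),
                      value = c(ba$mean_difference, ba$limits[2],
                                ba$limits[1]))
  f <- file.path(dir, "bland_altman_lines.csv")
  utils::write.csv(lines, f, row.names = FALSE); files <- c(files, f)

  # scatter with identity and OLS best fit (virtual regressed on measured)
  fit <- stats::lm(virtual ~ measured,
                   data = data.frame(measured = pairs$measured,
                                     virtual = pairs$virtual))
  co <- stats::coef(fit)
  sc <- data.frame(case_id = pairs$case_ids, mPdPa = pairs$measured,
                   vPdPa = pairs$virtual)
  f <- file.path(dir, "correlation_scatter.csv")
  utils::write.csv(sc, f, row.names = FALSE); files <- c(files, f)
  f <- file.path(dir, "correlation_fit.csv")
  utils::write.csv(data.frame(intercept = co[1], slope = co[2],
                              pearson_r = report$pearson_r),
                   f, row.names = FALSE); files <- c(files, f)

  if (render && capabilities("cairo")) {
    rng <- range(c(pairs$measured, pairs$virtual))
    f <- file.path(dir, "pdpa_bars.svg")
    grDevices::svg(f, width = 7, height = 4.5)
    graphics::barplot(t(as.matrix(bars[, c("mPdPa", "vPdPa")])),
                      beside = TRUE, names.arg = bars$case_id,
                      col = c("grey30", "grey70"),
                      ylab = "Pd/Pa", xlab = "stenosis",
                      ylim = c(0, 1.1))
    graphics::abline(h = 0.9, lty = 3)
    graphics::legend("bottomright", c("measured", "virtual"),
                     fill = c("grey30", "grey70"), bty = "n")
    grDevices::dev.off(); files <- c(files, f)

    f <- file.path(dir, "bland_altman.svg")
    grDevices::svg(f, width = 6, height = 4.5)
    graphics::plot(bad$mean_of_pair, bad$difference,
                   pch = 19, xlab = "mean of measured and virtual Pd/Pa",
                   ylab = "difference (measured - virtual)",
                   ylim = range(c(bad$difference, ba$limits)) +
                     c(-0.02, 0.02))
    graphics::abline(h = ba$mean_difference, lty = 1)
    graphics::abline(h = ba$limits, lty = 3)
    grDevices::dev.off(); files <- c(files, f)

    f <- file.path(dir, "correlation.svg")
    grDevices::svg(f, width = 5.5, height = 5.5)
    graphics::plot(pairs$measured, pairs$virtual, pch = 19,
                   xlim = rng, ylim = rng,
                   xlab = "measured Pd/Pa", ylab = "virtual Pd/Pa")
    graphics::abline(0, 1, lty = 2, col = "grey50")
    graphics::abline(co[1], co[2], lty = 1)
    grDevices::dev.off(); files <- c(files, f)
  }
  invisible(list(ols = c(intercept = unname(co[1]), slope = unname(co[2])),
                 files = files))
}
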