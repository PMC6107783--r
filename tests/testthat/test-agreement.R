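test_that("the validation cohort reproduces the reported statistics", {
  pairs <- validation_cohort()
  expect_identical(length(pairs$measured), 7L)
  ba <- bland_altman(pairs)
  expect_equal(ba$mean_difference, 0.015, tolerance = 1e-6)
  expect_equal(ba$sd_differences, 0.087, tolerance = 0.005)
  expect_equal(ba$ci_halfwidth, 0.08, tolerance = 0.01)
  expect_equal(mean_absolute_error(pairs), 0.064, tolerance = 0.005)
  expect_equal(pearson_r(pairs), 0.604, tolerance = 0.001)
  # limits of agreement bracket the mean difference at +/- 2 SD
  expect_equal(unname(ba$limits),
               ba$mean_difference + c(-2, 2) * ba$sd_differences)
})

test_that("degenerate paired series behave sensibly", {
  same <- paired_series(NULL, c(0.9, 0.8, 0.7), c(0.9, 0.8, 0.7))
  ba <- bland_altman(same)
  expect_identical(ba$mean_difference, 0)
  expect_identical(ba$sd_differences, 0)
  expect_identical(mean_absolute_error(same), 0)
  hand <- paired_series(NULL, c(1.0, 0.8), c(0.9, 1.0))
  expect_equal(mean_absolute_error(hand), 0.15)
  expect_error(paired_series(NULL, c(1, 2), c(1, 2, 3)), "length")
  expect_error(paired_series(NULL, 1, 1), "2 pairs")
  expect_error(paired_series(NULL, c(1, -1), c(1, 1)), "> 0")
})

test_that("pearson_r matches its definitional computation", {
  set.seed(5)
  for (k in 1:5) {
    m <- runif(9, 0.5, 1.1); v <- m + rnorm(9, 0, 0.05)
    p <- paired_series(NULL, m, v)
    num <- sum((m - mean(m)) * (v - mean(v)))
    den <- sqrt(sum((m - mean(m))^2) * sum((v - mean(v))^2))
    expect_equal(pearson_r(p), num / den, tolerance = 1e-12)
  }
  lin <- paired_series(NULL, 1:5 / 10 + 0.5, 2 * (1:5 / 10) + 0.1)
  expect_equal(pearson_r(lin), 1, tolerance = 1e-12)
  expect_error(pearson_r(paired_series(NULL, rep(0.9, 4),
                                       c(0.7, 0.8, 0.9, 1.0))),
               "variance")
  expect_error(pearson_r(paired_series(NULL, c(1, 2), c(1, 2))), "3 pairs")
})

test_that("agreement statistics obey sign and scale symmetries", {
  set.seed(9)
  m <- runif(8, 0.6, 1.05); v <- runif(8, 0.6, 1.05)
  a <- paired_series(NULL, m, v)
  b <- paired_series(NULL, v, m)  # swapped
  expect_equal(bland_altman(b)$mean_difference,
               -bland_altman(a)$mean_difference, tolerance = 1e-14)
  expect_equal(bland_altman(b)$sd_differences,
               bland_altman(a)$sd_differences, tolerance = 1e-14)
  expect_equal(mean_absolute_error(b), mean_absolute_error(a),
               tolerance = 1e-14)
  expect_equal(pearson_r(b), pearson_r(a), tolerance = 1e-12)
  sc <- paired_series(NULL, 3.7 * m, 3.7 * v)
  expect_equal(pearson_r(sc), pearson_r(a), tolerance = 1e-12)
})

test_that("the diagnostic confusion matrix matches the reported counts", {
  diag <- diagnostic_accuracy(validation_cohort())
  expect_identical(unname(diag$confusion),
                   c(4L, 1L, 2L, 0L))  # TP FP TN FN
  expect_equal(diag$metrics$sensitivity$estimate, 1)
  expect_equal(diag$metrics$specificity$estimate, 2 / 3)
  expect_equal(diag$metrics$ppv$estimate, 0.8)
  expect_equal(diag$metrics$npv$estimate, 1)
  expect_equal(diag$metrics$accuracy$estimate, 6 / 7)
  # the single discordant stenosis: measured negative, virtual positive
  disc <- diag$per_case[diag$per_case$outcome == "false positive", ]
  expect_identical(disc$case_id, "6")
  # printed-style CI bounds
  expect_equal(diag$metrics$sensitivity$lower, 0.3976, tolerance = 1e-3)
  expect_equal(diag$metrics$sensitivity$upper, 1)
})

test_that("metrics with empty denominators are undefined, not errors", {
  allpos <- paired_series(NULL, c(0.7, 0.8, 0.85), c(0.72, 0.79, 0.86))
  diag <- diagnostic_accuracy(allpos)
  expect_equal(diag$metrics$sensitivity$estimate, 1)
  expect_equal(diag$metrics$accuracy$estimate, 1)
  expect_true(is.na(diag$metrics$specificity$estimate))
  expect_true(is.na(diag$metrics$npv$estimate))
})

test_that("confusion counts match brute force over all outcome patterns", {
  # 4 pairs, each independently concordant/discordant in every direction
  vals <- list(c(0.80, 0.80),  # TP: both positive
               c(0.95, 0.80),  # FP: measured neg, virtual pos
               c(0.95, 0.95),  # TN
               c(0.80, 0.95))  # FN
  for (pattern in seq_len(4^4)) {
    idx <- (pattern - 1) %/% 4^(0:3) %% 4 + 1
    m <- vapply(idx, function(i) vals[[i]][1], numeric(1))
    v <- vapply(idx, function(i) vals[[i]][2], numeric(1))
    diag <- diagnostic_accuracy(paired_series(NULL, m, v))
    brute <- c(TP = sum(idx == 1), FP = sum(idx == 2),
               TN = sum(idx == 3), FN = sum(idx == 4))
    expect_identical(diag$confusion[names(brute)], brute)
    expect_identical(sum(diag$confusion), 4L)
  }
})

test_that("binomial_ci is the exact Clopper-Pearson interval", {
  ci <- binomial_ci(4, 4)
  expect_equal(unname(ci[1]), 0.025^(1 / 4), tolerance = 1e-12)
  expect_identical(unname(ci[2]), 1)
  expect_equal(unname(binomial_ci(2, 2)[1]), sqrt(0.025), tolerance = 1e-12)
  # against the independent implementation in stats::binom.test
  for (n in 1:7) for (x in 0:n) {
    expect_equal(unname(binomial_ci(x, n)),
                 as.numeric(stats::binom.test(x, n)$conf.int),
                 tolerance = 1e-10)
  }
  expect_error(binomial_ci(1, 0), "trials")
  expect_error(binomial_ci(5, 4), "successes")
})

test_that("figure export writes deterministic plot data with an OLS fit", {
  pairs <- validation_cohort()
  report <- agreement_report(pairs)
  dir <- withr::local_tempdir()
  out <- export_validation_figures(pairs, report, dir, render = FALSE)
  # OLS against the normal equations
  X <- cbind(1, pairs$measured)
  beta <- solve(t(X) %*% X, t(X) %*% pairs$virtual)
  expect_equal(unname(out$ols), as.numeric(beta), tolerance = 1e-10)
  lines <- utils::read.csv(file.path(dir, "bland_altman_lines.csv"))
  ba <- report$bland_altman
  expect_equal(lines$value,
               unname(c(ba$mean_difference, ba$limits[2], ba$limits[1])),
               tolerance = 1e-12)
  # identical series fall on the identity line
  same <- paired_series(NULL, c(0.7, 0.8, 0.9), c(0.7, 0.8, 0.9))
  rep2 <- agreement_report(same)
  out2 <- export_validation_figures(same, rep2, withr::local_tempdir(),
                                    render = FALSE)
  expect_equal(unname(out2$ols), c(0, 1), tolerance = 1e-10)
})

test_that("Clopper-Pearson coverage meets its nominal level by simulation", {
  set.seed(20180817)
  n <- 7; p <- 0.5; reps <- 10000
  x <- stats::rbinom(reps, n, p)
  covered <- vapply(x, function(xi) {
    ci <- binomial_ci(xi, n)
    ci[1] <= p && p <= ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.94)
})
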