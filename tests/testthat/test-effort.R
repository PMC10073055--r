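test_that("effort_to_fraction scans the curve with an unrounded threshold", {
  expect_equal(effort_to_fraction(c(1, 1, 2, 3), 0.75), 4L)  # threshold 2.25
  expect_equal(effort_to_fraction(c(1, 1, 2, 3), 1), 4L)
  expect_equal(effort_to_fraction(c(1, 1, 2, 3), 1e-9), 1L)
  expect_equal(effort_to_fraction(c(2, 2, 2), 1), 1L)
  expect_error(effort_to_fraction(c(1, 2), 0),
               class = "effortdiv_validation_error")
  expect_error(effort_to_fraction(c(1, 2), 1.1),
               class = "effortdiv_validation_error")
})

test_that("effort_to_fraction is monotone in the fraction", {
  withr::local_seed(53)
  for (rep in 1:30) {
    curve <- cumsum(stats::rpois(12, 0.7))
    if (curve[12] == 0) next
    ps <- sort(stats::runif(4, 0.05, 1))
    ks <- vapply(ps, function(p) effort_to_fraction(curve, p), integer(1))
    expect_true(all(diff(ks) >= 0))
  }
})

test_that("h_100 equals the first haul whose cumulative species set is complete", {
  for (seed in 1:3) {
    sim <- generate_study(community_params(n_sites = 6, hauls_per_site = 12),
                          seed = seed)
    curves <- accumulation_curve(sim$hauls, "richness")
    for (site in unique(sim$hauls$site_id)) {
      curve <- curves$value[curves$site_id == site]
      expect_equal(effort_to_fraction(curve, 1),
                   oracle_h100_setwise(sim$hauls, site))
    }
  }
})

test_that("stabilization effort finds the entry into the terminal band", {
  expect_equal(stabilization_effort(rep(0.4, 6), epsilon = 0.01), 1L)
  expect_equal(stabilization_effort(c(0.9, 0.5, 0.5, 0.5), epsilon = 0.01), 2L)
  expect_equal(stabilization_effort(c(0.9, 0.5, 0.6, 0.5), epsilon = 0.5), 1L)
  expect_equal(stabilization_effort(c(1, 2, 3, 4), epsilon = 0.1), 4L)
  expect_true(is.na(stabilization_effort(c(1, 2, 3, 4), epsilon = 0.1,
                                         window = 2)))
})

test_that("site summaries satisfy their structural invariants on synthetic data", {
  sim <- generate_study(mrg_like_preset(), seed = 29)
  s <- site_summaries(sim$hauls, sim$covariates)
  expect_equal(nrow(s), 20)
  expect_true(all(s$s_5 <= s$s_10 & s$s_10 <= s$s_20 & s$s_20 <= s$s_40))
  expect_true(all(s$s_chao >= s$s_40))
  expect_true(all(s$h_75 >= 1 & s$h_75 <= s$h_100 & s$h_100 <= 40))
  expect_true(all(c("wetted_width", "mean_depth", "prop_run") %in% names(s)))

  expect_error(site_summaries(sim$hauls, sim$covariates[-1, ]),
               class = "effortdiv_validation_error", regexp = "site01")
})

test_that("a single-species site reaches both thresholds at its first capture", {
  solo <- degenerate_cases()$single_species
  s <- site_summaries(solo, checkpoints = c(1L, 3L), fractions = c(0.75, 1))
  expect_equal(s$h_75, 1L)
  expect_equal(s$h_100, 1L)
})

test_that("effort regression recovers a perfect linear relationship", {
  dat <- tibble::tibble(site_id = as.character(1:5),
                        wetted_width = c(2, 4, 6, 8, 10),
                        h_75 = 1 + 2 * c(2, 4, 6, 8, 10))
  fit <- effort_regression(dat, "h_75", "wetted_width")
  # summary.lm warns about the noise-free fit; the estimates are exact
  tt <- suppressWarnings(tidy(fit))
  expect_equal(tt$estimate[tt$term == "wetted_width"], 2)
  expect_equal(suppressWarnings(glance(fit))$adj.r.squared, 1)
  expect_lt(tt$p.value[tt$term == "wetted_width"], 1e-6)

  const <- dplyr::mutate(dat, wetted_width = 3)
  expect_error(effort_regression(const, "h_75", "wetted_width"),
               class = "effortdiv_validation_error", regexp = "constant")
})

test_that("null predictors give slope estimates centred on zero", {
  withr::local_seed(59)
  slopes <- replicate(200, {
    s <- linked_site_summaries(n_sites = 20, slope = 0, sigma = 5,
                               seed = sample.int(1e6, 1))
    fit <- effort_regression(s, "response", "wetted_width")
    tidy(fit)$estimate[2]
  })
  expect_lt(abs(mean(slopes)), 0.05)
})

test_that("regression standard errors are calibrated (2-SE coverage)", {
  true_slope <- 0.15
  hits <- vapply(1:1000, function(seed) {
    s <- linked_site_summaries(n_sites = 50, slope = true_slope,
                               intercept = 8, sigma = 4, seed = seed)
    tt <- tidy(effort_regression(s, "response", "wetted_width"))
    abs(tt$estimate[2] - true_slope) <= 2 * tt$std.error[2]
  }, logical(1))
  expect_gte(mean(hits), 0.93)
})

test_that("adjusted R^2 is reported unclamped (negative for null predictors)", {
  fit <- effort_regression(table1_fixture(), "h_75", "wetted_width")
  expect_lt(glance(fit)$adj.r.squared, 0)
})

test_that("the full study report runs end to end on synthetic data", {
  sim <- generate_study(mrg_like_preset(), seed = 61)
  rep_full <- suppressWarnings(study_report(sim$hauls, sim$covariates))
  expect_s3_class(rep_full, "effort_report")
  expect_equal(nrow(rep_full$regressions), 6)
  expect_true(all(is.finite(rep_full$regressions$slope)))
  expect_true(all(is.finite(rep_full$regressions$adj_r2)))
  expect_equal(nrow(rep_full$beta_curve), 40)
  # report means equal the arithmetic means of the per-site columns
  expect_equal(
    rep_full$summary_stats$mean[rep_full$summary_stats$statistic == "h_75"],
    mean(rep_full$site_summaries$h_75)
  )

  outdir <- withr::local_tempdir()
  write_report(rep_full, outdir, plots = FALSE)
  expect_true(file.exists(file.path(outdir, "site_summaries.csv")))
  expect_true(file.exists(file.path(outdir, "report.json")))

  p <- autoplot(rep_full, "beta")
  expect_s3_class(p, "ggplot")
})

test_that("summaries-only mode reproduces the regression table without curves", {
  rep_fix <- study_report(NULL, summaries = table1_fixture())
  expect_null(rep_fix$alpha_curves)
  expect_equal(nrow(rep_fix$regressions), 6)
  slope <- rep_fix$regressions$slope[
    rep_fix$regressions$response == "h_75" &
      rep_fix$regressions$predictor == "wetted_width"]
  expect_equal(round(slope, 2), -0.03)
})
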