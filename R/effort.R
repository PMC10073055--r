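#' Effort needed to reach a fraction of full-effort richness
#'
#' Given a collector-order richness curve `v_1..v_K`, returns the smallest
#' `k` with `v_k >= p * v_K`. The fractional threshold is not rounded: with
#' a final richness of 6 and `p = 0.75` the threshold is 4.5, first met when
#' 5 species have accumulated. `k = K` always qualifies, so the result is
#' well defined for any `p <= 1`.
#'
#' @param values Numeric vector: a per-effort diversity curve (typically
#'   richness, which is non-decreasing).
#' @param p Fraction of the final value to reach, in `(0, 1]`.
#' @return The smallest qualifying effort `k` (integer).
#' @examples
#' effort_to_fraction(c(1, 1, 2, 3), 0.75)  # threshold 2.25 -> k = 4
#' effort_to_fraction(c(1, 1, 2, 3), 1)     # k = 4
#' @export
effort_to_fraction <- function(values, p) {
  if (!is.numeric(values) || length(values) == 0 || any(is.na(values))) {
    stop_validation("values must be a non-empty numeric curve")
  }
  if (!is.numeric(p) || length(p) != 1 || p <= 0 || p > 1) {
    stop_validation("p must be a single fraction in (0, 1]")
  }
  threshold <- p * values[length(values)]
  as.integer(which(values >= threshold)[1])
}

#' Effort at which a diversity curve stabilizes
#'
#' Operationalizes "the curve stabilized after k hauls": the smallest `k`
#' such that every later value (including `v_k` itself) stays within
#' `epsilon` of the final value `v_K`. `window` requires the stable tail to
#' contain at least that many points; if the band is only entered at the very
#' end and the tail is shorter than `window`, the curve is deemed not to have
#' stabilized and `NA` is returned.
#'
#' @param values Numeric curve `v_1..v_K`.
#' @param epsilon Half-width of the stability band around `v_K` (> 0). In
#'   reporting defaults the package uses 0.5 species for richness curves and
#'   0.02 for Simpson and beta-partition curves.
#' @param window Minimum number of trailing points required inside the band
#'   (default 1).
#' @return Integer effort, or `NA_integer_` if the window criterion fails.
#' @examples
#' stabilization_effort(c(0.9, 0.5, 0.5, 0.5), epsilon = 0.01)  # 2
#' @export
stabilization_effort <- function(values, epsilon, window = 1L) {
  if (!is.numeric(values) || length(values) == 0 || any(is.na(values))) {
    stop_validation("values must be a non-empty numeric curve")
  }
  if (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon <= 0) {
    stop_validation("epsilon must be a single positive number")
  }
  kk <- length(values)
  if (!is.numeric(window) || window < 1 || window > kk) {
    stop_validation("window must be an integer in [1, length(values)]")
  }
  inside <- abs(values - values[kk]) <= epsilon
  # smallest k with all of k..K inside the band
  outside <- which(!inside)
  k <- if (length(outside) == 0) 1L else as.integer(max(outside) + 1L)
  if (kk - k + 1L < window) {
    return(NA_integer_)
  }
  k
}

#' Per-site effort and diversity summaries
#'
#' Builds the per-site summary table: richness checkpoints along the
#' collector-order accumulation curve, the bias-corrected Chao1 estimate at
#' full effort, hauls needed to reach each requested fraction of full-effort
#' richness, and (optionally) site covariates.
#'
#' @param x A validated haul table in which every site has at least
#'   `max(checkpoints)` hauls.
#' @param covariates Optional data frame with columns `site_id`,
#'   `wetted_width`, `mean_depth`, `prop_run` (any subset of the three
#'   covariates). Every site in `x` must appear.
#' @param checkpoints Efforts at which to report observed richness (default
#'   5, 10, 20, 40 hauls, reported as `s_5` ... `s_40`).
#' @param fractions Richness fractions for effort thresholds (default 0.75
#'   and 1, reported as `h_75` and `h_100`).
#' @return A tibble with one row per site. Richness checkpoints are
#'   non-decreasing across effort by construction, `s_chao >= s_40`, and
#'   `h_75 <= h_100`.
#' @export
site_summaries <- function(x, covariates = NULL,
                           checkpoints = c(5L, 10L, 20L, 40L),
                           fractions = c(0.75, 1)) {
  x <- validate_haul_table(x)
  checkpoints <- sort(unique(as.integer(checkpoints)))
  ks <- tapply(x$haul_number, x$site_id, max)
  short <- names(ks)[ks < max(checkpoints)]
  if (length(short) > 0) {
    stop_validation(sprintf(
      "site(s) with fewer than %d hauls: %s (reduce checkpoints or drop sites)",
      max(checkpoints), paste(short, collapse = ", ")
    ))
  }
  out <- purrr::map_dfr(split(x, x$site_id), function(rows) {
    cum <- site_cumulative_matrix(rows, kmax = max(checkpoints))
    rich <- stat_from_cumulative(cum, "richness")
    final <- pool_counts(rows, rows$site_id[1], max(checkpoints))
    row <- tibble::tibble(site_id = rows$site_id[1])
    for (cp in checkpoints) {
      row[[paste0("s_", cp)]] <- as.integer(rich[cp])
    }
    row$s_chao <- chao1_bc(final)
    for (p in fractions) {
      row[[sprintf("h_%g", p * 100)]] <- effort_to_fraction(rich, p)
    }
    row
  })
  if (!is.null(covariates)) {
    covariates <- tibble::as_tibble(covariates)
    if (!"site_id" %in% names(covariates)) {
      stop_schema("covariates need a site_id column")
    }
    covariates$site_id <- as.character(covariates$site_id)
    absent <- setdiff(out$site_id, covariates$site_id)
    if (length(absent) > 0) {
      stop_validation(sprintf("missing covariates for site(s): %s",
                              paste(absent, collapse = ", ")))
    }
    check_site_covariates(covariates)
    out <- dplyr::left_join(out, covariates, by = "site_id")
  }
  out
}

# invariants of the covariate table
check_site_covariates <- function(covariates) {
  if ("prop_run" %in% names(covariates)) {
    pr <- covariates$prop_run
    if (any(!is.na(pr) & (pr < 0 | pr > 1))) {
      stop_validation("prop_run must lie in [0, 1]")
    }
  }
  for (col in intersect(c("wetted_width", "mean_depth"), names(covariates))) {
    if (any(!is.na(covariates[[col]]) & covariates[[col]] <= 0)) {
      stop_validation(sprintf("%s must be > 0", col))
    }
  }
  invisible(covariates)
}

#' Simple linear regression of effort on one site covariate
#'
#' Ordinary least squares of an effort statistic (e.g. `h_75`) on a single
#' covariate with intercept. Returns a thin wrapper around the fitted
#' [stats::lm()] carrying the response/predictor names; use [tidy()] and
#' [glance()] for broom-style summaries. The two-sided p-value comes from
#' the t distribution on `n - 2` degrees of freedom, and the reported R^2 is
#' the adjusted one (which can legitimately be negative for null
#' predictors).
#'
#' @param summaries A per-site summary table (see [site_summaries()] or
#'   [table1_fixture()]).
#' @param response Name of the response column (e.g. `"h_75"`, `"h_100"`).
#' @param predictor Name of the predictor column (e.g. `"wetted_width"`,
#'   `"mean_depth"`, `"prop_run"`).
#' @return An object of class `"effort_lm"`.
#' @examples
#' fit <- effort_regression(table1_fixture(), "h_75", "wetted_width")
#' tidy(fit)
#' glance(fit)$adj.r.squared
#' @export
effort_regression <- function(summaries, response, predictor) {
  summaries <- tibble::as_tibble(summaries)
  for (col in c(response, predictor)) {
    if (!col %in% names(summaries)) {
      stop_schema(sprintf("column '%s' not found in summaries", col))
    }
  }
  dat <- summaries[stats::complete.cases(summaries[, c(response, predictor)]), ]
  if (nrow(dat) < 3) {
    stop_validation("need at least 3 complete sites for a regression")
  }
  if (length(unique(dat[[predictor]])) < 2) {
    stop_validation(sprintf("degenerate design: predictor '%s' is constant",
                            predictor))
  }
  fml <- stats::reformulate(predictor, response = response)
  fit <- stats::lm(fml, data = dat)
  structure(
    list(model = fit, response = response, predictor = predictor,
         n = nrow(dat)),
    class = "effort_lm"
  )
}

#' @export
print.effort_lm <- function(x, ...) {
  tt <- tidy(x)
  sl <- tt[tt$term == x$predictor, ]
  cat(sprintf("Effort regression: %s ~ %s (n = %d)\n", x$response,
              x$predictor, x$n))
  cat(sprintf("  slope %.4g (SE %.4g), adj R^2 %.3f, p = %.3g\n",
              sl$estimate, sl$std.error, glance(x)$adj.r.squared, sl$p.value))
  invisible(x)
}

#' @rdname effort_regression
#' @param x An `effort_lm` object.
#' @param ... Unused.
#' @method tidy effort_lm
#' @export
tidy.effort_lm <- function(x, ...) {
  cf <- summary(x$model)$coefficients
  tibble::tibble(
    term = rownames(cf),
    estimate = unname(cf[, "Estimate"]),
    std.error = unname(cf[, "Std. Error"]),
    statistic = unname(cf[, "t value"]),
    p.value = unname(cf[, "Pr(>|t|)"])
  )
}

#' @rdname effort_regression
#' @method glance effort_lm
#' @export
glance.effort_lm <- function(x, ...) {
  s <- summary(x$model)
  f <- s$fstatistic
  tibble::tibble(
    r.squared = s$r.squared,
    adj.r.squared = s$adj.r.squared,
    sigma = s$sigma,
    statistic = unname(f[1]),
    p.value = stats::pf(f[1], f[2], f[3], lower.tail = FALSE),
    df.residual = x$model$df.residual,
    nobs = x$n
  )
}

#' All effort-covariate regressions in one table
#'
#' Fits every response/predictor combination as separate univariate OLS
#' models (no multiple-testing correction; the models are deliberately
#' independent probes, not a joint model).
#'
#' @inheritParams effort_regression
#' @param responses Response columns (default `h_75` and `h_100`).
#' @param predictors Predictor columns (default the three site covariates).
#' @return A tibble with columns `response`, `predictor`, `slope`,
#'   `slope_se`, `adj_r2`, `p_value`.
#' @export
effort_regressions <- function(summaries,
                               responses = c("h_75", "h_100"),
                               predictors = c("wetted_width", "mean_depth",
                                              "prop_run")) {
  grid <- tidyr::expand_grid(response = responses, predictor = predictors)
  purrr::pmap_dfr(grid, function(response, predictor) {
    fit <- effort_regression(summaries, response, predictor)
    tt <- tidy(fit)
    sl <- tt[tt$term == predictor, ]
    tibble::tibble(
      response = response, predictor = predictor,
      slope = sl$estimate, slope_se = sl$std.error,
      adj_r2 = glance(fit)$adj.r.squared, p_value = sl$p.value
    )
  })
}
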