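#' Full effort-diversity study report
#'
#' Runs the whole pipeline on a haul table: per-site and regional
#' accumulation curves for richness, Chao1 and the Gini-Simpson index, the
#' beta-partition effort curve, the per-site summary table, all
#' effort-covariate regressions, and study-level summary statistics.
#' Alternatively, pass a ready-made `summaries` table (such as
#' [table1_fixture()]) with `x = NULL` to produce the regression table and
#' summary statistics alone, when raw haul data are not available.
#'
#' @param x A validated haul table, or `NULL` when only `summaries` is given.
#' @param covariates Per-site covariates (see [site_summaries()]).
#' @param summaries Optional pre-computed per-site summary table.
#' @param checkpoints,fractions Passed to [site_summaries()].
#' @param epsilons Named stability half-widths used for stabilization
#'   efforts: `richness` (species) and `simpson`/`beta` (index units).
#' @return A list of class `"effort_report"` with tibbles `site_summaries`,
#'   `regressions`, `alpha_curves`, `gamma_curves`, `beta_curve`,
#'   `stabilization`, `summary_stats`, plus the `config` used.
#' @seealso [write_report()] to serialise, [autoplot.effort_report()] to
#'   plot.
#' @export
study_report <- function(x, covariates = NULL, summaries = NULL,
                         checkpoints = c(5L, 10L, 20L, 40L),
                         fractions = c(0.75, 1),
                         epsilons = c(richness = 0.5, simpson = 0.02,
                                      beta = 0.02)) {
  if (is.null(x) && is.null(summaries)) {
    stop_schema("study_report needs a haul table or a summaries table")
  }
  config <- list(checkpoints = checkpoints, fractions = fractions,
                 epsilons = as.list(epsilons))

  alpha_curves <- gamma_curves <- beta_curve <- stab <- NULL
  if (!is.null(x)) {
    x <- validate_haul_table(x)
    summaries <- site_summaries(x, covariates, checkpoints, fractions)
    alpha_curves <- dplyr::bind_rows(
      accumulation_curve(x, "richness"),
      accumulation_curve(x, "chao"),
      accumulation_curve(x, "simpson")
    )
    gamma_curves <- dplyr::bind_rows(
      gamma_curve(x, "richness"),
      gamma_curve(x, "chao"),
      gamma_curve(x, "simpson")
    )
    beta_curve <- suppressWarnings(beta_effort_curve(x))
    eps_beta <- epsilons[["beta"]]
    stab <- dplyr::bind_rows(
      tibble::tibble(
        curve = "gamma_richness",
        k = stabilization_effort(
          gamma_curves$value[gamma_curves$statistic == "richness"],
          epsilons[["richness"]])
      ),
      tibble::tibble(
        curve = "gamma_simpson",
        k = stabilization_effort(
          gamma_curves$value[gamma_curves$statistic == "simpson"],
          epsilons[["simpson"]])
      ),
      tibble::tibble(curve = "d_tot",
                     k = stabilization_effort(beta_curve$d_tot, eps_beta)),
      tibble::tibble(curve = "d_bal",
                     k = stabilization_effort(beta_curve$d_bal, eps_beta)),
      tibble::tibble(curve = "d_gra",
                     k = stabilization_effort(beta_curve$d_gra, eps_beta))
    )
  } else {
    summaries <- tibble::as_tibble(summaries)
  }

  have_covars <- all(c("wetted_width", "mean_depth", "prop_run") %in%
                       names(summaries))
  regressions <- if (have_covars) effort_regressions(summaries) else NULL

  effort_cols <- grep("^h_", names(summaries), value = TRUE)
  rich_cols <- grep("^s_", names(summaries), value = TRUE)
  summary_stats <- purrr::map_dfr(c(rich_cols, effort_cols), function(col) {
    v <- summaries[[col]]
    tibble::tibble(statistic = col, mean = mean(v), min = min(v),
                   max = max(v))
  })

  structure(
    list(site_summaries = summaries, regressions = regressions,
         alpha_curves = alpha_curves, gamma_curves = gamma_curves,
         beta_curve = beta_curve, stabilization = stab,
         summary_stats = summary_stats, config = config),
    class = "effort_report"
  )
}

#' @export
print.effort_report <- function(x, ...) {
  cat(sprintf("Effort-diversity report: %d sites\n", nrow(x$site_summaries)))
  print(x$summary_stats)
  if (!is.null(x$regressions)) {
    cat("\nEffort-covariate regressions:\n")
    print(x$regressions)
  }
  invisible(x)
}

#' Write a study report to disk
#'
#' Serialises every table of an `"effort_report"` as CSV, the summary
#' statistics and configuration as JSON, and (optionally) the standard
#' figures as PNG.
#'
#' @param report An object from [study_report()].
#' @param outdir Output directory (created if absent).
#' @param plots Write PNG figures too? (default `TRUE`; needs curve data).
#' @return `outdir`, invisibly.
#' @export
write_report <- function(report, outdir, plots = TRUE) {
  if (!inherits(report, "effort_report")) {
    stop_schema("write_report expects an effort_report")
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("site_summaries", "regressions", "alpha_curves",
               "gamma_curves", "beta_curve", "stabilization",
               "summary_stats")) {
    if (!is.null(report[[nm]])) {
      readr::write_csv(report[[nm]], file.path(outdir, paste0(nm, ".csv")))
    }
  }
  jsonlite::write_json(
    list(summary_stats = report$summary_stats, config = report$config),
    file.path(outdir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  if (plots && !is.null(report$alpha_curves)) {
    ggplot2::ggsave(file.path(outdir, "alpha_curves.png"),
                    autoplot(report, which = "alpha"),
                    width = 9, height = 4, dpi = 150)
    if (!is.null(report$beta_curve)) {
      ggplot2::ggsave(file.path(outdir, "beta_curve.png"),
                      autoplot(report, which = "beta"),
                      width = 6, height = 4, dpi = 150)
    }
  }
  invisible(outdir)
}

#' Plot an effort-diversity report
#'
#' `which = "alpha"` draws per-site accumulation curves (thin grey) with the
#' regional curve on top (thick black), faceted by statistic, mirroring the
#' usual presentation of effort studies; `which = "beta"` draws the three
#' partition components against effort.
#'
#' @param object An `"effort_report"`.
#' @param which `"alpha"` or `"beta"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot effort_report
#' @export
autoplot.effort_report <- function(object, which = c("alpha", "beta"), ...) {
  which <- match.arg(which)
  if (which == "alpha") {
    if (is.null(object$alpha_curves)) {
      stop_schema("report holds no curve data (built from summaries only)")
    }
    ggplot2::ggplot(object$alpha_curves,
                    ggplot2::aes(x = .data$k, y = .data$value,
                                 group = .data$site_id)) +
      ggplot2::geom_line(colour = "grey60", linewidth = 0.3) +
      ggplot2::geom_line(data = object$gamma_curves,
                         ggplot2::aes(group = NULL),
                         colour = "black", linewidth = 1) +
      ggplot2::facet_wrap(~statistic, scales = "free_y") +
      ggplot2::labs(x = "Seine hauls per site", y = "Index value") +
      ggplot2::theme_minimal()
  } else {
    if (is.null(object$beta_curve)) {
      stop_schema("report holds no beta curve")
    }
    long <- tidyr::pivot_longer(object$beta_curve,
                                c("d_tot", "d_bal", "d_gra"),
                                names_to = "component", values_to = "value")
    ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$value,
                                       colour = .data$component)) +
      ggplot2::geom_line(linewidth = 0.8) +
      ggplot2::scale_colour_manual(
        values = c(d_tot = "black", d_bal = "#2166ac", d_gra = "#b2182b")
      ) +
      ggplot2::labs(x = "Seine hauls per site", y = "Dissimilarity",
                    colour = NULL) +
      ggplot2::ylim(0, 1) +
      ggplot2::theme_minimal()
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
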