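#' Parameters of the synthetic seine-survey community model
#'
#' Describes a regional fish community and a within-site seining protocol for
#' the generator in [generate_study()]. The model is deliberately simple:
#' a geometric-series species abundance distribution for a species-poor,
#' uneven assemblage; per-site log-normal scatter on each species' density
#' (which creates between-site abundance substitution, the driver of the
#' balanced-variation beta component); habitat multipliers per species; and
#' Poisson counts per haul with mean density x area x habitat multiplier.
#'
#' @param n_species Regional species-pool size (default 11).
#' @param sad_shape Geometric-series parameter `c` in (0, 1): regional
#'   relative abundances are proportional to `c * (1 - c)^(i - 1)`.
#' @param site_heterogeneity Standard deviation (log scale) of the per-site,
#'   per-species log-normal density multiplier; multipliers are mean-1.
#' @param site_scale_sd Standard deviation (log scale) of a whole-site
#'   density multiplier, creating poor and rich sites.
#' @param density Expected total fish per square metre at an average site in
#'   run habitat (summed over species). The per-haul abundance scale of the
#'   emulated survey is not published, so this is a calibration knob.
#' @param habitat_affinity Species-by-habitat multiplier matrix with columns
#'   `run`, `riffle`, `pool`, `backwater`; `NULL` builds a stylized default
#'   in which every third species is a riffle/pool/backwater affiliate.
#' @param n_sites,hauls_per_site Survey dimensions (defaults 20 and 40).
#' @param haul_area_range Range of per-haul swept area in square metres
#'   (default 12-30).
#' @param rare_habitat_fraction Fraction of the first half of the hauls made
#'   in non-run mesohabitats; the second half is run habitat only, mirroring
#'   a protocol that seines proportionally rare habitats first.
#' @param dispersion Negative-binomial size parameter; `Inf` (default) gives
#'   Poisson counts.
#' @return A validated list of class `"community_params"`.
#' @seealso [mrg_like_preset()] for the calibrated default.
#' @export
community_params <- function(n_species = 11L,
                             sad_shape = 0.45,
                             site_heterogeneity = 2.1,
                             site_scale_sd = 0.45,
                             density = 0.70,
                             habitat_affinity = NULL,
                             n_sites = 20L,
                             hauls_per_site = 40L,
                             haul_area_range = c(12, 30),
                             rare_habitat_fraction = 0.55,
                             dispersion = Inf) {
  p <- list(
    n_species = as.integer(n_species), sad_shape = sad_shape,
    site_heterogeneity = site_heterogeneity, site_scale_sd = site_scale_sd,
    density = density, habitat_affinity = habitat_affinity,
    n_sites = as.integer(n_sites), hauls_per_site = as.integer(hauls_per_site),
    haul_area_range = haul_area_range,
    rare_habitat_fraction = rare_habitat_fraction, dispersion = dispersion
  )
  if (p$n_species < 1 || p$n_sites < 1 || p$hauls_per_site < 1) {
    stop_validation("n_species, n_sites and hauls_per_site must be >= 1")
  }
  if (!(p$sad_shape > 0 && p$sad_shape < 1)) {
    stop_validation("sad_shape must lie in (0, 1)")
  }
  if (p$site_heterogeneity < 0 || p$site_scale_sd < 0) {
    stop_validation("heterogeneity standard deviations must be >= 0")
  }
  if (p$density <= 0) stop_validation("density must be > 0")
  if (length(p$haul_area_range) != 2 || any(p$haul_area_range <= 0) ||
      diff(p$haul_area_range) < 0) {
    stop_validation("haul_area_range must be a positive increasing pair")
  }
  if (p$rare_habitat_fraction < 0 || p$rare_habitat_fraction > 1) {
    stop_validation("rare_habitat_fraction must lie in [0, 1]")
  }
  if (is.null(p$habitat_affinity)) {
    p$habitat_affinity <- default_habitat_affinity(p$n_species)
  }
  ha <- p$habitat_affinity
  if (!is.matrix(ha) || nrow(ha) != p$n_species ||
      !all(c("run", "riffle", "pool", "backwater") %in% colnames(ha)) ||
      any(ha < 0)) {
    stop_validation(
      "habitat_affinity must be a non-negative n_species x habitat matrix with columns run, riffle, pool, backwater"
    )
  }
  structure(p, class = "community_params")
}

# stylized default: most species slightly prefer runs; every third species is
# a riffle affiliate, every fourth a pool affiliate, every fifth likes
# backwaters. Multipliers are modest so habitat structure flavours, but does
# not dominate, site composition.
default_habitat_affinity <- function(n_species) {
  i <- seq_len(n_species)
  m <- cbind(
    run = rep(1, n_species),
    riffle = ifelse(i %% 3 == 0, 2.0, 0.7),
    pool = ifelse(i %% 4 == 0, 2.0, 0.8),
    backwater = ifelse(i %% 5 == 0, 2.5, 0.6)
  )
  rownames(m) <- species_labels(n_species)
  m
}

species_labels <- function(n) sprintf("sp%02d", seq_len(n))

#' Calibrated parameter preset for a sand-bed river seine survey
#'
#' The frozen parameter set used throughout the package's tests and
#' examples. It emulates the scale of a depauperate sand-bed river survey:
#' 20 sites x 40 hauls, an 11-species regional pool, per-site full-effort
#' richness mostly between 3 and 9 species, regional richness recovered
#' within a few hauls per site, and an average of roughly 7-13 hauls to
#' reach 75% of full-effort richness. Calibration targets are ranges, not
#' point values, because only ranges are available for the emulated survey.
#'
#' @return A `"community_params"` object.
#' @export
mrg_like_preset <- function() {
  community_params(
    n_species = 11L,
    sad_shape = 0.45,
    site_heterogeneity = 2.1,
    site_scale_sd = 0.45,
    density = 0.70,
    n_sites = 20L,
    hauls_per_site = 40L,
    haul_area_range = c(12, 30),
    rare_habitat_fraction = 0.55
  )
}

#' Generate a synthetic seine survey
#'
#' Draws one realisation of the community model: per-site species densities
#' (regional geometric SAD x site-scale multiplier x per-species log-normal
#' site effect), a habitat sequence with non-run habitats concentrated in
#' the first half of the hauls and the second half all run, per-haul swept
#' areas uniform in the configured range, and Poisson (or negative-binomial)
#' counts per haul and species. Empty hauls are recorded with a sentinel row
#' so effort indexing stays contiguous.
#'
#' @param params A [community_params()] object.
#' @param seed Integer seed; the same `params` + `seed` reproduce the output
#'   exactly. The caller's RNG state is left untouched.
#' @return A list of class `"seine_simulation"` with elements
#'   \describe{
#'     \item{hauls}{a validated haul table}
#'     \item{covariates}{per-site `wetted_width` (m), `mean_depth` (m) and
#'       `prop_run` (consistent with the habitat assignment)}
#'     \item{truth}{generator ground truth: regional SAD, the site-by-species
#'       density matrix (fish per m^2 in run habitat), the habitat affinity
#'       matrix, expected per-haul counts by habitat at the mean haul area,
#'       and the regional richness}
#'   }
#' @examples
#' sim <- generate_study(mrg_like_preset(), seed = 42)
#' dplyr::n_distinct(sim$hauls$site_id)
#' @export
generate_study <- function(params = mrg_like_preset(), seed = 1L) {
  if (!inherits(params, "community_params")) {
    params <- do.call(community_params, params)
  }
  local_rng(seed)
  sp <- species_labels(params$n_species)
  sites <- sprintf("site%02d", seq_len(params$n_sites))
  kk <- params$hauls_per_site

  # regional SAD (geometric series, normalised)
  c0 <- params$sad_shape
  sad <- c0 * (1 - c0)^(seq_len(params$n_species) - 1)
  sad <- sad / sum(sad)

  # per-site densities: density * SAD * site scale * mean-1 lognormal effect
  sdl <- params$site_heterogeneity
  site_scale <- exp(stats::rnorm(params$n_sites, -params$site_scale_sd^2 / 2,
                                 params$site_scale_sd))
  effects <- matrix(
    exp(stats::rnorm(params$n_sites * params$n_species, -sdl^2 / 2, sdl)),
    nrow = params$n_sites
  )
  dens <- params$density * site_scale * sweep(effects, 2, sad, "*")
  dimnames(dens) <- list(sites, sp)

  # habitat sequence per site: non-run habitats only in the first half.
  # The realised rare-habitat share varies between sites (beta-binomial
  # around rare_habitat_fraction), as mesohabitat availability does in a
  # braided channel, so prop_run is a genuine between-site covariate.
  first_half <- seq_len(floor(kk / 2))
  conc <- 6
  frac_site <- stats::rbeta(params$n_sites,
                            params$rare_habitat_fraction * conc,
                            (1 - params$rare_habitat_fraction) * conc)
  n_rare_site <- stats::rbinom(params$n_sites, length(first_half), frac_site)
  rare_pool <- c("riffle", "pool", "backwater")

  # covariates: width/depth from log-normal site models
  width <- round(pmax(3, stats::rlnorm(params$n_sites, log(28), 0.65)))
  depth_site <- round(pmin(0.6, pmax(
    0.12, stats::rlnorm(params$n_sites, log(0.24), 0.35))), 2)

  rows <- vector("list", params$n_sites)
  prop_run <- numeric(params$n_sites)
  mean_depth <- numeric(params$n_sites)
  for (s in seq_len(params$n_sites)) {
    habitat <- rep("run", kk)
    n_rare <- n_rare_site[s]
    if (n_rare > 0) {
      rare_at <- sample(first_half, n_rare)
      habitat[rare_at] <- sample(rare_pool, n_rare, replace = TRUE,
                                 prob = c(0.5, 0.3, 0.2))
    }
    area <- stats::runif(kk, params$haul_area_range[1],
                         params$haul_area_range[2])
    length_m <- round(area / 2.5, 1)  # 2.5 m effective seine spread
    depth <- round(pmax(0.05, depth_site[s] *
                          exp(stats::rnorm(kk, 0, 0.25))), 2)
    mult <- params$habitat_affinity[, habitat, drop = FALSE]  # sp x hauls
    lambda <- sweep(t(mult), 2, dens[s, ], "*") * area  # hauls x sp
    counts <- if (is.finite(params$dispersion)) {
      matrix(stats::rnbinom(kk * params$n_species, mu = lambda,
                            size = params$dispersion), nrow = kk)
    } else {
      matrix(stats::rpois(kk * params$n_species, lambda), nrow = kk)
    }
    colnames(counts) <- sp
    long <- tibble::tibble(
      site_id = sites[s],
      haul_number = rep(seq_len(kk), times = params$n_species),
      habitat = rep(habitat, times = params$n_species),
      haul_length = rep(length_m, times = params$n_species),
      haul_depth = rep(depth, times = params$n_species),
      species = rep(sp, each = kk),
      count = as.integer(counts)
    )
    caught <- long[long$count > 0, , drop = FALSE]
    empty_hauls <- setdiff(seq_len(kk), unique(caught$haul_number))
    if (length(empty_hauls) > 0) {
      caught <- dplyr::bind_rows(caught, tibble::tibble(
        site_id = sites[s], haul_number = empty_hauls,
        habitat = habitat[empty_hauls], haul_length = length_m[empty_hauls],
        haul_depth = depth[empty_hauls], species = NA_character_, count = 0L
      ))
    }
    rows[[s]] <- dplyr::arrange(caught, .data$haul_number, .data$species)
    prop_run[s] <- mean(habitat == "run")
    mean_depth[s] <- round(mean(depth), 2)
  }

  hauls <- validate_haul_table(dplyr::bind_rows(rows))
  covariates <- tibble::tibble(
    site_id = sites, wetted_width = width, mean_depth = mean_depth,
    prop_run = prop_run
  )
  mean_area <- mean(params$haul_area_range)
  expected_per_haul <- lapply(
    stats::setNames(colnames(params$habitat_affinity),
                    colnames(params$habitat_affinity)),
    function(h) sweep(dens, 2, params$habitat_affinity[, h], "*") * mean_area
  )
  truth <- list(
    regional_richness = params$n_species,
    regional_sad = stats::setNames(sad, sp),
    site_density = dens,
    habitat_affinity = params$habitat_affinity,
    expected_per_haul = expected_per_haul,
    params = params,
    seed = as.integer(seed)
  )
  structure(list(hauls = hauls, covariates = covariates, truth = truth),
            class = "seine_simulation")
}

#' @export
print.seine_simulation <- function(x, ...) {
  cat(sprintf(
    "Synthetic seine survey: %d sites x %d hauls, %d-species pool (seed %d)\n",
    x$truth$params$n_sites, x$truth$params$hauls_per_site,
    x$truth$params$n_species, x$truth$seed
  ))
  invisible(x)
}

#' Fixed degenerate haul tables for edge-case testing
#'
#' Tiny deterministic fixtures used across the package's tests:
#' a single-species site, a pair of identical sites, a pair with disjoint
#' species, a nested-abundance pair (one site a scaled-down copy of the
#' other), and a site containing empty hauls (sentinel rows).
#'
#' @return A named list of haul tables.
#' @export
degenerate_cases <- function() {
  haul <- function(site, k, species, count, habitat = "run") {
    tibble::tibble(site_id = site, haul_number = as.integer(k),
                   habitat = habitat, species = species,
                   count = as.integer(count))
  }
  list(
    single_species = dplyr::bind_rows(
      haul("solo", 1, "a", 2), haul("solo", 2, "a", 1), haul("solo", 3, "a", 4)
    ),
    identical_pair = dplyr::bind_rows(
      haul("i1", 1, "a", 3), haul("i1", 1, "b", 2), haul("i1", 2, "a", 1),
      haul("i2", 1, "a", 3), haul("i2", 1, "b", 2), haul("i2", 2, "a", 1)
    ),
    disjoint_pair = dplyr::bind_rows(
      haul("d1", 1, "a", 2), haul("d1", 2, "a", 1),
      haul("d2", 1, "b", 5), haul("d2", 2, "b", 2)
    ),
    nested_pair = dplyr::bind_rows(
      haul("n1", 1, "a", 2), haul("n1", 1, "b", 2),
      haul("n2", 1, "a", 1), haul("n2", 1, "b", 1)
    ),
    with_empty_hauls = dplyr::bind_rows(
      haul("e1", 1, "a", 1),
      haul("e1", 2, NA_character_, 0),
      haul("e1", 3, "b", 2),
      haul("e1", 4, NA_character_, 0)
    )
  )
}

#' Site summaries with a known covariate-effort link
#'
#' Power-check utility: draws site covariates from the generator's covariate
#' model and constructs a response with a known linear link,
#' `response = intercept + slope * predictor + Normal(0, sigma)`. Because
#' effort thresholds are emergent statistics of the haul-level generator, a
#' known true slope can only be injected at the summary level; this is the
#' generator's "linked covariate" mode used to verify regression coverage.
#'
#' @param n_sites Number of sites.
#' @param predictor One of `"wetted_width"`, `"mean_depth"`, `"prop_run"`.
#' @param slope,intercept True linear coefficients.
#' @param sigma Residual standard deviation.
#' @param seed Integer seed.
#' @return A tibble with `site_id`, the predictor column, and a `response`
#'   column, ready for [effort_regression()].
#' @export
linked_site_summaries <- function(n_sites = 20L,
                                  predictor = c("wetted_width", "mean_depth",
                                                "prop_run"),
                                  slope = 0.1, intercept = 10, sigma = 5,
                                  seed = 1L) {
  predictor <- match.arg(predictor)
  local_rng(seed)
  xvals <- switch(
    predictor,
    wetted_width = round(pmax(3, stats::rlnorm(n_sites, log(28), 0.65))),
    mean_depth = round(pmin(0.6, pmax(0.12, stats::rlnorm(n_sites, log(0.24),
                                                          0.35))), 2),
    prop_run = round(stats::runif(n_sites, 0.4, 1), 2)
  )
  out <- tibble::tibble(
    site_id = sprintf("site%02d", seq_len(n_sites)),
    response = intercept + slope * xvals + stats::rnorm(n_sites, 0, sigma)
  )
  out[[predictor]] <- xvals
  out
}
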