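#' Observed species richness
#'
#' Number of species with a positive count.
#'
#' @param x Named numeric vector of species counts (or a data frame with
#'   `species` and `count` columns).
#' @return Integer richness; 0 for an empty vector.
#' @export
observed_richness <- function(x) {
  x <- check_abundance(x)
  sum(x > 0L)
}

#' Bias-corrected Chao1 richness estimate
#'
#' The abundance-based, bias-corrected Chao1 estimator
#' \deqn{\hat S = S_{obs} + \frac{f_1 (f_1 - 1)}{2 (f_2 + 1)}}
#' where \eqn{f_1} and \eqn{f_2} are the numbers of singleton and doubleton
#' species. The `f2 + 1` denominator keeps the estimator defined when no
#' doubletons are present; when \eqn{f_1 \le 1} the correction vanishes and
#' the estimate equals observed richness. Fractional estimates are never
#' rounded.
#'
#' @inheritParams observed_richness
#' @param detail If `TRUE`, return a one-row tibble with `s_obs`, `s_chao`,
#'   `f1`, `f2` instead of a bare number.
#' @return A double (`s_chao >= s_obs` always), or a tibble when
#'   `detail = TRUE`.
#' @examples
#' chao1_bc(c(a = 1, b = 1, c = 2, d = 5))  # 4 + 2*1/(2*2) = 4.5
#' chao1_bc(c(a = 5, b = 3))                # no singletons: equals S_obs
#' @export
chao1_bc <- function(x, detail = FALSE) {
  x <- check_abundance(x)
  s_obs <- sum(x > 0L)
  f1 <- sum(x == 1L)
  f2 <- sum(x == 2L)
  s_chao <- s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  if (detail) {
    return(tibble::tibble(s_obs = s_obs, s_chao = s_chao, f1 = f1, f2 = f2))
  }
  s_chao
}

#' Gini-Simpson diversity index
#'
#' Returns \eqn{1 - \sum_i p_i^2} with plug-in proportions \eqn{p_i = n_i/N}:
#' the probability that two individuals drawn at random (with replacement)
#' belong to different species. Values near 1 indicate diverse, even
#' assemblages; a monoculture scores 0. The small-sample unbiased variant
#' \eqn{1 - \sum n_i (n_i - 1) / (N (N - 1))} is available via `variant`.
#'
#' @inheritParams observed_richness
#' @param variant `"gini-simpson"` (plug-in, default) or `"unbiased"`.
#' @return A double in `[0, 1 - 1/S]` for the plug-in form.
#' @examples
#' simpson_index(c(a = 1, b = 1))            # 0.5
#' simpson_index(c(a = 1, b = 1, c = 1, d = 1))  # 0.75
#' @export
simpson_index <- function(x, variant = c("gini-simpson", "unbiased")) {
  variant <- match.arg(variant)
  x <- check_abundance(x)
  x <- x[x > 0]
  n <- sum(x)
  if (n < 1) {
    stop_validation("simpson_index is undefined for an empty assemblage (N = 0)")
  }
  if (variant == "gini-simpson") {
    1 - sum((x / n)^2)
  } else {
    if (n < 2) {
      stop_validation("unbiased Simpson variant needs N >= 2")
    }
    1 - sum(x * (x - 1)) / (n * (n - 1))
  }
}

# --- vectorised statistics on a cumulative species-by-haul count matrix -----
# `cum` is species x k with column j holding counts pooled over hauls 1..j.
stat_from_cumulative <- function(cum, statistic) {
  if (!is.matrix(cum)) cum <- matrix(cum, nrow = length(cum))
  totals <- colSums(cum)
  switch(
    statistic,
    richness = as.numeric(colSums(cum > 0)),
    chao = {
      s <- colSums(cum > 0)
      f1 <- colSums(cum == 1)
      f2 <- colSums(cum == 2)
      as.numeric(s + f1 * (f1 - 1) / (2 * (f2 + 1)))
    },
    simpson = {
      p2 <- colSums(sweep(cum, 2, pmax(totals, 1), "/")^2)
      ifelse(totals >= 1, 1 - p2, NA_real_)
    },
    abort(sprintf("unknown statistic '%s'", statistic),
          class = "effortdiv_error")
  )
}

# species x K cumulative count matrix for one site's rows (validated input)
site_cumulative_matrix <- function(rows, kmax = NULL) {
  kmax <- kmax %||% max(rows$haul_number)
  rows <- rows[!is.na(rows$species) & rows$count > 0 &
                 rows$haul_number <= kmax, , drop = FALSE]
  species <- sort(unique(rows$species))
  m <- matrix(0L, nrow = length(species), ncol = kmax,
              dimnames = list(species, NULL))
  if (nrow(rows) > 0) {
    idx <- cbind(match(rows$species, species), rows$haul_number)
    # accumulate duplicates (same species in same haul cannot occur post
    # validation, but be safe)
    for (r in seq_len(nrow(rows))) {
      m[idx[r, 1], idx[r, 2]] <- m[idx[r, 1], idx[r, 2]] + rows$count[r]
    }
  }
  if (ncol(m) > 1 && nrow(m) > 0) {
    for (j in 2:ncol(m)) m[, j] <- m[, j] + m[, j - 1]
  }
  m
}

#' Collector-order accumulation curves of site-level diversity
#'
#' Evaluates a diversity statistic on counts pooled over hauls `1..k` for
#' `k = 1..K` at each site, with hauls taken strictly in recorded collector
#' order (never permuted). Collector order is retained deliberately: in the
#' survey design this package supports, rare habitats are seined first and
#' later hauls are mostly mid-channel runs, so the realised order is itself
#' part of the protocol under study. For randomized-order expectations see
#' [permutation_curve()].
#'
#' @param x A validated haul table.
#' @param statistic One of `"richness"`, `"chao"`, `"simpson"`.
#' @param sites Optional character vector restricting which sites to include
#'   (default: all sites in `x`).
#' @return A tibble with columns `site_id`, `k`, `statistic`, `value`. The
#'   Simpson value is `NA` at efforts where no fish have yet been caught.
#' @examples
#' tbl <- tibble::tibble(
#'   site_id = "s1", haul_number = c(1L, 2L, 3L),
#'   species = c("a", "a", "b"), count = 1L
#' )
#' accumulation_curve(tbl, "richness")$value  # 1, 1, 2
#' @export
accumulation_curve <- function(x, statistic = c("richness", "chao", "simpson"),
                               sites = NULL) {
  statistic <- match.arg(statistic)
  x <- validate_haul_table(x)
  if (!is.null(sites)) {
    missing_sites <- setdiff(sites, unique(x$site_id))
    if (length(missing_sites) > 0) {
      stop_validation(sprintf("site(s) not in table: %s",
                              paste(missing_sites, collapse = ", ")))
    }
    x <- x[x$site_id %in% sites, , drop = FALSE]
  }
  purrr::map_dfr(split(x, x$site_id), function(rows) {
    cum <- site_cumulative_matrix(rows)
    vals <- stat_from_cumulative(cum, statistic)
    tibble::tibble(
      site_id = rows$site_id[1],
      k = seq_len(ncol(cum)),
      statistic = statistic,
      value = vals
    )
  })
}

#' Regional (gamma) diversity accumulation curve
#'
#' Pools counts over hauls `1..k` across all sites and evaluates the
#' statistic on the regional pool, for each per-site effort level `k`. With a
#' ragged design (sites with unequal haul counts) the curve stops at the
#' minimum `K` across sites, with a warning.
#'
#' @inheritParams accumulation_curve
#' @return A tibble with columns `k`, `statistic`, `value`.
#' @export
gamma_curve <- function(x, statistic = c("richness", "chao", "simpson")) {
  statistic <- match.arg(statistic)
  x <- validate_haul_table(x)
  ks <- tapply(x$haul_number, x$site_id, max)
  kmax <- min(ks)
  if (length(unique(ks)) > 1) {
    warn(sprintf(
      "ragged design: sites have %d-%d hauls; gamma curve evaluated to k = %d",
      min(ks), max(ks), kmax
    ))
  }
  mats <- lapply(split(x, x$site_id), site_cumulative_matrix, kmax = kmax)
  species <- sort(unique(unlist(lapply(mats, rownames))))
  pooled <- matrix(0, nrow = length(species), ncol = kmax,
                   dimnames = list(species, NULL))
  for (m in mats) {
    if (nrow(m) > 0) pooled[rownames(m), ] <- pooled[rownames(m), ] + m
  }
  vals <- stat_from_cumulative(pooled, statistic)
  tibble::tibble(
    k = seq_len(kmax),
    statistic = statistic,
    value = vals
  )
}

#' Expected accumulation curve under random haul order
#'
#' Averages per-site accumulation curves over random permutations of haul
#' order. This is a comparison utility only; the main pipeline always uses
#' collector order.
#'
#' @inheritParams accumulation_curve
#' @param n_perm Number of random permutations (default 100).
#' @param seed Integer seed; results are reproducible for a fixed seed.
#' @return A tibble with columns `site_id`, `k`, `statistic`, `value` where
#'   `value` is the mean over permutations.
#' @export
permutation_curve <- function(x, statistic = c("richness", "chao", "simpson"),
                              n_perm = 100, seed = 1L) {
  statistic <- match.arg(statistic)
  x <- validate_haul_table(x)
  local_rng(seed)
  purrr::map_dfr(split(x, x$site_id), function(rows) {
    kmax <- max(rows$haul_number)
    acc <- matrix(0, nrow = n_perm, ncol = kmax)
    for (b in seq_len(n_perm)) {
      perm <- sample.int(kmax)
      shuffled <- rows
      shuffled$haul_number <- match(rows$haul_number, perm)
      cum <- site_cumulative_matrix(shuffled)
      acc[b, ] <- stat_from_cumulative(cum, statistic)
    }
    tibble::tibble(
      site_id = rows$site_id[1],
      k = seq_len(kmax),
      statistic = statistic,
      value = colMeans(acc)
    )
  })
}
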