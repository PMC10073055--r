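#' Bray-Curtis components of a site pair
#'
#' For two abundance vectors over the union of their species, returns
#' \eqn{A = \sum_s \min(x_s, y_s)} (shared abundance) and the site-specific
#' residuals \eqn{B = \sum_s (x_s - \min)} and \eqn{C = \sum_s (y_s - \min)}.
#' These are the building blocks of the abundance-based Bray-Curtis
#' dissimilarity and its balanced-variation / abundance-gradient partition.
#'
#' @param x,y Named numeric vectors of species counts.
#' @return One-row tibble with columns `A`, `B`, `C`. `A + B` is the total
#'   abundance of `x`; `A + C` that of `y`.
#' @examples
#' pair_components(c(a = 2, b = 2), c(a = 1, b = 1))  # A = 2, B = 2, C = 0
#' @export
pair_components <- function(x, y) {
  x <- check_abundance(x)
  y <- check_abundance(y)
  species <- union(names(x), names(y))
  xs <- stats::setNames(rep(0, length(species)), species)
  ys <- xs
  xs[names(x)] <- x
  ys[names(y)] <- y
  a <- sum(pmin(xs, ys))
  tibble::tibble(A = a, B = sum(xs) - a, C = sum(ys) - a)
}

partition_from_sums <- function(sum_a, sum_min, sum_max) {
  d_bal <- sum_min / (sum_a + sum_min)
  d_tot <- (sum_min + sum_max) / (2 * sum_a + sum_min + sum_max)
  tibble::tibble(d_tot = d_tot, d_bal = d_bal, d_gra = d_tot - d_bal)
}

#' Pairwise abundance-based Bray-Curtis partition
#'
#' Partitions the Bray-Curtis dissimilarity between two sites into a
#' balanced-variation component (individuals of one species substituted by
#' equal numbers of another between sites; the abundance analogue of
#' turnover) and an abundance-gradient component (individuals lost from one
#' site to the other without substitution; the analogue of nestedness):
#' \deqn{d_{tot} = \frac{B + C}{2A + B + C}, \quad
#'       d_{bal} = \frac{\min(B, C)}{A + \min(B, C)}, \quad
#'       d_{gra} = d_{tot} - d_{bal}.}
#'
#' @inheritParams pair_components
#' @return One-row tibble with columns `d_tot`, `d_bal`, `d_gra`, all in
#'   `[0, 1]` with `d_tot = d_bal + d_gra`.
#' @examples
#' bray_pair(c(a = 2), c(b = 5))            # disjoint: pure substitution
#' bray_pair(c(a = 2, b = 2), c(a = 1, b = 1))  # nested: pure gradient
#' @export
bray_pair <- function(x, y) {
  comp <- pair_components(x, y)
  if (comp$A + comp$B + comp$C == 0) {
    stop_validation("Bray-Curtis partition is undefined when both sites are empty")
  }
  partition_from_sums(comp$A, min(comp$B, comp$C), max(comp$B, comp$C))
}

# accept a sites-by-species matrix, a list of named abundance vectors, or a
# long data frame (site_id, species, count); return sites-by-species matrix
as_site_matrix <- function(x) {
  if (is.matrix(x)) {
    if (is.null(rownames(x))) rownames(x) <- paste0("site", seq_len(nrow(x)))
    return(x)
  }
  if (is.data.frame(x)) {
    need <- c("site_id", "species", "count")
    if (!all(need %in% names(x))) {
      stop_schema("long-format input needs columns site_id, species, count")
    }
    x <- x[!is.na(x$species), , drop = FALSE]
    wide <- tidyr::pivot_wider(
      dplyr::summarise(dplyr::group_by(x, .data$site_id, .data$species),
                       count = sum(.data$count), .groups = "drop"),
      names_from = "species", values_from = "count", values_fill = 0
    )
    m <- as.matrix(wide[, setdiff(names(wide), "site_id"), drop = FALSE])
    rownames(m) <- wide$site_id
    return(m)
  }
  if (is.list(x)) {
    x <- lapply(x, check_abundance)
    species <- sort(unique(unlist(lapply(x, names))))
    m <- matrix(0, nrow = length(x), ncol = length(species),
                dimnames = list(names(x) %||% paste0("site", seq_along(x)),
                                species))
    for (i in seq_along(x)) m[i, names(x[[i]])] <- x[[i]]
    return(m)
  }
  stop_schema("cannot interpret input as a site-by-species abundance table")
}

#' Multiple-site abundance-based Bray-Curtis partition
#'
#' The multiple-site extension of the pairwise partition. With pairwise
#' components \eqn{A_{ij}, B_{ij}, C_{ij}} summed over all site pairs
#' \eqn{i < j},
#' \deqn{d_{bal} = \frac{\sum \min(B_{ij}, C_{ij})}
#'                      {\sum A_{ij} + \sum \min(B_{ij}, C_{ij})}}
#' \deqn{d_{tot} = \frac{\sum \min(B_{ij}, C_{ij}) + \sum \max(B_{ij}, C_{ij})}
#'                      {2 \sum A_{ij} + \sum \min(B_{ij}, C_{ij}) +
#'                       \sum \max(B_{ij}, C_{ij})}}
#' and \eqn{d_{gra} = d_{tot} - d_{bal}}. For two sites this reduces exactly
#' to [bray_pair()]; the components are invariant to site order and to
#' multiplying every count by a common positive factor.
#'
#' Sites with zero total abundance are excluded (with a warning): an empty
#' site carries no abundance information and would otherwise contribute 0/0
#' pairs.
#'
#' @param x A sites-by-species count matrix (sites in rows), a list of named
#'   abundance vectors, or a long data frame with columns `site_id`,
#'   `species`, `count`.
#' @return One-row tibble with columns `n_sites`, `d_tot`, `d_bal`, `d_gra`.
#' @examples
#' m <- rbind(s1 = c(a = 3, b = 0), s2 = c(a = 1, b = 2))
#' bray_multi(m)
#' @export
bray_multi <- function(x) {
  m <- as_site_matrix(x)
  empty <- rowSums(m) == 0
  if (any(empty)) {
    warn(sprintf("excluding %d empty site(s) from the multiple-site partition: %s",
                 sum(empty), paste(rownames(m)[empty], collapse = ", ")))
    m <- m[!empty, , drop = FALSE]
  }
  n <- nrow(m)
  if (n < 2) {
    stop_validation("multiple-site partition needs at least 2 non-empty sites")
  }
  sum_a <- sum_min <- sum_max <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      a <- sum(pmin(m[i, ], m[j, ]))
      b <- sum(m[i, ]) - a
      cc <- sum(m[j, ]) - a
      sum_a <- sum_a + a
      sum_min <- sum_min + min(b, cc)
      sum_max <- sum_max + max(b, cc)
    }
  }
  out <- partition_from_sums(sum_a, sum_min, sum_max)
  tibble::tibble(n_sites = n, out)
}

#' Beta-diversity as a function of within-site effort
#'
#' Evaluates the multiple-site Bray-Curtis partition across all sites with
#' each site pooled to its first `k` hauls, for `k = 1..k_max`. This is the
#' curve that shows how apparent between-site dissimilarity (and its
#' substitution/gradient make-up) depends on within-site sampling intensity.
#'
#' @param x A validated haul table.
#' @param k_max Largest effort level to evaluate (default: the minimum number
#'   of hauls across sites; a larger request is truncated with a warning).
#' @return A tibble with columns `k`, `n_sites` (non-empty sites entering the
#'   partition at that effort), `d_tot`, `d_bal`, `d_gra`.
#' @export
beta_effort_curve <- function(x, k_max = NULL) {
  x <- validate_haul_table(x)
  ks <- tapply(x$haul_number, x$site_id, max)
  limit <- min(ks)
  if (is.null(k_max)) {
    k_max <- limit
    if (length(unique(ks)) > 1) {
      warn(sprintf("ragged design: beta curve evaluated to k = %d", limit))
    }
  } else if (k_max > limit) {
    warn(sprintf("k_max = %d exceeds the shallowest site; truncated to %d",
                 k_max, limit))
    k_max <- limit
  }
  mats <- lapply(split(x, x$site_id), site_cumulative_matrix, kmax = k_max)
  species <- sort(unique(unlist(lapply(mats, rownames))))
  purrr::map_dfr(seq_len(k_max), function(k) {
    m <- matrix(0, nrow = length(mats), ncol = length(species),
                dimnames = list(names(mats), species))
    for (i in seq_along(mats)) {
      mi <- mats[[i]]
      if (nrow(mi) > 0) m[i, rownames(mi)] <- mi[, k]
    }
    n_empty <- sum(rowSums(m) == 0)
    part <- withCallingHandlers(
      bray_multi(m),
      warning = function(w) invokeRestart("muffleWarning")
    )
    if (n_empty > 0) {
      warn(sprintf("k = %d: %d empty site(s) excluded from the partition",
                   k, n_empty))
    }
    tibble::tibble(k = k, part)
  })
}
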