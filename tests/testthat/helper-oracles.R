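# Independent oracles, written against the definitions rather than the
# package implementation. Each deliberately uses a different computational
# route (explicit loops, set algebra) so agreement is informative.

# Chao1-bc by direct evaluation of the closed form from a raw species map
oracle_chao1 <- function(counts) {
  counts <- counts[counts > 0]
  s_obs <- length(counts)
  f1 <- 0; f2 <- 0
  for (v in counts) {
    if (v == 1) f1 <- f1 + 1
    if (v == 2) f2 <- f2 + 1
  }
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

# pairwise Bray-Curtis partition straight from the component definitions
oracle_bray_pair <- function(x, y) {
  sp <- union(names(x), names(y))
  xv <- sapply(sp, function(s) if (s %in% names(x)) x[[s]] else 0)
  yv <- sapply(sp, function(s) if (s %in% names(y)) y[[s]] else 0)
  a <- sum(mapply(min, xv, yv))
  b <- sum(xv) - a
  cc <- sum(yv) - a
  d_tot <- (b + cc) / (2 * a + b + cc)
  d_bal <- min(b, cc) / (a + min(b, cc))
  c(d_tot = d_tot, d_bal = d_bal, d_gra = d_tot - d_bal)
}

# multiple-site partition by exhaustive pair enumeration over a list of
# named abundance vectors
oracle_bray_multi <- function(vlist) {
  n <- length(vlist)
  sum_a <- 0; sum_min <- 0; sum_max <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sp <- union(names(vlist[[i]]), names(vlist[[j]]))
      xv <- sapply(sp, function(s) if (s %in% names(vlist[[i]])) vlist[[i]][[s]] else 0)
      yv <- sapply(sp, function(s) if (s %in% names(vlist[[j]])) vlist[[j]][[s]] else 0)
      a <- sum(mapply(min, xv, yv))
      sum_a <- sum_a + a
      sum_min <- sum_min + min(sum(xv) - a, sum(yv) - a)
      sum_max <- sum_max + max(sum(xv) - a, sum(yv) - a)
    }
  }
  d_bal <- sum_min / (sum_a + sum_min)
  d_tot <- (sum_min + sum_max) / (2 * sum_a + sum_min + sum_max)
  c(d_tot = d_tot, d_bal = d_bal, d_gra = d_tot - d_bal)
}

# set-based effort threshold: first haul k at which the cumulative species
# SET equals the full-effort set
oracle_h100_setwise <- function(tbl, site) {
  rows <- tbl[tbl$site_id == site & !is.na(tbl$species) & tbl$count > 0, ]
  kk <- max(tbl$haul_number[tbl$site_id == site])
  full <- unique(rows$species)
  for (k in seq_len(kk)) {
    seen <- unique(rows$species[rows$haul_number <= k])
    if (setequal(seen, full)) return(k)
  }
  kk
}

# random small haul table for property tests
random_haul_table <- function(n_sites = 3, n_hauls = 5, n_species = 4) {
  species <- letters[seq_len(n_species)]
  rows <- expand.grid(site_id = paste0("s", seq_len(n_sites)),
                      haul_number = seq_len(n_hauls),
                      species = species, stringsAsFactors = FALSE)
  rows$count <- stats::rpois(nrow(rows), 1.2)
  rows <- rows[rows$count > 0, ]
  # ensure contiguity: add sentinels for hauls that ended up empty
  out <- list(tibble::as_tibble(rows))
  for (s in paste0("s", seq_len(n_sites))) {
    present <- unique(rows$haul_number[rows$site_id == s])
    missing <- setdiff(seq_len(n_hauls), present)
    if (length(missing) > 0) {
      out[[length(out) + 1]] <- tibble::tibble(
        site_id = s, haul_number = missing, species = NA_character_,
        count = 0L
      )
    }
  }
  dplyr::bind_rows(out)
}
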