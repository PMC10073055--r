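test_that("pair components match hand sums", {
  expect_equal(as.numeric(pair_components(c(a = 3), c(a = 3))), c(3, 0, 0))
  expect_equal(as.numeric(pair_components(c(a = 2), c(b = 5))), c(0, 2, 5))
  expect_equal(as.numeric(pair_components(c(a = 2, b = 2), c(a = 1, b = 1))),
               c(2, 2, 0))
  # A + B and A + C recover the site totals
  comp <- pair_components(c(a = 4, b = 1), c(a = 2, c = 6))
  expect_equal(comp$A + comp$B, 5)
  expect_equal(comp$A + comp$C, 8)
})

test_that("pairwise partition reproduces the canonical special cases", {
  ident <- bray_pair(c(a = 3, b = 2), c(a = 3, b = 2))
  expect_equal(as.numeric(ident), c(0, 0, 0))

  disj <- bray_pair(c(a = 2), c(b = 5))
  expect_equal(disj$d_tot, 1)
  expect_equal(disj$d_bal, 1)
  expect_equal(disj$d_gra, 0)

  nested <- bray_pair(c(a = 2, b = 2), c(a = 1, b = 1))
  expect_equal(nested$d_tot, 2 / 6)
  expect_equal(nested$d_bal, 0)
  expect_equal(nested$d_gra, 2 / 6)

  expect_error(bray_pair(c(a = 0), c(b = 0)),
               class = "effortdiv_validation_error")
})

test_that("multisite partition reduces exactly to the pairwise formulas at n = 2", {
  withr::local_seed(41)
  for (rep in 1:25) {
    x <- stats::setNames(stats::rpois(5, 2), letters[1:5])
    y <- stats::setNames(stats::rpois(5, 2), letters[1:5])
    if (sum(x) == 0 || sum(y) == 0) next
    pairwise <- bray_pair(x, y)
    multi <- bray_multi(list(s1 = x, s2 = y))
    expect_identical(pairwise$d_tot, multi$d_tot)
    expect_identical(pairwise$d_bal, multi$d_bal)
    expect_identical(pairwise$d_gra, multi$d_gra)
  }
})

test_that("multisite partition equals the brute-force oracle for small cases", {
  # fixed 3-site toy
  toy <- list(s1 = c(a = 3), s2 = c(a = 1, b = 2), s3 = c(b = 1))
  got <- bray_multi(toy)
  exp <- oracle_bray_multi(toy)
  expect_equal(got$d_tot, unname(exp["d_tot"]))
  expect_equal(got$d_bal, unname(exp["d_bal"]))
  expect_equal(got$d_gra, unname(exp["d_gra"]))

  withr::local_seed(43)
  for (rep in 1:30) {
    n <- sample(2:4, 1)
    vlist <- lapply(seq_len(n), function(i) {
      v <- stats::rpois(5, 1.5)
      names(v) <- letters[1:5]
      v[v > 0]
    })
    names(vlist) <- paste0("s", seq_len(n))
    if (any(vapply(vlist, sum, 1) == 0)) next
    got <- bray_multi(vlist)
    exp <- oracle_bray_multi(vlist)
    expect_equal(got$d_tot, unname(exp["d_tot"]), tolerance = 1e-14)
    expect_equal(got$d_bal, unname(exp["d_bal"]), tolerance = 1e-14)
    expect_equal(got$d_gra, unname(exp["d_gra"]), tolerance = 1e-14)
  }
})

test_that("partition additivity, range, permutation and scale invariance hold", {
  withr::local_seed(47)
  for (rep in 1:30) {
    n <- sample(2:6, 1)
    m <- matrix(stats::rpois(n * 6, 1.5), nrow = n,
                dimnames = list(paste0("s", 1:n), letters[1:6]))
    m <- m[rowSums(m) > 0, , drop = FALSE]
    if (nrow(m) < 2) next
    part <- bray_multi(m)
    expect_equal(part$d_tot, part$d_bal + part$d_gra, tolerance = 1e-12)
    expect_true(all(c(part$d_tot, part$d_bal, part$d_gra) >= -1e-15))
    expect_true(all(c(part$d_tot, part$d_bal, part$d_gra) <= 1 + 1e-15))

    perm <- m[sample(nrow(m)), , drop = FALSE]
    expect_equal(bray_multi(perm)[-1], part[-1])

    scaled <- m * 7L
    expect_equal(bray_multi(scaled)[-1], part[-1], tolerance = 1e-12)
  }
})

test_that("identical sites give an all-zero partition at any count of sites", {
  base <- c(a = 4, b = 1, c = 2)
  for (n in 2:5) {
    vlist <- rep(list(base), n)
    names(vlist) <- paste0("s", 1:n)
    part <- bray_multi(vlist)
    expect_equal(as.numeric(part[-1]), c(0, 0, 0))
  }
})

test_that("empty sites are excluded with a warning; too few sites error", {
  m <- rbind(s1 = c(a = 2, b = 0), s2 = c(a = 0, b = 0), s3 = c(a = 1, b = 3))
  expect_warning(part <- bray_multi(m), "empty site")
  expect_equal(part$n_sites, 2)
  expect_error(suppressWarnings(bray_multi(m[1:2, ])),
               class = "effortdiv_validation_error")
})

test_that("beta effort curve is flat zero for identical sites and additive always", {
  ident <- degenerate_cases()$identical_pair
  curve <- beta_effort_curve(ident)
  expect_equal(curve$d_tot, c(0, 0))
  expect_equal(curve$d_bal, c(0, 0))
  expect_equal(curve$d_gra, c(0, 0))

  sim <- generate_study(mrg_like_preset(), seed = 13)
  bc <- suppressWarnings(beta_effort_curve(sim$hauls))
  expect_equal(nrow(bc), 40)
  expect_equal(bc$d_tot, bc$d_bal + bc$d_gra, tolerance = 1e-12)
  expect_true(all(bc$d_tot >= 0 & bc$d_tot <= 1))
})

test_that("site-to-site abundance substitution drives the balanced component", {
  # the generator's log-normal site effects create substitution-dominated
  # dissimilarity at full effort, as in real depauperate sand-bed surveys
  sim <- generate_study(mrg_like_preset(), seed = 17)
  bc <- suppressWarnings(beta_effort_curve(sim$hauls))
  final <- bc[bc$k == 40, ]
  expect_gt(final$d_bal / final$d_tot, final$d_gra / final$d_tot)
})

test_that("long-format and matrix inputs agree", {
  sim <- generate_study(community_params(n_sites = 5, hauls_per_site = 8),
                        seed = 19)
  long <- sim$hauls[!is.na(sim$hauls$species),
                    c("site_id", "species", "count")]
  from_long <- suppressWarnings(bray_multi(long))
  vlist <- lapply(split(long, long$site_id), function(d) {
    tapply(d$count, d$species, sum)
  })
  from_list <- suppressWarnings(bray_multi(vlist))
  expect_equal(from_long, from_list, tolerance = 1e-14)
})
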