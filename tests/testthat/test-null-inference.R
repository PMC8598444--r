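test_that("permutation preserves the label multiset and the None mask", {
  set.seed(1)
  for (i in 1:10) {
    lab <- matrix(sample(c(NA, 1:3), 64, replace = TRUE), 8, 8)
    if (!any(!is.na(lab))) next
    m <- trait_matrix(lab, C = 3)
    mp <- permute_combinations(m, seed = i)
    expect_identical(is.na(unclass(mp)), is.na(lab))
    expect_identical(tabulate(unclass(mp), 3), tabulate(lab, 3))
  }
  single <- trait_matrix(matrix(c(2L, NA, NA, NA), 2, 2), C = 2)
  expect_identical(unclass(permute_combinations(single, seed = 1)),
                   unclass(single))
})

test_that("permutations are uniform over arrangements", {
  m <- trait_matrix(matrix(1:4, 2, 2), C = 4)
  set.seed(7)
  seen <- replicate(2000, paste(unclass(permute_combinations(m)),
                                collapse = ""))
  tab <- table(seen)
  expect_equal(length(tab), 24L)          # all 4! arrangements occur
  chi <- stats::chisq.test(as.vector(tab))
  expect_gt(chi$p.value, 1e-4)
})

test_that("null moments degenerate correctly and respect the seed", {
  mono <- trait_matrix(matrix(1L, 8, 8), C = 1)
  nm <- estimate_null_moments(mono, 4, n_permutations = 50, seed = 1)
  expect_true(all(nm$mu == 0) && all(nm$sigma == 0))

  # single-entry regions are pinned at mu = 0 and counted
  lab <- matrix(NA_integer_, 4, 4)
  lab[1, 1] <- 1L; lab[3:4, 3:4] <- c(1L, 2L, 1L, 2L)
  m <- trait_matrix(lab, C = 2)
  nm2 <- estimate_null_moments(m, 2, n_permutations = 100, seed = 2)
  expect_equal(nm2$n_single_entry, 1L)
  one <- which(nm2$weights == 1 / 5)
  expect_equal(nm2$mu[one], 0)
  expect_equal(nm2$sigma[one], 0)

  m3 <- random_uniform_map(c(16, 16), 2, seed = 5)
  a <- estimate_null_moments(m3, 4, n_permutations = 100, seed = 9)
  b <- estimate_null_moments(m3, 4, n_permutations = 100, seed = 9)
  expect_identical(a$mu, b$mu)
  expect_identical(a$sigma, b$sigma)

  expect_error(estimate_null_moments(mono, 8, n_permutations = 50),
               "at least 2")
})

test_that("exact enumeration reproduces the two-trait region null", {
  em2 <- exact_region_moments(c(2, 2), n_traits = 2)
  em3 <- exact_region_moments(c(3, 3), n_traits = 2)
  # frozen from an independent brute-force enumeration of all 4^4 and
  # 4^9 per-cell configurations
  expect_equal(em2$mu, 0.5730997, tolerance = 1e-6)
  expect_equal(em2$sigma, 0.3096096, tolerance = 1e-6)
  expect_equal(em3$mu, 0.8333844, tolerance = 1e-6)
  expect_equal(em3$sigma, 0.1697512, tolerance = 1e-6)

  # independent oracle, recomputed here: explicit state-by-state walk
  states <- as.matrix(expand.grid(rep(list(0:3), 4)))
  vals <- apply(states, 1, function(st) {
    occ <- st[st > 0]
    if (!length(occ)) return(NA_real_)
    hti(tabulate(occ, 3), 3)
  })
  vals <- vals[!is.na(vals)]
  expect_equal(em2$mu, mean(vals), tolerance = 1e-12)
  expect_equal(em2$sigma, sqrt(mean((vals - mean(vals))^2)),
               tolerance = 1e-12)
})

test_that("exact moments agree with Monte-Carlo sampling within 3 SE", {
  set.seed(31)
  n <- 1e5
  states <- matrix(sample.int(4, n * 4, replace = TRUE) - 1L, n, 4)
  vals <- apply(states, 1, function(st) {
    occ <- st[st > 0]
    if (!length(occ)) return(NA_real_)
    hti(tabulate(occ, 3), 3)
  })
  vals <- vals[!is.na(vals)]
  em <- exact_region_moments(c(2, 2), 2)
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - em$mu), 3 * se)
})

test_that("exact path guards capacity and degenerates for one trait", {
  expect_equal(exact_region_moments(c(5, 5), 1)[c("mu", "sigma")],
               list(mu = 0, sigma = 0))
  expect_error(exact_region_moments(c(10, 10), 4), "guard")
})

test_that("p-values identify homogeneity and heterogeneity correctly", {
  hom <- region_homogeneous_map(c(32, 32), 8)
  fhom <- suppressWarnings(hta_test(hom, 8, n_permutations = 500, seed = 3))
  expect_lt(fhom$p$p_homogeneity, 1e-10)
  expect_gt(fhom$p$p_heterogeneity, 1 - 1e-10)

  # heterogeneity significance sharpens at fine grids: at coarse regions
  # the permutation null already sits near maximal entropy, compressing
  # the upper tail, so the balanced map is tested at its finest grid
  het <- region_heterogeneous_map(c(32, 32), 2)
  fhet <- suppressWarnings(hta_test(het, 2, n_permutations = 500, seed = 4))
  expect_lt(fhet$p$p_heterogeneity, 1e-10)

  het8 <- region_heterogeneous_map(c(32, 32), 8)
  f8 <- suppressWarnings(hta_test(het8, 8, n_permutations = 500, seed = 5))
  expect_lt(f8$p$p_overall, 0.05)     # still significant, but compressed

  for (f in list(fhom, fhet)) {
    expect_equal(f$p$p_homogeneity + f$p$p_heterogeneity, 1)
    expect_equal(f$p$p_overall,
                 min(2 * min(f$p$p_homogeneity, f$p$p_heterogeneity), 1))
  }
})

test_that("degenerate and small-R cases are flagged", {
  mono <- trait_matrix(matrix(1L, 8, 8), C = 1)
  expect_error(suppressWarnings(
    hta_test(mono, 4, n_permutations = 50, seed = 1)), "zero")
  m <- random_uniform_map(c(16, 16), 2, seed = 6)
  expect_warning(hta_test(m, 8, n_permutations = 100, seed = 1),
                 "normal approximation")
})

test_that("equal-weight regions: Lyapunov z matches the iid-CLT z", {
  # fully occupied matrix, equal regions: pooling the per-region
  # permutation moments must reproduce the weighted standardisation up
  # to the Monte-Carlo spread of the per-region means
  m <- random_label_matrix(c(32, 32), C = 3, seed = 13)
  st <- hta_index(m, 8)
  nm <- estimate_null_moments(m, 8, n_permutations = 2000, seed = 14)
  z_lyap <- hta_p_values(st, nm, min_R = 2)$z
  mu_pool <- mean(nm$mu)
  sd_pool <- sqrt(mean(nm$sigma^2) + mean((nm$mu - mu_pool)^2))
  z_iid <- (st$hta - mu_pool) / (sd_pool / sqrt(st$R))
  expect_equal(z_lyap, z_iid, tolerance = 0.05)
})

test_that("mixing a homogeneous map never decreases the homogeneity p-value", {
  z <- vapply(c(0, 0.4, 0.85, 1), function(frac) {
    m <- mixed_homogeneous_map(frac = frac, seed = 7)
    suppressWarnings(hta_test(m, 8, n_permutations = 300, seed = 11))$p$z
  }, numeric(1))
  expect_true(all(diff(z) > 0))   # z (hence p_homogeneity) increases
})
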