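test_that("chi2_fit solves the affine fit in closed form", {
  q <- default_q_grid()
  M <- debye_chain((q * 30)^2)
  exp_p <- scattering_profile(q, 3 * M + 5, rep(1, length(q)))
  r <- chi2_fit(exp_p, M)
  expect_equal(r$c, 3, tolerance = 1e-9)
  expect_equal(r$b, 5, tolerance = 1e-9)
  expect_equal(r$chi2, 0, tolerance = 1e-12)

  # scale-only mode
  exp_s <- scattering_profile(q, 3 * M, rep(1, length(q)))
  rs <- chi2_fit(exp_s, M, fit_background = FALSE)
  expect_equal(rs$c, 3, tolerance = 1e-9)
  expect_equal(rs$chi2, 0, tolerance = 1e-12)

  # unit Gaussian noise at sigma = 1: reduced chi2 near 1 (K - 2 dof)
  set.seed(123)
  noisy <- scattering_profile(q, M + rnorm(length(q)), rep(1, length(q)))
  rn <- chi2_fit(noisy, M)
  expect_gt(rn$chi2, 0.6)
  expect_lt(rn$chi2, 1.5)

  flat <- rep(2, length(q))
  expect_error(chi2_fit(exp_p, flat), "singular-fit")
})

test_that("GA equals exhaustive search on an enumerable problem", {
  pl <- shared_pool()
  q <- default_q_grid()
  small <- pl$profiles[1:6, ]
  target <- colMeans(small[c(2, 5), ])
  exp_p <- scattering_profile(q, target, pmax(0.01 * target, 1e-9))
  ex <- exhaustive_select(exp_p, small, size = 2L)
  ga <- ga_select(exp_p, small,
                  ga_settings(ensemble_size = 2L, n_generations = 300L,
                              seed = 21))
  expect_equal(ga$chi2, ex$chi2, tolerance = 1e-9)
})

test_that("GA recovers a planted single conformer", {
  pl <- shared_pool()
  q <- default_q_grid()
  profiles <- pl$profiles[1:200, ]
  target <- profiles[37, ]
  exp_p <- scattering_profile(q, target, 0.01 * target)
  res <- ga_select(exp_p, profiles, ga_settings(seed = 5))
  expect_lt(res$chi2, 0.1)
  # >= 80% of mass on conformers whose profile correlates > 0.999 with it
  ids <- as.integer(names(res$fractions))
  cors <- vapply(ids, function(i) stats::cor(profiles[i, ], target), 1.0)
  expect_gte(sum(res$fractions[cors > 0.999]), 0.8)
})

test_that("GA invariants: monotone trace, bit-stable reruns, chi2 bound", {
  pl <- shared_pool()
  q <- default_q_grid()
  set.seed(31)
  rg <- pl$pool$metrics$rg
  idx <- c(sample(which(rg < 35), 35, TRUE), sample(which(rg > 45), 15, TRUE))
  I <- colMeans(pl$profiles[idx, ])
  sg <- 0.01 * sqrt(I[1] * I)
  exp_p <- scattering_profile(q, I + rnorm(length(I), 0, sg), sg)

  st <- ga_settings(seed = 9, n_generations = 400L)
  r1 <- ga_select(exp_p, pl$profiles, st, pool = pl$pool)
  expect_true(all(diff(r1$fitness_trace) <= 0))
  expect_equal(sum(r1$fractions), 1, tolerance = 1e-12)

  r2 <- ga_select(exp_p, pl$profiles, st, pool = pl$pool)
  expect_identical(r1$indices, r2$indices)
  expect_identical(r1$chi2, r2$chi2)

  # ensemble chi2 can never exceed the best single conformer replicated
  best_single <- min(apply(pl$profiles, 1L, function(m)
    chi2_fit(exp_p, m)$chi2))
  expect_lte(r1$chi2, best_single + 1e-12)
})

test_that("two-population mixtures are recovered within 10 points", {
  pl <- shared_pool()
  q <- default_q_grid()
  set.seed(77)
  rg <- pl$pool$metrics$rg
  idx <- c(sample(which(rg < 35), 35, TRUE), sample(which(rg > 45), 15, TRUE))
  I <- colMeans(pl$profiles[idx, ])
  sg <- 0.01 * sqrt(I[1] * I)
  exp_p <- scattering_profile(q, I + rnorm(length(I), 0, sg), sg)
  res <- ga_select(exp_p, pl$profiles, ga_settings(seed = 13), pool = pl$pool)
  expect_lt(abs(extended_mass(res, pl$pool) - 0.30), 0.10)
})

test_that("rg_distribution: point mass, sampling identity, provenance", {
  pl <- shared_pool()
  q <- default_q_grid()
  # all multiplicity on one conformer -> a single nonzero bin
  k <- which.min(abs(pl$pool$metrics$rg - 31))
  fake <- structure(list(
    multiplicities = stats::setNames(50L, k),
    fractions = stats::setNames(1.0, k),
    indices = rep(k, 50), chi2 = 0, c = 1, b = 0,
    pool_seed = pl$pool$seed), class = "ensemble_fit")
  h <- rg_distribution(fake, pl$pool)
  expect_equal(sum(h$weight > 0), 1L)
  rgk <- pl$pool$metrics$rg[k]
  nz <- which(h$weight > 0)
  expect_true(h$rg_lo[nz] <= rgk && rgk < h$rg_hi[nz] + 1e-9)

  # uniform multiplicities over a large sample track the pool histogram
  set.seed(2)
  ids <- sample(length(pl$pool), 500, replace = TRUE)
  tab <- table(ids)
  unif <- structure(list(
    multiplicities = stats::setNames(as.integer(tab), names(tab)),
    fractions = stats::setNames(as.numeric(tab) / 500, names(tab)),
    indices = ids, chi2 = 0, c = 1, b = 0,
    pool_seed = pl$pool$seed), class = "ensemble_fit")
  hu <- rg_distribution(unif, pl$pool)
  tv <- 0.5 * sum(abs(hu$weight - hu$pool_weight))
  expect_lt(tv, 0.1)

  other <- generate_pool(10, seed = 999)
  expect_error(rg_distribution(fake, other), "provenance")
})
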