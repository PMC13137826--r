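test_that("generated chains respect bond length and excluded volume", {
  c3 <- generate_chain(3, seed = 5)
  d <- sqrt(rowSums(diff(c3$coords)^2))
  expect_equal(d, rep(3.8, 2), tolerance = 1e-6)

  # determinism at n_res = 140
  a <- generate_chain(140, seed = 11)
  b <- generate_chain(140, seed = 11)
  expect_identical(a$coords, b$coords)

  # brute-force O(N^2) audit of bonds and clashes over many chains
  set.seed(99)
  for (i in 1:200) {
    ch <- generate_chain(140)
    bonds <- sqrt(rowSums(diff(ch$coords)^2))
    expect_true(all(abs(bonds - 3.8) < 1e-6))
    dm <- as.matrix(stats::dist(ch$coords))
    nonadj <- abs(row(dm) - col(dm)) >= 2
    expect_gte(min(dm[nonadj]), 3.8 - 1e-9)
  }
})

test_that("chain metrics match hand calculations and are rigid-motion invariant", {
  rod <- structure(list(coords = cbind(c(0, 3.8, 7.6), 0, 0),
                        n_res = 3L, id = 1L), class = "conformer")
  m <- chain_metrics(rod, domain_scheme(list(ree = c(1L, 3L),
                                             ntd_internal = c(1L, 2L),
                                             nac_internal = c(2L, 3L),
                                             ctd_internal = c(1L, 3L),
                                             ntd_nac = c(1L, 3L),
                                             nac_ctd = c(1L, 3L))))
  expect_equal(m$ree, 7.6)
  expect_equal(m$rg, 3.8 * sqrt(2 / 3), tolerance = 1e-9)

  # two-point molecule: rg = d/2
  two <- structure(list(coords = cbind(c(0, 10), 0, 0), n_res = 2L, id = 1L),
                   class = "conformer")
  sch2 <- domain_scheme(lapply(domain_scheme(), function(x) c(1L, 2L)))
  expect_equal(chain_metrics(two, sch2)$rg, 5)

  # random rigid rotations + translation leave all metrics unchanged
  ch <- generate_chain(60, seed = 3)
  m0 <- chain_metrics(ch, domain_scheme(list(ree = c(1L, 60L),
                                             ntd_internal = c(1L, 25L),
                                             nac_internal = c(26L, 40L),
                                             ctd_internal = c(41L, 60L),
                                             ntd_nac = c(1L, 40L),
                                             nac_ctd = c(26L, 60L))))
  set.seed(12)
  for (k in 1:10) {
    th <- runif(3, 0, 2 * pi)
    Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
                c(0, sin(th[1]), cos(th[1])))
    Rz <- rbind(c(cos(th[3]), -sin(th[3]), 0),
                c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
    rot <- ch
    rot$coords <- ch$coords %*% (Rx %*% Rz) +
      matrix(runif(3, -50, 50), 60, 3, byrow = TRUE)
    mr <- chain_metrics(rot, domain_scheme(list(ree = c(1L, 60L),
                                                ntd_internal = c(1L, 25L),
                                                nac_internal = c(26L, 40L),
                                                ctd_internal = c(41L, 60L),
                                                ntd_nac = c(1L, 40L),
                                                nac_ctd = c(26L, 60L))))
    expect_equal(as.numeric(mr[-1]), as.numeric(m0[-1]), tolerance = 1e-9)
  }
})

test_that("pools are deterministic, counted, and span compact to extended", {
  p1 <- generate_pool(10, seed = 1)
  expect_equal(nrow(p1$metrics), 10L)
  p2 <- generate_pool(10, seed = 1)
  expect_equal(p1$metrics, p2$metrics)

  pl <- shared_pool()  # 800 chains, default mixture
  rg <- pl$pool$metrics$rg
  expect_lt(min(rg), 25)
  expect_gt(max(rg), 55)
})

test_that("flexible-regime chains satisfy polymer scaling, pools stable across seeds", {
  pl <- shared_pool()
  flex <- pl$pool$metrics[pl$pool$metrics$regime == "flexible", ]
  ratio <- mean(flex$ree^2) / mean(flex$rg^2)
  expect_gt(ratio, 5)
  expect_lt(ratio, 8)

  other <- generate_pool(800, seed = 8)
  ks <- suppressWarnings(stats::ks.test(pl$pool$metrics$rg,
                                        other$metrics$rg))
  expect_lt(unname(ks$statistic), 0.08)
})

test_that("multi-model PDB round-trips coordinates", {
  pool <- generate_pool(10, n_res = 30, seed = 2)
  path <- tempfile(fileext = ".pdb")
  write_pool_pdb(pool, path)
  back <- read_calpha_pdb(path)
  expect_length(back, 10L)
  expect_equal(back[[3]]$coords, unname(pool$conformers[[3]]$coords),
               tolerance = 1e-3)  # PDB fixed-width precision
})
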