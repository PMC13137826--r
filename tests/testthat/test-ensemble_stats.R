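make_fake_fit <- function(ids, weights, pool_seed = NA_integer_) {
  w <- weights / sum(weights)
  structure(list(multiplicities = stats::setNames(as.integer(weights * 100), ids),
                 fractions = stats::setNames(w, ids),
                 indices = rep(as.integer(ids), round(weights * 4)),
                 chi2 = 1, c = 1, b = 0, pool_seed = pool_seed),
            class = "ensemble_fit")
}

test_that("weighted domain distances: identity, hand arithmetic, convexity", {
  pl <- shared_pool()
  f1 <- make_fake_fit(5, 1, pl$pool$seed)
  d1 <- weighted_domain_distances(f1, pl$pool)
  expect_equal(d1$mean[d1$pair == "ree"], pl$pool$metrics$ree[5])
  expect_equal(d1$sd, rep(0, 6))

  # two conformers, weights 0.25/0.75 on distances d_a, d_b
  f2 <- make_fake_fit(c(3, 9), c(0.25, 0.75), pl$pool$seed)
  d2 <- weighted_domain_distances(f2, pl$pool)
  for (pr in d2$pair) {
    da <- pl$pool$metrics[[pr]][3]; db <- pl$pool$metrics[[pr]][9]
    expect_equal(d2$mean[d2$pair == pr], 0.25 * da + 0.75 * db)
    # convexity
    expect_gte(d2$mean[d2$pair == pr], min(da, db) - 1e-12)
    expect_lte(d2$mean[d2$pair == pr], max(da, db) + 1e-12)
  }

  # hand check with synthetic distances 50 and 100 at 0.25/0.75
  expect_equal(0.25 * 50 + 0.75 * 100, 87.5)

  # pairing preserved under permutation of the (id, weight) listing
  f2p <- make_fake_fit(c(9, 3), c(0.75, 0.25), pl$pool$seed)
  d2p <- weighted_domain_distances(f2p, pl$pool)
  expect_equal(d2p$mean, d2$mean)
})

test_that("clustering recovers planted blobs and honours the threshold limit", {
  set.seed(5)
  centers <- list(c(25, 60, 0.2), c(45, 110, 0.5), c(60, 160, 0.8))
  rows <- do.call(rbind, lapply(1:3, function(k) {
    n <- 50
    data.frame(rg = centers[[k]][1] + rnorm(n, 0, 0.3),
               ree = centers[[k]][2] + rnorm(n, 0, 0.8),
               fraction = centers[[k]][3] + rnorm(n, 0, 0.004),
               condition = sprintf("cond%d", (seq_len(n) %% 3) + 1),
               time = 1, truth = k)
  }))
  cm <- cluster_ensembles(rows)
  expect_equal(cm$k, 3L)
  expect_equal(adjusted_rand(cm$assignments, rows$truth), 1.0)
  expect_gt(cm$silhouette, 0.8)

  # t -> infinity collapses everything into one cluster
  cm1 <- cluster_ensembles(rows, t = 1e9)
  expect_equal(cm1$k, 1L)
  expect_true(cm1$single_cluster)

  # duplication invariance of cluster means
  dup <- rbind(rows, rows)
  cmd <- cluster_ensembles(dup)
  expect_equal(sort(cmd$summaries$mean_rg), sort(cm$summaries$mean_rg),
               tolerance = 1e-9)

  # row order invariance (up to label permutation)
  perm <- sample(nrow(rows))
  cmp <- cluster_ensembles(rows[perm, ])
  expect_equal(adjusted_rand(cmp$assignments, cm$assignments[perm]), 1.0)
})

test_that("Hedges g matches hand computation and null identity", {
  expect_equal(hedges_g(c(1, 2, 3), c(2, 3, 4)), -0.8)
  expect_equal(hedges_g(c(5, 6, 7, 8), c(5, 6, 7, 8)), 0)
})

test_that("condition_stats: flags a planted shift, BH monotone, small groups dropped", {
  set.seed(11)
  mk <- function(cond, rg_mu, n = 40) {
    data.frame(rg = rnorm(n, rg_mu, 2), ree = rnorm(n, 100, 8),
               fraction = rep(1 / n, n), condition = cond, time = 1)
  }
  feats <- rbind(mk("wt", 35), mk("mn", 35.3), mk("fe", 28), mk("zn", 35.2))
  rep <- condition_stats(feats)
  expect_s3_class(rep, "stat_report")
  kw_rg <- rep$kruskal[rep$kruskal$feature == "rg", ]
  expect_lt(kw_rg$p, 0.05)
  pw <- rep$pairwise[rep$pairwise$feature == "rg", ]
  fe_pairs <- pw[pw$group1 == "fe" | pw$group2 == "fe", ]
  other <- pw[pw$group1 != "fe" & pw$group2 != "fe", ]
  expect_true(all(fe_pairs$flag))
  expect_false(any(other$flag))
  # |g| > 0.8 on the shifted condition
  expect_true(all(abs(fe_pairs$g) > 0.8))

  # BH monotonicity: q ordered as p
  ord <- order(pw$p)
  expect_true(all(diff(pw$q[ord]) >= -1e-12))
  expect_true(all(pw$q >= pw$p - 1e-12))

  tiny <- rbind(feats, mk("cu", 30, n = 2))
  expect_warning(rep2 <- condition_stats(tiny), "fewer than 3")
  expect_false("cu" %in% c(rep2$pairwise$group1, rep2$pairwise$group2))
})

test_that("a single extended-shifted condition is the only flagged one across seeds", {
  hits <- 0L
  for (s in 1:10) {
    set.seed(s)
    mk <- function(cond, rg_mu, ree_mu) {
      n <- 30
      data.frame(rg = rnorm(n, rg_mu, 2.5), ree = rnorm(n, ree_mu, 10),
                 fraction = rep(1 / n, n), condition = cond, time = 1)
    }
    feats <- rbind(mk("wt", 33, 95), mk("mn", 33.4, 96), mk("fe", 32.8, 94),
                   mk("zn", 33.2, 95), mk("cu", 42, 135))
    rep <- condition_stats(feats)
    pw <- rep$pairwise[rep$pairwise$feature == "rg", ]
    cu <- pw[pw$group1 == "cu" | pw$group2 == "cu", ]
    rest <- pw[pw$group1 != "cu" & pw$group2 != "cu", ]
    if (all(abs(cu$g) > 0.8) && all(cu$flag) && !any(rest$flag)) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("feature table fractions sum to 1 within each fit", {
  pl <- shared_pool()
  fits <- list(wt = list(`0.18` = make_fake_fit(c(2, 4, 6), c(0.2, 0.3, 0.5),
                                                pl$pool$seed),
                         `0.54` = make_fake_fit(c(1, 8), c(0.5, 0.5),
                                                pl$pool$seed)))
  ft <- feature_table(fits, pl$pool)
  sums <- tapply(ft$fraction, paste(ft$condition, ft$time), sum)
  expect_equal(as.numeric(sums), rep(1, 2), tolerance = 1e-12)
  expect_true(all(ft$rg > 0 & ft$ree > 0))
})
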