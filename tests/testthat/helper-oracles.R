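# Closed-form curves used as independent oracles, plus a shared conformer
# pool cached across test files (building it once keeps the suite fast).

gaussian_chain_profile <- function(rg, i0 = 100,
                                   q = seq(0.005, 0.2, length.out = 120),
                                   rel_sigma = 1e-3) {
  I <- i0 * debye_chain((q * rg)^2)
  scattering_profile(q, I, rel_sigma * I, label = sprintf("chain Rg=%g", rg))
}

guinier_law_profile <- function(rg, i0 = 100,
                                q = seq(0.002, 0.05, by = 5e-4),
                                rel_sigma = 1e-3) {
  I <- i0 * exp(-q^2 * rg^2 / 3)
  scattering_profile(q, I, rel_sigma * I, label = sprintf("guinier Rg=%g", rg))
}

sphere_profile <- function(radius, i0 = 1,
                           q = seq(0.008, 0.35, length.out = 120),
                           rel_sigma = 1e-2) {
  I <- sphere_intensity(q, radius, i0)
  # counting-statistics floor: noise does not vanish at the form-factor minima
  scattering_profile(q, I, rel_sigma * (I + 0.01 * i0),
                     label = sprintf("sphere R=%g", radius))
}

# pair-distance distribution of a homogeneous sphere of radius R
# (diameter D = 2R): p(r) ~ r^2 (1 - 3r/(2D) + r^3/(2D^3)) for r <= D
sphere_pr <- function(r, radius) {
  D <- 2 * radius
  x <- r / D
  p <- r^2 * (1 - 1.5 * x + 0.5 * x^3)
  p[r > D] <- 0
  p
}

.pool_cache <- new.env(parent = emptyenv())

shared_pool <- function(n = 800L, seed = 7L) {
  key <- sprintf("pool_%d_%d", n, seed)
  if (is.null(.pool_cache[[key]])) {
    pool <- generate_pool(n, seed = seed)
    profiles <- pool_profiles(pool)
    .pool_cache[[key]] <- list(pool = pool, profiles = profiles)
  }
  .pool_cache[[key]]
}

# adjusted Rand index between two partitions (permutation-invariant
# agreement; 1 = identical up to relabelling)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}
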