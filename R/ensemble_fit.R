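#' Genetic-algorithm settings for sub-ensemble selection
#'
#' Defaults follow the ensemble-optimization convention for disordered
#' proteins: 1000 generations of 50 candidate ensembles, each a multiset of
#' 50 pool conformers, with a constant background fitted alongside the scale.
#'
#' @param ensemble_size conformers per ensemble (with repetition), default 50.
#' @param n_ensembles candidate ensembles per generation, default 50.
#' @param n_generations generation budget, default 1000.
#' @param mutation_rate per-slot random-reset probability, default 0.1.
#' @param crossover_rate probability a child is made by uniform crossover
#'   (otherwise cloned from one parent), default 0.5.
#' @param elite_count ensembles copied unchanged each generation, default 5.
#' @param local_moves single-slot hill-climbing proposals applied to the
#'   incumbent best ensemble each generation (a memetic refinement that
#'   purifies the multiset much faster than mutation alone); default 30,
#'   0 disables.
#' @param seed integer RNG seed.
#' @param fit_background fit a constant background, default TRUE.
#' @param polish run an exact coordinate-descent refinement of the final
#'   ensemble (each slot in turn set to the chi2-minimizing pool conformer
#'   until no slot can be improved); default TRUE.
#' @param tol,patience early stop when the best chi2 improves by less than
#'   \code{tol} over \code{patience} consecutive generations.
#' @export
ga_settings <- function(ensemble_size = 50L, n_ensembles = 50L,
                        n_generations = 1000L, mutation_rate = 0.1,
                        crossover_rate = 0.5, elite_count = 5L,
                        local_moves = 30L, polish = TRUE,
                        seed = 1L, fit_background = TRUE,
                        tol = 1e-4, patience = 100L) {
  stopifnot(ensemble_size >= 1L, elite_count < n_ensembles,
            mutation_rate >= 0, mutation_rate <= 1,
            crossover_rate >= 0, crossover_rate <= 1)
  structure(list(ensemble_size = as.integer(ensemble_size),
                 n_ensembles = as.integer(n_ensembles),
                 n_generations = as.integer(n_generations),
                 mutation_rate = mutation_rate,
                 crossover_rate = crossover_rate,
                 elite_count = as.integer(elite_count),
                 local_moves = as.integer(local_moves),
                 polish = isTRUE(polish),
                 seed = as.integer(seed),
                 fit_background = isTRUE(fit_background),
                 tol = tol, patience = as.integer(patience)),
            class = "ga_settings")
}

#' Fit scale and background of a model curve to data
#'
#' Closed-form weighted linear least squares for (c, b) in
#' \eqn{\sum_k [(I_k - c M_k - b)/\sigma_k]^2}; b is fixed to 0 when
#' \code{fit_background} is off. The reported chi2 is reduced by K - 2
#' degrees of freedom (K - 1 with b fixed).
#'
#' @param exp a \code{\link{scattering_profile}} with sigma > 0.
#' @param model numeric model intensities on the same q grid (or a
#'   theoretical \code{scattering_profile}).
#' @param fit_background default TRUE.
#' @return list(chi2, c, b).
#' @export
chi2_fit <- function(exp, model, fit_background = TRUE) {
  stopifnot(inherits(exp, "scattering_profile"))
  if (inherits(model, "scattering_profile")) {
    if (!q_grids_match(exp, model))
      stop("grid-mismatch error: model and data q grids differ")
    model <- model$intensity
  }
  I <- exp$intensity; s <- exp$sigma
  stopifnot(length(model) == length(I), all(s > 0))
  w <- 1 / s^2
  K <- length(I)
  if (fit_background) {
    Sw <- sum(w); Sm <- sum(w * model); Sm2 <- sum(w * model^2)
    Si <- sum(w * I); Smi <- sum(w * model * I)
    det <- Sm2 * Sw - Sm^2
    if (abs(det) <= 1e-12 * Sm2 * Sw)
      stop("singular-fit error: model is constant, scale and background are confounded")
    cc <- (Smi * Sw - Sm * Si) / det
    b <- (Sm2 * Si - Sm * Smi) / det
    dof <- K - 2L
  } else {
    cc <- sum(w * model * I) / sum(w * model^2)
    b <- 0.0
    dof <- K - 1L
  }
  chi2 <- sum(w * (I - cc * model - b)^2) / max(1L, dof)
  list(chi2 = chi2, c = cc, b = b)
}

#' Genetic-algorithm sub-ensemble selection
#'
#' Selects a fixed-size multiset of pool conformers (repetition allowed)
#' whose average theoretical profile, after fitting a scale and constant
#' background, best matches the experimental curve. Generational loop with
#' elitism, binary tournament selection, uniform multiset crossover and
#' per-slot random-reset mutation; fully reproducible from
#' \code{settings$seed}. The elitist best-chi2 trace is non-increasing by
#' construction.
#'
#' @param exp experimental \code{\link{scattering_profile}}.
#' @param profiles pool profile matrix (n_conformers x n_q), rows in pool
#'   order (see \code{\link{pool_profiles}}).
#' @param settings a \code{\link{ga_settings}}.
#' @param pool optional \code{conformer_pool} for the Rg distribution.
#' @return object of class \code{ensemble_fit}: \code{multiplicities}
#'   (named counts per selected conformer id), \code{fractions},
#'   \code{chi2}, \code{c}, \code{b}, \code{indices} (the best multiset),
#'   \code{fitness_trace}, \code{generations_run}, and, when \code{pool} is
#'   given, \code{rg_distribution}.
#' @export
ga_select <- function(exp, profiles, settings = ga_settings(), pool = NULL) {
  stopifnot(inherits(exp, "scattering_profile"), is.matrix(profiles))
  n_pool <- nrow(profiles)
  stopifnot(n_pool >= settings$ensemble_size || n_pool >= 1L)
  if (ncol(profiles) != length(exp$q))
    stop("grid-mismatch error: profile matrix does not match the data q grid")
  set.seed(settings$seed)
  S <- settings$ensemble_size
  P <- settings$n_ensembles
  w <- 1 / exp$sigma^2
  I <- exp$intensity
  fitness <- function(idx) {
    M <- colMeans(profiles[idx, , drop = FALSE])
    chi2_fit(exp, M, settings$fit_background)$chi2
  }
  chrom <- matrix(sample.int(n_pool, P * S, replace = TRUE), P, S)
  # seed two chromosomes with informed starts: the continuous NNLS
  # solution rounded to the slot granularity, and the best single
  # conformer replicated; the GA operators then refine the multiset
  seed_idx <- tryCatch(nnls_seed(I, exp$sigma, profiles, S,
                                 settings$fit_background),
                       error = function(e) NULL)
  if (!is.null(seed_idx)) chrom[1L, ] <- seed_idx
  single_chi <- vapply(seq_len(n_pool), function(i)
    tryCatch(chi2_fit(exp, profiles[i, ], settings$fit_background)$chi2,
             error = function(e) Inf), 1.0)
  chrom[2L, ] <- rep(which.min(single_chi), S)
  fit <- apply(chrom, 1L, fitness)
  best_trace <- numeric(0)
  best_chi2 <- Inf; best_idx <- NULL
  stall <- 0L
  gens <- 0L
  for (g in seq_len(settings$n_generations)) {
    gens <- g
    ord <- order(fit)
    if (fit[ord[1L]] < best_chi2 - settings$tol) stall <- 0L
    else stall <- stall + 1L
    if (fit[ord[1L]] < best_chi2) {
      best_chi2 <- fit[ord[1L]]
      best_idx <- chrom[ord[1L], ]
    }
    best_trace <- c(best_trace, best_chi2)
    if (stall >= settings$patience) break
    elite <- chrom[ord[seq_len(settings$elite_count)], , drop = FALSE]
    n_off <- P - settings$elite_count
    offspring <- matrix(0L, n_off, S)
    for (k in seq_len(n_off)) {
      # binary tournament for each parent
      t1 <- sample.int(P, 2L); t2 <- sample.int(P, 2L)
      p1 <- chrom[t1[which.min(fit[t1])], ]
      p2 <- chrom[t2[which.min(fit[t2])], ]
      child <- if (stats::runif(1) < settings$crossover_rate) {
        pick <- stats::runif(S) < 0.5
        ifelse(pick, p1, p2)
      } else p1
      mut <- stats::runif(S) < settings$mutation_rate
      if (any(mut)) child[mut] <- sample.int(n_pool, sum(mut), replace = TRUE)
      offspring[k, ] <- child
    }
    chrom <- rbind(elite, offspring)
    fit <- c(fit[ord[seq_len(settings$elite_count)]],
             apply(offspring, 1L, fitness))
    # memetic step: single-slot hill climbing on the incumbent best,
    # with an O(n_q) incremental update of the ensemble-average profile
    if (settings$local_moves > 0L) {
      bi <- which.min(fit)
      cur <- chrom[bi, ]
      csum <- colSums(profiles[cur, , drop = FALSE])
      cchi <- fit[bi]
      slots <- sample.int(S, settings$local_moves, replace = TRUE)
      cands <- sample.int(n_pool, settings$local_moves, replace = TRUE)
      # half the proposals consolidate mass on conformers already selected,
      # which escapes compensating mixtures that single random swaps cannot
      dup <- stats::runif(settings$local_moves) < 0.5
      cands[dup] <- cur[sample.int(S, sum(dup), replace = TRUE)]
      for (m in seq_len(settings$local_moves)) {
        sl <- slots[m]; cand <- cands[m]
        if (cand == cur[sl]) next
        nsum <- csum - profiles[cur[sl], ] + profiles[cand, ]
        nchi <- tryCatch(chi2_fit(exp, nsum / S, settings$fit_background)$chi2,
                         error = function(e) Inf)
        if (nchi < cchi) {
          cur[sl] <- cand; csum <- nsum; cchi <- nchi
        }
      }
      chrom[bi, ] <- cur
      fit[bi] <- cchi
    }
  }
  if (settings$polish)
    best_idx <- polish_ensemble(exp, profiles, best_idx,
                                settings$fit_background)
  M <- colMeans(profiles[best_idx, , drop = FALSE])
  cb <- chi2_fit(exp, M, settings$fit_background)
  counts <- table(best_idx)
  res <- structure(list(
    multiplicities = stats::setNames(as.integer(counts), names(counts)),
    fractions = stats::setNames(as.numeric(counts) / S, names(counts)),
    indices = best_idx,
    chi2 = cb$chi2, c = cb$c, b = cb$b,
    fitness_trace = best_trace, generations_run = gens,
    settings = settings,
    pool_seed = if (!is.null(pool)) pool$seed else NA_integer_),
    class = "ensemble_fit")
  if (!is.null(pool))
    res$rg_distribution <- rg_distribution(res, pool)
  res
}

#' @export
print.ensemble_fit <- function(x, ...) {
  cat(sprintf("<ensemble_fit> chi2 = %.3f (c = %.3g, b = %.3g), %d distinct conformers, %d generations\n",
              x$chi2, x$c, x$b, length(x$multiplicities), x$generations_run))
  invisible(x)
}

#' Ensemble-weighted Rg histogram
#'
#' Histogram of pool Rg values weighted by the selected fractions,
#' normalized to sum 1, with the pool's own (unweighted, normalized)
#' histogram attached for comparison.
#'
#' @param res an \code{ensemble_fit}.
#' @param pool the \code{conformer_pool} the fit was run against.
#' @param bin_width histogram bin width in A, default 2.
#' @return data.frame with columns \code{rg_lo}, \code{rg_hi},
#'   \code{weight}, \code{pool_weight}.
#' @export
rg_distribution <- function(res, pool, bin_width = 2.0) {
  stopifnot(inherits(res, "ensemble_fit"), inherits(pool, "conformer_pool"))
  if (!is.na(res$pool_seed) && res$pool_seed != pool$seed)
    stop("provenance error: result was fitted against a different pool")
  rg <- pool$metrics$rg
  ids <- as.integer(names(res$fractions))
  if (any(ids < 1L | ids > length(rg)))
    stop("provenance error: conformer ids outside the pool")
  breaks <- seq(floor(min(rg) / bin_width) * bin_width,
                ceiling(max(rg) / bin_width) * bin_width, by = bin_width)
  sel_bin <- findInterval(rg[ids], breaks, rightmost.closed = TRUE)
  wt <- numeric(length(breaks) - 1L)
  for (k in seq_along(ids)) wt[sel_bin[k]] <- wt[sel_bin[k]] + res$fractions[k]
  pool_bin <- findInterval(rg, breaks, rightmost.closed = TRUE)
  pw <- tabulate(pool_bin, nbins = length(breaks) - 1L) / length(rg)
  data.frame(rg_lo = breaks[-length(breaks)], rg_hi = breaks[-1L],
             weight = wt / sum(wt), pool_weight = pw)
}

# Continuous-relaxation seed: nonnegative least squares of the data on all
# pool profiles (plus a signed constant when the background is fitted),
# with the weight vector rounded to S slots by largest remainder.
nnls_seed <- function(I, sigma, profiles, S, fit_background) {
  A <- t(profiles) / sigma
  if (fit_background) A <- cbind(A, 1 / sigma, -1 / sigma)
  x <- nnls_solve(A, I / sigma, maxit = 5000L)
  wgt <- x[seq_len(nrow(profiles))]
  if (sum(wgt) <= 0) stop("empty nnls solution")
  wgt <- wgt / sum(wgt)
  counts <- floor(wgt * S)
  rem <- wgt * S - counts
  short <- S - sum(counts)
  if (short > 0L) {
    top <- order(rem, decreasing = TRUE)[seq_len(short)]
    counts[top] <- counts[top] + 1L
  }
  rep(seq_along(counts), counts)
}

# Exact coordinate descent on the multiset: each slot in turn is set to
# the pool conformer minimizing the (scale + background)-fitted weighted
# residual sum of squares, sweeping until no slot improves. The per-slot
# minimization over all candidates is done in closed form.
polish_ensemble <- function(exp, profiles, idx, fit_background = TRUE,
                            max_sweeps = 20L) {
  S <- length(idx)
  w <- 1 / exp$sigma^2
  I <- exp$intensity
  Sw <- sum(w); Si <- sum(w * I); Sii <- sum(w * I^2)
  # per-candidate constants (v_c = profile_c / S)
  B1 <- as.numeric(profiles %*% w) / S
  B2 <- as.numeric(profiles^2 %*% w) / S^2
  D2 <- as.numeric(profiles %*% (w * I)) / S
  csum <- colSums(profiles[idx, , drop = FALSE])
  ss_of <- function(u_all) { # residual SS of the current full model
    cb <- tryCatch(chi2_fit(exp, u_all, fit_background),
                   error = function(e) NULL)
    if (is.null(cb)) return(Inf)
    sum(w * (I - cb$c * u_all - cb$b)^2)
  }
  cur_ss <- ss_of(csum / S)
  for (sweep in seq_len(max_sweeps)) {
    improved <- FALSE
    for (s in seq_len(S)) {
      u <- (csum - profiles[idx[s], ]) / S
      A1 <- sum(w * u); A2 <- sum(w * u^2); D1 <- sum(w * I * u)
      C <- as.numeric(profiles %*% (w * u)) / S
      Sm <- A1 + B1; Sm2 <- A2 + 2 * C + B2; Smi <- D1 + D2
      if (fit_background) {
        det <- Sm2 * Sw - Sm^2
        ok <- abs(det) > 1e-12 * pmax(Sm2 * Sw, 1)
        cc <- (Smi * Sw - Sm * Si) / det
        bb <- (Sm2 * Si - Sm * Smi) / det
        ss <- Sii - cc * Smi - bb * Si
      } else {
        ok <- Sm2 > 0
        cc <- Smi / Sm2
        ss <- Sii - cc * Smi
      }
      ss[!ok] <- Inf
      best <- which.min(ss)
      if (ss[best] < cur_ss - 1e-10 * max(cur_ss, 1)) {
        csum <- csum - profiles[idx[s], ] + profiles[best, ]
        idx[s] <- best
        cur_ss <- ss[best]
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  idx
}

#' Exhaustive best sub-ensemble (small problems only)
#'
#' Enumerates every multiset of \code{size} conformers and returns the
#' minimum chi2; the brute-force reference the genetic algorithm is checked
#' against.
#'
#' @param exp experimental profile.
#' @param profiles pool profile matrix.
#' @param size ensemble size.
#' @param fit_background default TRUE.
#' @return list(chi2, indices).
#' @export
exhaustive_select <- function(exp, profiles, size = 2L,
                              fit_background = TRUE) {
  n <- nrow(profiles)
  stopifnot(choose(n + size - 1, size) <= 1e5)
  best <- list(chi2 = Inf, indices = NULL)
  combos <- utils::combn(n + size - 1L, size)  # multisets via stars and bars
  for (j in seq_len(ncol(combos))) {
    idx <- combos[, j] - seq_len(size) + 1L
    M <- colMeans(profiles[idx, , drop = FALSE])
    chi2 <- tryCatch(chi2_fit(exp, M, fit_background)$chi2,
                     error = function(e) Inf)
    if (chi2 < best$chi2) best <- list(chi2 = chi2, indices = idx)
  }
  best
}
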