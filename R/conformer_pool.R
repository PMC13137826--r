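#' Chain-geometry settings for the coarse-grained walk
#'
#' Virtual C-alpha bond length, pseudo-bond-angle range (degrees), hard-sphere
#' excluded-volume cutoff between non-adjacent residues, and retry/restart
#' budgets for the self-avoiding walk.
#'
#' @param bond virtual bond length, A; default 3.8.
#' @param angle_range pseudo-bond-angle range in degrees; default c(65, 145).
#' @param ev_cutoff excluded-volume cutoff, A; default 3.8.
#' @param max_retries placement retries per residue; default 50.
#' @param max_restarts whole-chain restarts; default 100.
#' @export
chain_geometry <- function(bond = 3.8, angle_range = c(65, 145),
                           ev_cutoff = 3.8, max_retries = 50L,
                           max_restarts = 100L) {
  stopifnot(bond > 0, length(angle_range) == 2L,
            angle_range[1] > 0, angle_range[2] <= 180,
            angle_range[1] <= angle_range[2], ev_cutoff >= 0)
  list(bond = bond, angle_range = as.numeric(angle_range),
       ev_cutoff = ev_cutoff, max_retries = as.integer(max_retries),
       max_restarts = as.integer(max_restarts))
}

#' Generate one self-avoiding C-alpha chain
#'
#' Builds the chain residue by residue: fixed virtual bond, pseudo-bond angle
#' uniform in the configured range, dihedral uniform on [-180, 180).
#' Placements violating the excluded-volume cutoff are retried; a chain that
#' exhausts its retries is restarted. Deterministic for a given seed.
#'
#' @param n_res number of residues, >= 3; default 140 (alpha-synuclein).
#' @param seed integer seed; if NULL the current RNG state is used.
#' @param geometry a \code{\link{chain_geometry}}.
#' @param id integer id stored on the conformer.
#' @return object of class \code{conformer}: \code{coords} (n_res x 3),
#'   \code{n_res}, \code{id}.
#' @export
generate_chain <- function(n_res = 140L, seed = NULL,
                           geometry = chain_geometry(), id = 1L) {
  stopifnot(n_res >= 3L)
  if (!is.null(seed)) set.seed(seed)
  deg2rad <- pi / 180
  coords <- cpp_generate_chain(as.integer(n_res), geometry$bond,
                               geometry$angle_range[1] * deg2rad,
                               geometry$angle_range[2] * deg2rad,
                               geometry$ev_cutoff, geometry$max_retries,
                               geometry$max_restarts)
  structure(list(coords = coords, n_res = as.integer(n_res),
                 id = as.integer(id)),
            class = "conformer")
}

#' Domain-distance scheme for alpha-synuclein
#'
#' Named 1-based residue pairs: end-to-end (1-140), within the N-terminal
#' domain (1-60), within the NAC region (61-90), within the C-terminal
#' domain (91-140), NTD to NAC (1-90), and NAC to CTD (61-140). The pairs
#' are configurable because the NAC boundary differs between conventions.
#'
#' @param pairs named list of length-2 integer vectors overriding defaults.
#' @param n_res chain length; boundaries are rescaled proportionally when
#'   it differs from the canonical 140.
#' @export
domain_scheme <- function(pairs = NULL, n_res = 140L) {
  default <- list(ree = c(1L, 140L), ntd_internal = c(1L, 60L),
                  nac_internal = c(61L, 90L), ctd_internal = c(91L, 140L),
                  ntd_nac = c(1L, 90L), nac_ctd = c(61L, 140L))
  if (n_res != 140L)
    default <- lapply(default, function(p)
      pmin(as.integer(n_res), pmax(1L, as.integer(round(p * n_res / 140)))))
  if (!is.null(pairs)) default[names(pairs)] <- pairs
  default
}

#' Per-conformer geometry metrics
#'
#' Radius of gyration (unit residue masses), end-to-end distance, and the
#' scheme's domain C-alpha to C-alpha distances.
#'
#' @param conformer a \code{\link{generate_chain}} result.
#' @param scheme a \code{\link{domain_scheme}}.
#' @return one-row data.frame: \code{id}, \code{rg}, plus one column per
#'   scheme pair (\code{ree} first).
#' @export
chain_metrics <- function(conformer, scheme = domain_scheme()) {
  x <- conformer$coords
  n <- nrow(x)
  for (p in scheme)
    if (any(p < 1L | p > n)) stop("scheme indices outside [1, n_res]")
  com <- colMeans(x)
  rg <- sqrt(mean(rowSums((x - matrix(com, n, 3, byrow = TRUE))^2)))
  d <- vapply(scheme, function(p) sqrt(sum((x[p[1], ] - x[p[2], ])^2)), 1.0)
  cbind(data.frame(id = conformer$id, rg = rg), as.data.frame(as.list(d)))
}

default_stiffness_mix <- function() {
  list(
    flexible     = list(angle_range = c(65, 145), weight = 0.5),
    intermediate = list(angle_range = c(90, 150), weight = 0.3),
    stiff        = list(angle_range = c(120, 165), weight = 0.2)
  )
}

#' Generate a pool of self-avoiding conformers
#'
#' Chains are drawn from a mixture of stiffness regimes (pseudo-bond-angle
#' ranges) so that a single pool spans compact (Rg below 25 A) through
#' highly extended (above 55 A) conformations of a 140-residue chain, the
#' coverage the downstream ensemble selection needs. Reproducible from
#' (seed, settings).
#'
#' @param n number of conformers, >= 10.
#' @param n_res residues per chain; default 140.
#' @param seed integer seed.
#' @param stiffness_mix named list of regimes, each with
#'   \code{angle_range} (degrees) and \code{weight}; weights are normalized.
#' @param geometry base \code{\link{chain_geometry}} (angle range is
#'   overridden per regime).
#' @param scheme \code{\link{domain_scheme}} used for the metrics table.
#' @return object of class \code{conformer_pool}: \code{conformers} (list),
#'   \code{metrics} (data.frame with rg, ree, domain distances, regime),
#'   \code{seed}, \code{settings}.
#' @export
generate_pool <- function(n, n_res = 140L, seed = 1L,
                          stiffness_mix = default_stiffness_mix(),
                          geometry = chain_geometry(),
                          scheme = NULL) {
  stopifnot(n >= 10L)
  if (is.null(scheme)) scheme <- domain_scheme(n_res = n_res)
  set.seed(seed)
  w <- vapply(stiffness_mix, function(r) r$weight, 1.0)
  regime <- sample(names(stiffness_mix), n, replace = TRUE, prob = w / sum(w))
  geoms <- lapply(stiffness_mix, function(r) {
    g <- geometry; g$angle_range <- as.numeric(r$angle_range); g
  })
  conformers <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    conformers[[i]] <- generate_chain(n_res, seed = NULL,
                                      geometry = geoms[[regime[i]]], id = i)
    rows[[i]] <- chain_metrics(conformers[[i]], scheme)
  }
  metrics <- do.call(rbind, rows)
  metrics$regime <- regime
  structure(list(conformers = conformers, metrics = metrics,
                 seed = as.integer(seed),
                 settings = list(n_res = as.integer(n_res),
                                 stiffness_mix = stiffness_mix,
                                 geometry = geometry, scheme = scheme)),
            class = "conformer_pool")
}

#' @export
print.conformer_pool <- function(x, ...) {
  cat(sprintf("<conformer_pool> %d chains of %d residues (seed %d); Rg in [%.1f, %.1f] A\n",
              length(x$conformers), x$settings$n_res, x$seed,
              min(x$metrics$rg), max(x$metrics$rg)))
  invisible(x)
}

#' @export
length.conformer_pool <- function(x) length(x$conformers)

#' Write a pool as a multi-model C-alpha PDB file
#'
#' One MODEL/ENDMDL block per conformer, CA-only ATOM records with 1-based
#' residue numbering.
#'
#' @param pool a \code{conformer_pool} (or list of conformers).
#' @param path output path.
#' @export
write_pool_pdb <- function(pool, path) {
  conformers <- if (inherits(pool, "conformer_pool")) pool$conformers else pool
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(conformers)) {
    x <- conformers[[m]]$coords
    writeLines(sprintf("MODEL     %4d", m), con)
    writeLines(sprintf(
      "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(nrow(x)), seq_len(nrow(x)), x[, 1], x[, 2], x[, 3]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read C-alpha coordinates from a PDB-format file
#'
#' Returns one conformer per MODEL block (or a single conformer for a
#' model-less file), keeping CA atoms only.
#'
#' @param path PDB file path.
#' @return list of \code{conformer} objects.
#' @export
read_calpha_pdb <- function(path) {
  if (requireNamespace("bio3d", quietly = TRUE)) {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    sel <- bio3d::atom.select(pdb, elety = "CA", verbose = FALSE)
    xyz <- pdb$xyz[, sel$xyz, drop = FALSE]
    return(lapply(seq_len(nrow(xyz)), function(i) {
      coords <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)
      structure(list(coords = coords, n_res = nrow(coords), id = i),
                class = "conformer")
    }))
  }
  lines <- readLines(path, warn = FALSE)
  models <- list()
  cur <- list()
  flush_model <- function(cur, models) {
    if (length(cur) == 0L) return(models)
    coords <- do.call(rbind, cur)
    c(models, list(coords))
  }
  for (ln in lines) {
    tag <- substr(ln, 1, 6)
    if (tag == "ENDMDL") { models <- flush_model(cur, models); cur <- list() }
    else if (startsWith(ln, "ATOM") &&
             trimws(substr(ln, 13, 16)) == "CA") {
      cur[[length(cur) + 1L]] <- as.numeric(c(substr(ln, 31, 38),
                                              substr(ln, 39, 46),
                                              substr(ln, 47, 54)))
    }
  }
  models <- flush_model(cur, models)
  if (length(models) == 0L) stop("no CA atoms found in ", path)
  lapply(seq_along(models), function(i)
    structure(list(coords = models[[i]], n_res = nrow(models[[i]]),
                   id = i), class = "conformer"))
}
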