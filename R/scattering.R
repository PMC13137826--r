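#' Residue form-factor model
#'
#' \code{"point"} (f = 1; the overall scale is fitted downstream, so a
#' constant prefactor is unidentifiable) or \code{"gaussian-dummy"}
#' (\eqn{f(q) = e^{-q^2 w^2 / 2}}) mimicking the excluded-volume falloff of
#' a dummy residue.
#'
#' @param kind \code{"point"} or \code{"gaussian-dummy"}.
#' @param width Gaussian width w in A (gaussian-dummy only), default 3.
#' @export
form_factor <- function(kind = c("point", "gaussian-dummy"), width = 3.0) {
  kind <- match.arg(kind)
  stopifnot(width > 0)
  structure(list(kind = kind, width = width), class = "form_factor")
}

ff_eval <- function(ff, q) {
  if (ff$kind == "point") rep(1.0, length(q))
  else exp(-q^2 * ff$width^2 / 2)
}

#' Default working q grid
#'
#' 101 points on [0.005, 0.5] 1/A, covering the Guinier low-q region and
#' the fractal-dimension window (0.04 to 0.1 1/A).
#' @export
default_q_grid <- function() seq(0.005, 0.5, length.out = 101L)

#' Theoretical SAXS profile of a conformer by the Debye formula
#'
#' Exact: \eqn{I(q) = f(q)^2 [N + 2\sum_{i<j} \mathrm{sinc}(q r_{ij})]}.
#' Histogram: pair distances are binned at \code{bin_width} and the sum
#' taken over bin centers, O(N^2 + B n_q) instead of O(N^2 n_q). The q = 0
#' limit uses sinc(0) = 1, so I(0) = N^2 for point form factors.
#'
#' @param conformer a \code{conformer}.
#' @param q_grid momentum-transfer grid, 1/A.
#' @param ff a \code{\link{form_factor}}.
#' @param method \code{"exact"} or \code{"histogram"}.
#' @param bin_width histogram bin width, A; default 0.5.
#' @return a theoretical \code{\link{scattering_profile}} (sigma = 0).
#' @export
debye_profile <- function(conformer, q_grid = default_q_grid(),
                          ff = form_factor(), method = c("exact", "histogram"),
                          bin_width = 0.5) {
  method <- match.arg(method)
  I <- debye_intensity(conformer$coords, q_grid, method, bin_width)
  I <- I * ff_eval(ff, q_grid)^2
  scattering_profile(q_grid, I, rep(0, length(q_grid)),
                     label = sprintf("conformer %d", conformer$id),
                     theoretical = TRUE)
}

debye_intensity <- function(coords, q_grid, method, bin_width = 0.5) {
  if (method == "exact") {
    cpp_debye_exact(coords, q_grid)
  } else {
    n <- nrow(coords)
    span <- sqrt(max(rowSums(coords^2))) * 2 + 10
    n_bins <- max(1L, ceiling(span / bin_width))
    H <- cpp_pair_hist(coords, bin_width, n_bins)
    cpp_debye_hist(H, n, q_grid)
  }
}

#' Theoretical profiles for every conformer in a pool
#'
#' Rows follow pool order. The histogram path is used automatically for
#' pools of 1000 or more conformers.
#'
#' @param pool a \code{conformer_pool}.
#' @param q_grid momentum-transfer grid.
#' @param ff a \code{\link{form_factor}}.
#' @param method \code{"auto"}, \code{"exact"} or \code{"histogram"}.
#' @param bin_width histogram bin width, A.
#' @return numeric matrix, n_conformers x n_q.
#' @export
pool_profiles <- function(pool, q_grid = default_q_grid(),
                          ff = form_factor(),
                          method = c("auto", "exact", "histogram"),
                          bin_width = 0.5) {
  method <- match.arg(method)
  if (method == "auto")
    method <- if (length(pool) >= 1000L) "histogram" else "exact"
  f2 <- ff_eval(ff, q_grid)^2
  out <- matrix(NA_real_, length(pool), length(q_grid))
  for (i in seq_along(pool$conformers))
    out[i, ] <- debye_intensity(pool$conformers[[i]]$coords, q_grid,
                                method, bin_width) * f2
  out
}
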