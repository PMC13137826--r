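# Forward operator: I(q_k) = 4*pi * sum_j w_j dr p(r_j) sinc(q_k r_j)
# (trapezoid weights; endpoint p pinned to zero so only interior columns used)
pddf_design <- function(q, r) {
  dr <- r[2] - r[1]
  w <- rep(1, length(r)); w[c(1, length(r))] <- 0.5
  qr <- outer(q, r)
  S <- ifelse(abs(qr) < 1e-10, 1, sin(qr) / pmax(qr, 1e-300))
  S[abs(qr) < 1e-10] <- 1
  sweep(4 * pi * dr * S, 2L, w, `*`)
}

second_diff_matrix <- function(n) {
  # second differences of the interior unknowns, with zero boundary values
  D <- matrix(0, n, n)
  for (j in seq_len(n)) {
    D[j, j] <- -2
    if (j > 1) D[j, j - 1] <- 1
    if (j < n) D[j, j + 1] <- 1
  }
  D
}

# Lawson-Hanson active-set nonnegative least squares. Written in-house
# because the problem can be badly scaled (weights spanning many orders of
# magnitude near intensity minima) and needs a generous iteration budget.
# Matrix-free in the number of columns: the Gram matrix is only formed on
# the (small) passive set, so very wide systems are fine.
nnls_solve <- function(M, b, maxit = NULL) {
  n <- ncol(M)
  if (is.null(maxit)) maxit <- max(300L * min(n, nrow(M)), 1000L)
  x <- numeric(n)
  passive <- logical(n)
  w <- as.numeric(crossprod(M, b))
  tol <- 1e3 * .Machine$double.eps * max(abs(w), 1e-300)
  it <- 0L
  while (any(!passive) && max(w[!passive]) > tol) {
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      it <- it + 1L
      if (it > maxit) stop("nnls: iteration budget exhausted")
      Mp <- M[, passive, drop = FALSE]
      s <- numeric(n)
      s[passive] <- qr.solve(crossprod(Mp), crossprod(Mp, b))
      if (all(s[passive] > 0)) { x <- s; break }
      neg <- passive & s <= 0
      a <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + a * (s - x)
      passive <- passive & x > tol
      x[!passive] <- 0
    }
    w <- as.numeric(crossprod(M, b - M %*% x))
  }
  as.numeric(x)
}

solve_pddf <- function(Aw, bw, D2, alpha, nonneg) {
  M <- rbind(Aw, sqrt(alpha) * D2)
  rhs <- c(bw, rep(0, nrow(D2)))
  if (nonneg) {
    nnls_solve(M, rhs)
  } else {
    stats::lm.fit(M, rhs)$coefficients
  }
}

#' Regularized indirect Fourier transform to p(r)
#'
#' Estimates the pair-distance distribution function p(r) on a uniform grid
#' \code{[0, dmax]} by Tikhonov-regularized, optionally nonnegative least
#' squares: minimize
#' \eqn{\sum_k [(I_k - (Ap)_k)/\sigma_k]^2 + \alpha \|D_2 p\|^2}
#' where A is the spherically averaged Fourier kernel
#' \eqn{(Ap)(q) = 4\pi \int p(r)\,\mathrm{sinc}(qr)\,dr} and \eqn{D_2} the
#' second-difference (curvature) operator; p is pinned to zero at both
#' endpoints. \code{alpha = "auto"} picks the corner of the L-curve
#' (maximum discrete curvature) over a log-spaced scan.
#'
#' @param profile a \code{\link{scattering_profile}} with at least 30 points.
#' @param dmax maximum intramolecular distance, A.
#' @param alpha regularization weight (> 0) or \code{"auto"}.
#' @param n_r number of r-grid points, default 101.
#' @param nonneg enforce p(r) >= 0 (default TRUE; a single scattering
#'   density has nonnegative p).
#' @return object of class \code{pddf_result}: \code{r}, \code{p},
#'   \code{dmax}, \code{alpha}, \code{rg_real}, \code{i0_real}, \code{chi2}
#'   (reduced, dof = n_q), \code{fitted} (model curve on the data grid).
#' @export
fit_pddf <- function(profile, dmax, alpha = "auto", n_r = 101L,
                     nonneg = TRUE) {
  stopifnot(inherits(profile, "scattering_profile"), dmax > 0, n_r >= 51L)
  if (length(profile$q) < 30L)
    stop("fit_pddf needs at least 30 data points")
  q <- profile$q; I <- profile$intensity
  s <- profile$sigma
  if (all(s == 0)) s <- pmax(abs(I) * 1e-3, 1e-12)
  r <- seq(0, dmax, length.out = n_r)
  A <- pddf_design(q, r)
  Ai <- A[, 2:(n_r - 1L), drop = FALSE]   # interior unknowns only
  Aw <- Ai / s
  bw <- I / s
  D2 <- second_diff_matrix(n_r - 2L)
  if (identical(alpha, "auto")) {
    # scale candidates to the problem: balance data and smoothness terms
    a0 <- sum(Aw^2) / max(sum(D2^2), 1)
    alphas <- a0 * 10^seq(-6, 2, length.out = 15L)
    resn <- smon <- numeric(length(alphas))
    sols <- vector("list", length(alphas))
    for (i in seq_along(alphas)) {
      p <- tryCatch(solve_pddf(Aw, bw, D2, alphas[i], nonneg),
                    error = function(e) NULL)
      if (is.null(p)) { resn[i] <- NA; next }
      sols[[i]] <- p
      resn[i] <- sqrt(sum((Aw %*% p - bw)^2))
      smon[i] <- sqrt(sum((D2 %*% p)^2))
    }
    ok <- which(is.finite(resn) & smon > 0)
    if (length(ok) < 3L)
      stop("regularization error: L-curve scan failed; try a larger alpha")
    lx <- log(resn[ok]); ly <- log(smon[ok])
    # discrete Menger curvature along the L-curve; corner = max curvature
    curv <- rep(-Inf, length(ok))
    for (i in 2:(length(ok) - 1L)) {
      a <- c(lx[i - 1], ly[i - 1]); b <- c(lx[i], ly[i]); cc <- c(lx[i + 1], ly[i + 1])
      ab <- sqrt(sum((a - b)^2)); bc <- sqrt(sum((b - cc)^2)); ca <- sqrt(sum((cc - a)^2))
      ar <- abs((b[1] - a[1]) * (cc[2] - a[2]) - (cc[1] - a[1]) * (b[2] - a[2])) / 2
      if (ab * bc * ca > 0) curv[i] <- 4 * ar / (ab * bc * ca)
    }
    pick <- ok[which.max(curv)]
    alpha <- alphas[pick]
    p_int <- sols[[pick]]
  } else {
    stopifnot(is.numeric(alpha), alpha > 0)
    p_int <- tryCatch(solve_pddf(Aw, bw, D2, alpha, nonneg),
                      error = function(e)
                        stop("regularization error: ill-conditioned system; ",
                             "try a larger alpha"))
  }
  p <- c(0, p_int, 0)
  fitted <- as.numeric(A %*% p)
  chi2 <- sum(((I - fitted) / s)^2) / length(q)
  res <- structure(list(r = r, p = p, dmax = dmax, alpha = alpha,
                        chi2 = chi2, fitted = fitted,
                        q = q, nonneg = nonneg),
                   class = "pddf_result")
  mom <- real_space_moments(res)
  res$rg_real <- mom[["rg_real"]]
  res$i0_real <- mom[["i0_real"]]
  res
}

#' @export
print.pddf_result <- function(x, ...) {
  cat(sprintf("<pddf_result> Dmax = %.1f A, Rg = %.2f A, I(0) = %.4g, alpha = %.3g, chi2 = %.3g\n",
              x$dmax, x$rg_real, x$i0_real, x$alpha, x$chi2))
  invisible(x)
}

#' Real-space moments of a p(r) distribution
#'
#' \eqn{R_g^2 = \int r^2 p\,dr / (2\int p\,dr)} and
#' \eqn{I(0) = 4\pi\int p\,dr}, by trapezoidal quadrature on the stored grid.
#'
#' @param res a \code{pddf_result}, or a list with elements \code{r}, \code{p}.
#' @return named numeric vector \code{c(rg_real =, i0_real =)}.
#' @export
real_space_moments <- function(res) {
  r <- res$r; p <- res$p
  m0 <- pracma::trapz(r, p)
  if (m0 <= 0) stop("degenerate-distribution error: integral of p(r) <= 0")
  m2 <- pracma::trapz(r, r^2 * p)
  c(rg_real = sqrt(m2 / (2 * m0)), i0_real = 4 * pi * m0)
}

# sign changes of p' beyond the main peak: a ringing score
oscillation_score <- function(res) {
  p <- res$p
  peak <- which.max(p)
  if (peak >= length(p) - 2L) return(0L)
  dp <- diff(p[peak:length(p)])
  sg <- sign(dp[dp != 0])
  if (length(sg) < 2L) return(0L)
  sum(diff(sg) != 0)
}

#' Scan candidate Dmax values
#'
#' Fits \code{\link{fit_pddf}} at each candidate and scores
#' \code{chi2 + osc_weight * oscillations}, where oscillations counts sign
#' changes of p'(r) beyond the main peak (ringing from an over- or
#' under-estimated Dmax). The full table is returned for audit.
#'
#' @param profile a \code{\link{scattering_profile}}.
#' @param dmax_grid numeric vector of candidate Dmax values, A.
#' @param osc_weight penalty per extra oscillation, default 0.1.
#' @param ... passed to \code{\link{fit_pddf}}.
#' @return list with \code{best_dmax}, \code{table} (dmax, chi2,
#'   oscillations, score), and \code{best_fit}.
#' @export
scan_dmax <- function(profile, dmax_grid, osc_weight = 0.1, ...) {
  stopifnot(length(dmax_grid) >= 1L)
  fits <- vector("list", length(dmax_grid))
  rows <- vector("list", length(dmax_grid))
  last_err <- NULL
  for (i in seq_along(dmax_grid)) {
    f <- tryCatch(fit_pddf(profile, dmax_grid[i], ...),
                  error = function(e) { last_err <<- e; NULL })
    fits[[i]] <- f
    if (!is.null(f))
      rows[[i]] <- data.frame(dmax = dmax_grid[i], chi2 = f$chi2,
                              oscillations = oscillation_score(f))
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab)) stop(last_err)
  tab$score <- tab$chi2 + osc_weight * tab$oscillations
  best <- tab$dmax[which.min(tab$score)]
  list(best_dmax = best, table = tab,
       best_fit = fits[[match(best, dmax_grid)]])
}

#' Write a plain-text p(r) report
#'
#' A GNOM-inspired report: a data-fit block (q, I, sigma, fitted), a p(r)
#' block, and a summary of Rg, I(0), Dmax, alpha and chi2.
#'
#' @param res a \code{pddf_result}.
#' @param path output path.
#' @export
write_pddf_report <- function(res, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# indirect Fourier transform report",
    sprintf("# Dmax   : %.3f A", res$dmax),
    sprintf("# alpha  : %.6g", res$alpha),
    sprintf("# Rg     : %.4f A (real space)", res$rg_real),
    sprintf("# I(0)   : %.6g (real space)", res$i0_real),
    sprintf("# chi2   : %.6g", res$chi2),
    "", "# data fit block: q I_fit"), con)
  writeLines(sprintf("%.8g %.8g", res$q, res$fitted), con)
  writeLines(c("", "# p(r) block: r p"), con)
  writeLines(sprintf("%.8g %.8g", res$r, res$p), con)
  invisible(path)
}
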