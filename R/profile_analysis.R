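#' Gaussian-chain (Debye) form factor
#'
#' \eqn{P(x) = 2(e^{-x} - 1 + x)/x^2} with \eqn{x = (qR_g)^2}; the classic
#' scattering function of an ideal polymer chain, used both as the
#' polymer-corrected Rg estimator and as a test oracle.
#'
#' @param x numeric, \eqn{(q R_g)^2} (or its Flory-generalized analogue).
#' @return P(x) with P(0) = 1.
#' @export
debye_chain <- function(x) {
  p <- ifelse(x < 1e-6, 1 - x / 3 + x^2 / 12,
              2 * (exp(-x) - 1 + x) / x^2)
  as.numeric(p)
}

#' Closed-form sphere scattering intensity
#'
#' Normalized form factor of a homogeneous sphere of radius \code{radius};
#' I(0) = i0. Used as the globular reference shape.
#'
#' @param q momentum transfer, 1/A.
#' @param radius sphere radius, A.
#' @param i0 forward intensity.
#' @export
sphere_intensity <- function(q, radius, i0 = 1.0) {
  x <- q * radius
  amp <- ifelse(abs(x) < 1e-8, 1.0, 3 * (sin(x) - x * cos(x)) / x^3)
  i0 * amp^2
}

#' Guinier fit of the low-q region
#'
#' Iterative sigma-weighted linear fit of \eqn{\ln I = \ln I_0 - q^2 R_g^2/3}
#' on the largest low-q window satisfying \eqn{q_{max} R_g \le} \code{qrg_limit}.
#' The window is shrunk from above until the fitted Rg and the window are
#' self-consistent.
#'
#' @param profile a \code{\link{scattering_profile}}.
#' @param qrg_limit Guinier validity limit on \eqn{q_{max} R_g}; default 1.1
#'   (between the globular 1.3 convention and strict IDP practice of 1.0).
#' @param min_points minimum number of points in the window, default 5.
#' @return object of class \code{guinier_fit}: \code{rg}, \code{i0},
#'   \code{q_window}, \code{qmax_rg}, \code{r2}, \code{n_points},
#'   \code{degenerate} flag.
#' @export
guinier_fit <- function(profile, qrg_limit = 1.1, min_points = 5L) {
  stopifnot(inherits(profile, "scattering_profile"))
  pos <- profile$intensity > 0
  q <- profile$q[pos]; I <- profile$intensity[pos]
  s <- profile$sigma[pos]
  if (all(s == 0)) s <- rep(1, length(q))  # theoretical curve: equal weights
  if (length(q) < min_points)
    stop("guinier-failure error: fewer than min_points positive intensities")
  y <- log(I); x <- q^2
  w <- (I / s)^2                      # var(ln I) = (sigma/I)^2
  fit_window <- function(m) {
    xi <- x[1:m]; yi <- y[1:m]; wi <- w[1:m]
    fit <- stats::lm.wfit(cbind(1, xi), yi, wi)
    b <- fit$coefficients
    b <- unname(b)
    list(i0 = exp(b[1]),
         rg = if (b[2] < 0) sqrt(-3 * b[2]) else 0,
         slope = b[2], fit = fit, m = m)
  }
  m <- length(q)
  last <- NULL
  for (iter in 1:50) {
    res <- fit_window(m)
    if (res$rg <= 0) { last <- res; break }
    m_new <- max(min_points, sum(q * res$rg <= qrg_limit))
    last <- res
    if (m_new == m) break
    m <- m_new
  }
  res <- last
  degenerate <- res$rg < 1
  yi <- y[1:res$m]; wi <- w[1:res$m]
  fitted <- cbind(1, x[1:res$m]) %*% res$fit$coefficients
  ss_res <- sum(wi * (yi - fitted)^2)
  ss_tot <- sum(wi * (yi - stats::weighted.mean(yi, wi))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  if (!degenerate && q[res$m] * res$rg > qrg_limit * 1.5)
    stop(sprintf(
      "guinier-failure error: no self-consistent window (last: %d pts, qmax*Rg = %.2f)",
      res$m, q[res$m] * res$rg))
  structure(list(rg = res$rg, i0 = unname(res$i0),
                 q_window = c(q[1], q[res$m]),
                 qmax_rg = q[res$m] * res$rg,
                 r2 = r2, n_points = res$m,
                 degenerate = degenerate),
            class = "guinier_fit")
}

#' @export
print.guinier_fit <- function(x, ...) {
  cat(sprintf("<guinier_fit> Rg = %.2f A, I(0) = %.4g, qmax*Rg = %.2f, %d pts, R2 = %.4f%s\n",
              x$rg, x$i0, x$qmax_rg, x$n_points, x$r2,
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

#' Polymer-corrected Rg for disordered chains
#'
#' Fits the Gaussian-chain (Debye) form factor
#' \eqn{I(q) = I_0 P((qR_g)^{1/\nu})} over the extended window
#' \eqn{q R_g \le} \code{fit_qrg_max}, which a plain Guinier fit cannot use.
#' With \code{fit_nu = TRUE} the Flory exponent is fitted too (heuristic
#' generalization \eqn{x = (qR_g)^{1/\nu}}, reducing to the ideal chain at
#' \eqn{\nu = 1/2}). A reduced chi-square above 5 flags a shape (e.g.
#' globular) outside the model class.
#'
#' @param profile a \code{\link{scattering_profile}}.
#' @param fit_qrg_max window limit on \eqn{q R_g}; default 3.
#' @param fit_nu fit the Flory exponent; default FALSE (nu = 1/2).
#' @return object of class \code{guinier_fit} with extra fields \code{nu},
#'   \code{chi2_reduced} and \code{poor_fit}.
#' @export
idp_rg <- function(profile, fit_qrg_max = 3.0, fit_nu = FALSE) {
  stopifnot(inherits(profile, "scattering_profile"))
  g0 <- tryCatch(guinier_fit(profile), error = function(e) NULL)
  rg0 <- if (!is.null(g0) && g0$rg > 1) g0$rg else 30
  i00 <- if (!is.null(g0)) g0$i0 else max(profile$intensity)
  q <- profile$q; I <- profile$intensity; s <- profile$sigma
  if (all(s == 0)) s <- pmax(abs(I) * 1e-4, 1e-12)
  rg <- rg0
  fit <- NULL
  for (iter in 1:3) {
    keep <- q * rg <= fit_qrg_max & I > 0
    if (sum(keep) < 8) keep <- seq_len(min(length(q), 20))
    df <- data.frame(q = q[keep], I = I[keep], s = s[keep])
    fit <- tryCatch({
      if (fit_nu) {
        minpack.lm::nlsLM(
          I ~ i0 * debye_chain((q * rg)^(1 / nu)),
          data = df, weights = 1 / df$s^2,
          start = list(i0 = i00, rg = rg, nu = 0.5),
          lower = c(1e-12, 1, 0.3), upper = c(Inf, 500, 1.0),
          control = minpack.lm::nls.lm.control(maxiter = 200))
      } else {
        minpack.lm::nlsLM(
          I ~ i0 * debye_chain((q * rg)^2),
          data = df, weights = 1 / df$s^2,
          start = list(i0 = i00, rg = rg),
          lower = c(1e-12, 1), upper = c(Inf, 500),
          control = minpack.lm::nls.lm.control(maxiter = 200))
      }
    }, error = function(e)
      stop("idp-fit error: nonlinear fit failed: ", conditionMessage(e)))
    cf <- stats::coef(fit)
    if (abs(cf[["rg"]] - rg) < 1e-3 * rg) { rg <- cf[["rg"]]; break }
    rg <- cf[["rg"]]
  }
  cf <- stats::coef(fit)
  resid <- (df$I - stats::predict(fit)) / df$s
  npar <- length(cf)
  chi2r <- sum(resid^2) / max(1L, nrow(df) - npar)
  structure(list(rg = unname(cf[["rg"]]), i0 = unname(cf[["i0"]]),
                 nu = if (fit_nu) unname(cf[["nu"]]) else 0.5,
                 q_window = range(df$q),
                 qmax_rg = max(df$q) * cf[["rg"]],
                 r2 = NA_real_, n_points = nrow(df),
                 chi2_reduced = chi2r, poor_fit = chi2r > 5,
                 degenerate = FALSE),
            class = "guinier_fit")
}

#' Kratky transform
#'
#' Pointwise \eqn{(q, q^2 I(q))} with propagated uncertainty
#' \eqn{q^2 \sigma}; no smoothing. For an ideal chain the transform
#' plateaus at \eqn{2 I_0 / R_g^2}; globular shapes peak and decay.
#'
#' @param profile a \code{\link{scattering_profile}}.
#' @return data.frame with columns \code{q}, \code{qsq_i}, \code{sigma}.
#' @export
kratky <- function(profile) {
  stopifnot(inherits(profile, "scattering_profile"))
  data.frame(q = profile$q,
             qsq_i = profile$q^2 * profile$intensity,
             sigma = profile$q^2 * profile$sigma)
}

#' Mass fractal dimension from the power-law regime
#'
#' Ordinary (unweighted) least squares of \eqn{\log_{10} I} on
#' \eqn{\log_{10} q} over the intermediate-q window, where
#' \eqn{I(q) \sim q^{-D_m}}; \eqn{D_m} is minus the slope. Points with
#' \eqn{I \le 0} are excluded before fitting. Dm is about 2 for ideal
#' chains, approaches 4 for compact globules, and falls below 2 for
#' swollen/extended chains.
#'
#' @param profile a \code{\link{scattering_profile}}.
#' @param log_window window in \eqn{\log_{10} q} (q in 1/A); default
#'   \code{c(-1.4, -1.0)}, i.e. q in [0.0398, 0.1] 1/A.
#' @param weighted use sigma weighting instead of OLS; default FALSE.
#' @return object of class \code{fractal_fit}: \code{dm}, \code{dm_se},
#'   \code{log_window}, \code{n_points}.
#' @export
fractal_fit <- function(profile, log_window = c(-1.4, -1.0),
                        weighted = FALSE) {
  stopifnot(inherits(profile, "scattering_profile"),
            length(log_window) == 2L, log_window[1] < log_window[2])
  lq <- log10(profile$q)
  inside <- lq >= log_window[1] & lq <= log_window[2]
  usable <- inside & profile$intensity > 0
  if (sum(usable) < 5L)
    stop(sprintf(
      "window error: only %d usable points (I > 0) in log10(q) window [%.2f, %.2f]",
      sum(usable), log_window[1], log_window[2]))
  x <- lq[usable]; y <- log10(profile$intensity[usable])
  if (weighted) {
    w <- (profile$intensity[usable] / profile$sigma[usable])^2
    fit <- stats::lm(y ~ x, weights = w)
  } else {
    fit <- stats::lm(y ~ x)
  }
  sm <- suppressWarnings(summary(fit))$coefficients
  structure(list(dm = -unname(sm["x", "Estimate"]),
                 dm_se = unname(sm["x", "Std. Error"]),
                 log_window = log_window,
                 n_points = sum(usable)),
            class = "fractal_fit")
}

#' @export
print.fractal_fit <- function(x, ...) {
  cat(sprintf("<fractal_fit> Dm = %.3f +/- %.3f (%d pts, log10 q in [%.2f, %.2f])\n",
              x$dm, x$dm_se, x$n_points, x$log_window[1], x$log_window[2]))
  invisible(x)
}

#' Normalized forward-intensity trace across a time series
#'
#' I(0) is proportional to protein concentration, so its decay tracks the
#' dilution of the protein stream by the flanking buffer streams.
#'
#' @param series a \code{\link{time_series}}.
#' @param mode \code{"guinier-i0"} (I0 from the Guinier fit) or
#'   \code{"lowq-mean"} (mean of the 5 lowest-q intensities).
#' @return data.frame with columns \code{time}, \code{i0}, \code{i0_norm};
#'   attribute \code{monotone_decay} is TRUE when the trace never rises by
#'   more than its propagated noise.
#' @export
forward_intensity_trace <- function(series,
                                    mode = c("guinier-i0", "lowq-mean")) {
  stopifnot(inherits(series, "saxs_timeseries"), length(series) >= 2L)
  mode <- match.arg(mode)
  i0 <- vapply(seq_along(series$profiles), function(i) {
    p <- series$profiles[[i]]
    if (mode == "guinier-i0") {
      tryCatch(guinier_fit(p)$i0,
               error = function(e)
                 stop(sprintf("guinier-failure at time index %d: %s",
                              i, conditionMessage(e))))
    } else {
      mean(p$intensity[seq_len(min(5L, length(p$q)))])
    }
  }, 1.0)
  out <- data.frame(time = series$times, i0 = i0, i0_norm = i0 / i0[1])
  noise <- stats::sd(diff(out$i0_norm)) / sqrt(2)
  attr(out, "monotone_decay") <-
    all(diff(out$i0_norm) <= 3 * max(noise, 1e-12))
  out
}
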