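#' Construct a scattering profile
#'
#' A \code{scattering_profile} holds a 1-D reduced SAXS curve: momentum
#' transfer \code{q} (\eqn{\AA^{-1}}, strictly increasing), intensity
#' (arbitrary units) and 1-sigma uncertainties.
#'
#' @param q numeric vector of momentum transfer values, strictly increasing,
#'   all positive, in \eqn{\AA^{-1}}.
#' @param intensity numeric vector, same length as \code{q}.
#' @param sigma numeric vector of 1-sigma uncertainties, same length; all
#'   strictly positive unless \code{theoretical = TRUE}.
#' @param label free-text label (condition, time point).
#' @param theoretical logical; theoretical curves carry \code{sigma = 0}.
#' @return an object of class \code{scattering_profile}.
#' @export
scattering_profile <- function(q, intensity, sigma, label = "",
                               theoretical = FALSE) {
  q <- as.numeric(q); intensity <- as.numeric(intensity)
  sigma <- as.numeric(sigma)
  if (length(q) != length(intensity) || length(q) != length(sigma))
    stop("q, intensity and sigma must have equal length")
  if (length(q) < 8L && !theoretical)
    stop("malformed input: a scattering profile needs at least 8 points")
  if (any(!is.finite(q)) || any(q <= 0))
    stop("q values must be finite and positive")
  if (any(diff(q) <= 0))
    stop("duplicate-q error: q must be strictly increasing")
  if (!theoretical && any(!(sigma > 0)))
    stop("all sigma must be > 0 (zero/negative uncertainties rejected)")
  structure(list(q = q, intensity = intensity, sigma = sigma,
                 label = as.character(label)[1]),
            class = "scattering_profile")
}

#' @export
print.scattering_profile <- function(x, ...) {
  cat(sprintf("<scattering_profile> %s\n  %d points, q in [%.4g, %.4g] 1/A\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$q), min(x$q), max(x$q)))
  invisible(x)
}

#' @export
length.scattering_profile <- function(x) length(x$q)

#' @export
as.data.frame.scattering_profile <- function(x, ...) {
  data.frame(q = x$q, intensity = x$intensity, sigma = x$sigma)
}

#' Read a SAXS profile from a plain-text file
#'
#' Parses 2- or 3-column whitespace-separated text (q, I, optional sigma).
#' Comment lines starting with \code{#} and non-numeric header lines are
#' skipped; rows with non-finite values are dropped with a warning giving the
#' count. Two-column input gets uncertainties synthesized as
#' \code{sigma_frac * I} because downstream fits require them.
#'
#' @param source path to a file, or a character vector of lines.
#' @param dialect \code{"three-column"} (sigma optional) or
#'   \code{"atsas-dat"} (sigma required).
#' @param sigma_frac relative uncertainty used when the file has no sigma
#'   column; default 0.02.
#' @param q_units \code{"A"} (default) or \code{"nm"}; nm^-1 grids are
#'   converted to \eqn{\AA^{-1}} by dividing by 10.
#' @param label label attached to the profile (defaults to the file name).
#' @return a \code{\link{scattering_profile}}.
#' @export
read_profile <- function(source, dialect = c("three-column", "atsas-dat"),
                         sigma_frac = 0.02, q_units = c("A", "nm"),
                         label = NULL) {
  dialect <- match.arg(dialect)
  q_units <- match.arg(q_units)
  if (length(source) == 1L && file.exists(source)) {
    lines <- readLines(source, warn = FALSE)
    if (is.null(label)) label <- basename(source)
  } else {
    lines <- as.character(source)
    if (is.null(label)) label <- ""
  }
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(trimws(lines), "#")]
  fields <- strsplit(trimws(lines), "\\s+")
  rows <- lapply(fields, function(f) suppressWarnings(as.numeric(f)))
  ncols <- vapply(rows, length, 1L)
  numeric_row <- vapply(rows, function(r) !anyNA(r) || any(is.finite(r)), TRUE)
  # header lines parse entirely to NA; keep rows with >= 2 numeric fields
  usable <- ncols >= 2L &
    vapply(rows, function(r) sum(is.finite(r)) >= 2L, TRUE) & numeric_row
  rows <- rows[usable]
  if (length(rows) == 0L) stop("malformed input: no numeric data rows")
  ncol_mode <- max(2L, min(vapply(rows, length, 1L)))
  if (dialect == "atsas-dat" && ncol_mode < 3L)
    stop("atsas-dat dialect requires a sigma column")
  mat <- t(vapply(rows, function(r) r[seq_len(min(3L, ncol_mode))],
                  numeric(min(3L, ncol_mode))))
  has_sigma <- ncol(mat) >= 3L
  finite <- is.finite(mat[, 1L]) & is.finite(mat[, 2L]) &
    (!has_sigma | is.finite(mat[, min(3L, ncol(mat))]))
  n_dropped <- sum(!finite)
  if (n_dropped > 0L)
    warning(sprintf("dropped %d rows with non-finite values", n_dropped))
  mat <- mat[finite, , drop = FALSE]
  if (nrow(mat) < 8L)
    stop("malformed input: fewer than 8 valid data rows")
  ord <- order(mat[, 1L])
  mat <- mat[ord, , drop = FALSE]
  if (any(diff(mat[, 1L]) <= 0))
    stop("duplicate-q error: repeated q values after sorting")
  q <- mat[, 1L]
  if (q_units == "nm") q <- q / 10
  intensity <- mat[, 2L]
  sigma <- if (has_sigma) mat[, 3L] else sigma_frac * abs(intensity)
  scattering_profile(q, intensity, sigma, label = label)
}

#' Write a SAXS profile as 3-column text
#'
#' Values are printed at 17 significant digits so that a read/write round
#' trip is bit-identical for finite doubles.
#'
#' @param profile a \code{\link{scattering_profile}}.
#' @param path output file path.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "scattering_profile"))
  header <- sprintf("# %s", profile$label)
  body <- sprintf("%.17g %.17g %.17g",
                  profile$q, profile$intensity, profile$sigma)
  writeLines(c(header, "# q[1/A] I(q) sigma", body), path)
  invisible(path)
}

q_grids_match <- function(a, b, tol = 1e-9) {
  length(a$q) == length(b$q) &&
    all(abs(a$q - b$q) <= tol * pmax(abs(a$q), abs(b$q)))
}

#' Subtract a buffer profile from a sample profile
#'
#' Pointwise \code{I_s - scale * I_b} with uncertainties added in quadrature.
#' Negative resulting intensities are retained (clipping would bias low-q
#' fits); if more than 20\% of points go negative the result carries the
#' attribute \code{mostly_negative = TRUE}.
#'
#' @param sample,buffer \code{\link{scattering_profile}} objects on identical
#'   q grids (relative tolerance 1e-9).
#' @param scale buffer scale factor, positive, default 1.
#' @return a \code{\link{scattering_profile}}.
#' @export
subtract_buffer <- function(sample, buffer, scale = 1.0) {
  stopifnot(inherits(sample, "scattering_profile"),
            inherits(buffer, "scattering_profile"), scale > 0)
  if (!q_grids_match(sample, buffer))
    stop("grid-mismatch error: sample and buffer q grids differ")
  intensity <- sample$intensity - scale * buffer$intensity
  sigma <- sqrt(sample$sigma^2 + scale^2 * buffer$sigma^2)
  out <- scattering_profile(sample$q, intensity, sigma,
                            label = sample$label)
  attr(out, "mostly_negative") <- mean(intensity < 0) > 0.2
  out
}

#' Average repeated frames with outlier rejection
#'
#' Per-q inverse-variance-weighted mean across frames. Frames whose median
#' standardized deviation from the per-q median curve exceeds
#' \code{outlier_cut} are excluded (a guard against radiation-damaged
#' frames; the median reference keeps a grossly deviant frame from masking
#' itself) and the average is computed over the survivors. The output
#' sigma is the propagated standard error of the weighted mean.
#'
#' @param frames list of \code{\link{scattering_profile}} objects on an
#'   identical q grid; at least 2.
#' @param outlier_cut rejection threshold in sigma units, default 3.
#' @return averaged \code{\link{scattering_profile}} with attribute
#'   \code{excluded} (integer indices of rejected frames).
#' @export
average_frames <- function(frames, outlier_cut = 3.0) {
  stopifnot(length(frames) >= 2L)
  for (f in frames[-1L])
    if (!q_grids_match(frames[[1L]], f))
      stop("grid-mismatch error: frames are not on a common q grid")
  I <- vapply(frames, function(f) f$intensity, numeric(length(frames[[1L]]$q)))
  S <- vapply(frames, function(f) f$sigma, numeric(length(frames[[1L]]$q)))
  w <- 1 / S^2
  ref <- apply(I, 1L, stats::median)
  dev <- abs(I - ref) / S
  med_dev <- apply(dev, 2L, stats::median)
  excluded <- which(med_dev > outlier_cut)
  keep <- setdiff(seq_along(frames), excluded)
  if (length(keep) == 0L)
    stop("empty-average error: all frames rejected at outlier_cut")
  Ik <- I[, keep, drop = FALSE]; wk <- w[, keep, drop = FALSE]
  mu <- rowSums(Ik * wk) / rowSums(wk)
  se <- sqrt(1 / rowSums(wk))
  out <- scattering_profile(frames[[1L]]$q, mu, se,
                            label = frames[[1L]]$label)
  attr(out, "excluded") <- as.integer(excluded)
  out
}

#' Assemble a time series of profiles
#'
#' Profiles are cropped to their common q range (intersection
#' [max of minima, min of maxima]) and checked for an identical grid there,
#' which downstream ensemble fits and fractal fits require.
#'
#' @param profiles ordered list of \code{\link{scattering_profile}} objects.
#' @param times numeric vector of times in seconds, non-negative, increasing.
#' @return an object of class \code{saxs_timeseries} with elements
#'   \code{profiles} and \code{times}.
#' @export
time_series <- function(profiles, times) {
  stopifnot(length(profiles) == length(times), length(profiles) >= 1L)
  times <- as.numeric(times)
  if (any(times < 0) || any(diff(times) <= 0))
    stop("times must be non-negative and increasing")
  qmin <- max(vapply(profiles, function(p) min(p$q), 1.0))
  qmax <- min(vapply(profiles, function(p) max(p$q), 1.0))
  if (qmin > qmax) stop("profiles share no common q range")
  profiles <- lapply(profiles, function(p) {
    keep <- p$q >= qmin - 1e-12 & p$q <= qmax + 1e-12
    scattering_profile(p$q[keep], p$intensity[keep], p$sigma[keep],
                       label = p$label,
                       theoretical = all(p$sigma == 0))
  })
  for (p in profiles[-1L])
    if (!q_grids_match(profiles[[1L]], p))
      stop("grid-mismatch error: cropped profiles do not share one q grid")
  structure(list(profiles = profiles, times = times),
            class = "saxs_timeseries")
}

#' @export
print.saxs_timeseries <- function(x, ...) {
  cat(sprintf("<saxs_timeseries> %d time points over [%.3g, %.3g] s\n",
              length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' @export
length.saxs_timeseries <- function(x) length(x$times)
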