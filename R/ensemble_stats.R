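#' Ensemble-weighted domain distances
#'
#' For each pair in the scheme, the mean of the per-conformer C-alpha
#' distances weighted by the conformer's fraction in the selected ensemble,
#' with the weighted standard deviation. The weighted mean is a convex
#' combination, so it always lies between the smallest and largest selected
#' distance.
#'
#' @param res an \code{ensemble_fit}.
#' @param pool the \code{conformer_pool} the fit refers to.
#' @param scheme a \code{\link{domain_scheme}}; must match the pool metrics
#'   columns.
#' @return data.frame with columns \code{pair}, \code{mean}, \code{sd}.
#' @export
weighted_domain_distances <- function(res, pool, scheme = domain_scheme()) {
  stopifnot(inherits(res, "ensemble_fit"), inherits(pool, "conformer_pool"))
  if (!is.na(res$pool_seed) && res$pool_seed != pool$seed)
    stop("provenance error: result was fitted against a different pool")
  ids <- as.integer(names(res$fractions))
  w <- as.numeric(res$fractions)
  rows <- lapply(names(scheme), function(nm) {
    if (!nm %in% names(pool$metrics))
      stop("scheme pair '", nm, "' missing from pool metrics")
    d <- unname(pool$metrics[[nm]][ids])
    m <- sum(w * d)
    v <- sum(w * (d - m)^2)
    data.frame(pair = nm, mean = m, sd = sqrt(v))
  })
  do.call(rbind, rows)
}

#' Build a conformational feature table from ensemble fits
#'
#' One row per selected conformer per (condition, time) fit, with its Rg,
#' end-to-end distance and ensemble fraction; fractions within each fit sum
#' to 1.
#'
#' @param fits named list (condition) of lists of \code{ensemble_fit}
#'   objects, one per time point, or a flat list with \code{conditions} and
#'   \code{times} vectors.
#' @param pool the shared \code{conformer_pool}.
#' @param conditions,times vectors parallel to \code{fits} when \code{fits}
#'   is a flat list.
#' @return data.frame with columns \code{rg}, \code{ree}, \code{fraction},
#'   \code{condition}, \code{time}.
#' @export
feature_table <- function(fits, pool, conditions = NULL, times = NULL) {
  stopifnot(inherits(pool, "conformer_pool"))
  if (is.null(conditions)) {
    conditions <- rep(names(fits), vapply(fits, length, 1L))
    times <- unlist(lapply(fits, function(l) {
      tm <- names(l)
      if (is.null(tm)) seq_along(l) else as.numeric(tm)
    }))
    fits <- unlist(fits, recursive = FALSE)
  }
  stopifnot(length(fits) == length(conditions), length(fits) == length(times))
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    ids <- as.integer(names(f$fractions))
    data.frame(rg = unname(pool$metrics$rg[ids]),
               ree = unname(pool$metrics$ree[ids]),
               fraction = as.numeric(f$fractions),
               condition = conditions[i], time = times[i],
               row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Ward-linkage clustering of conformational features
#'
#' Standardizes (z-scores) the rg, ree and fraction columns, agglomerates
#' with Ward's linkage on Euclidean distances, and cuts the dendrogram at
#' cophenetic distance \code{t}. Cluster summaries (mean Rg/Ree and
#' per-condition occupancy) are fraction-weighted by default, mirroring
#' the weighted-feature analysis; silhouette scores are computed on the
#' standardized features.
#'
#' @param features a \code{\link{feature_table}} (>= 10 rows).
#' @param t dendrogram cut height on the cophenetic distance, default 2.5.
#' @param weight_mode \code{"fraction-weighted"} (default) or \code{"raw"}
#'   summaries.
#' @return object of class \code{cluster_model}: \code{assignments},
#'   \code{k}, \code{silhouette} (mean; NA for a single cluster),
#'   \code{summaries} (per-cluster means and condition occupancy),
#'   \code{hclust}, \code{scaled} (the standardized feature matrix).
#' @export
cluster_ensembles <- function(features, t = 2.5,
                              weight_mode = c("fraction-weighted", "raw")) {
  weight_mode <- match.arg(weight_mode)
  stopifnot(nrow(features) >= 10L,
            all(c("rg", "ree", "fraction", "condition") %in% names(features)))
  X <- as.matrix(features[, c("rg", "ree", "fraction")])
  sds <- apply(X, 2L, stats::sd)
  degenerate_all <- all(sds == 0)
  sds[sds == 0] <- 1
  Z <- scale(X, center = TRUE, scale = sds)
  hc <- stats::hclust(stats::dist(Z), method = "ward.D2")
  assignments <- stats::cutree(hc, h = t)
  k <- length(unique(assignments))
  sil <- NA_real_
  if (k > 1L && !degenerate_all) {
    sw <- cluster::silhouette(assignments, stats::dist(Z))
    sil <- mean(sw[, "sil_width"])
  }
  w <- if (weight_mode == "fraction-weighted") features$fraction
       else rep(1, nrow(features))
  summaries <- do.call(rbind, lapply(sort(unique(assignments)), function(cl) {
    sel <- assignments == cl
    ww <- w[sel] / sum(w[sel])
    occ <- tapply(w * sel, features$condition, sum)
    occ <- occ / sum(occ, na.rm = TRUE)
    out <- data.frame(cluster = cl, n = sum(sel),
                      mean_rg = sum(ww * features$rg[sel]),
                      mean_ree = sum(ww * features$ree[sel]))
    for (cn in names(occ)) out[[paste0("occ_", cn)]] <-
      ifelse(is.na(occ[[cn]]), 0, occ[[cn]])
    out
  }))
  structure(list(assignments = assignments, k = k, t = t,
                 silhouette = sil, summaries = summaries,
                 hclust = hc, scaled = Z, weight_mode = weight_mode,
                 single_cluster = k == 1L),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> k = %d at t = %.2f; mean silhouette = %s\n",
              x$k, x$t,
              if (is.na(x$silhouette)) "undefined" else sprintf("%.3f", x$silhouette)))
  invisible(x)
}

# Dunn's post-hoc test with tie correction: pairwise z statistics on mean
# ranks after a Kruskal-Wallis test.
dunn_test <- function(values, groups) {
  groups <- factor(groups)
  N <- length(values)
  r <- rank(values)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  mean_ranks <- tapply(r, groups, mean)
  ns <- table(groups)
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / ns[[a]] + 1 / ns[[b]]))
    z <- (mean_ranks[[a]] - mean_ranks[[b]]) / se
    data.frame(group1 = a, group2 = b, z = z,
               p = 2 * stats::pnorm(-abs(z)))
  })
  do.call(rbind, rows)
}

#' Hedges' g standardized mean difference
#'
#' \eqn{g = J (m_1 - m_2)/s_{pooled}} with the small-sample correction
#' \eqn{J = 1 - 3/(4(n_1+n_2) - 9)}.
#'
#' @param x,y numeric samples.
#' @return g (numeric scalar; 0 when both groups are constant and equal).
#' @export
hedges_g <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
               (n1 + n2 - 2))
  J <- 1 - 3 / (4 * (n1 + n2) - 9)
  d <- mean(x) - mean(y)
  if (sp == 0) return(if (d == 0) 0 else sign(d) * Inf)
  J * d / sp
}

#' Condition-comparison statistics for ensemble features
#'
#' For each feature (rg, ree, fraction): a Kruskal-Wallis test across
#' conditions; when its p is below \code{alpha}, pairwise Dunn tests with
#' Benjamini-Hochberg adjustment applied within the feature's family of
#' pairwise tests; Hedges' g for every condition pair. Pairs with adjusted
#' q below \code{alpha} and |g| > 0.8 are flagged.
#'
#' @param features a \code{\link{feature_table}} with >= 2 conditions of
#'   >= 3 rows each (smaller conditions are excluded with a warning).
#' @param alpha significance level, default 0.05.
#' @param which_features columns to test, default
#'   \code{c("rg", "ree", "fraction")}.
#' @return object of class \code{stat_report}: \code{kruskal} (per-feature
#'   H, df, p) and \code{pairwise} (feature, pair, p, q, g, flag).
#' @export
condition_stats <- function(features, alpha = 0.05,
                            which_features = c("rg", "ree", "fraction")) {
  counts <- table(features$condition)
  small <- names(counts)[counts < 3L]
  if (length(small) > 0L) {
    warning("excluding conditions with fewer than 3 rows: ",
            paste(small, collapse = ", "))
    features <- features[!features$condition %in% small, , drop = FALSE]
  }
  conds <- unique(features$condition)
  if (length(conds) < 2L) stop("need at least 2 conditions with >= 3 rows")
  kw_rows <- list(); pw_rows <- list()
  for (feat in which_features) {
    v <- features[[feat]]
    g <- factor(features$condition)
    kw <- stats::kruskal.test(v, g)
    kw_rows[[feat]] <- data.frame(
      feature = feat, H = unname(kw$statistic),
      df = unname(kw$parameter), p = kw$p.value)
    dn <- dunn_test(v, g)
    dn$q <- stats::p.adjust(dn$p, method = "BH")
    gg <- vapply(seq_len(nrow(dn)), function(j)
      hedges_g(v[g == dn$group1[j]], v[g == dn$group2[j]]), 1.0)
    pw_rows[[feat]] <- data.frame(
      feature = feat, group1 = dn$group1, group2 = dn$group2,
      p = dn$p, q = dn$q, g = gg,
      flag = kw$p.value < alpha & dn$q < alpha & abs(gg) > 0.8)
  }
  structure(list(kruskal = do.call(rbind, kw_rows),
                 pairwise = do.call(rbind, pw_rows),
                 alpha = alpha),
            class = "stat_report")
}

#' @export
print.stat_report <- function(x, ...) {
  cat("<stat_report>\n")
  print(x$kruskal, row.names = FALSE)
  n_flag <- sum(x$pairwise$flag)
  cat(sprintf("  %d of %d pairwise comparisons flagged (q < %.2g and |g| > 0.8)\n",
              n_flag, nrow(x$pairwise), x$alpha))
  invisible(x)
}
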