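#' Empirical (cross-)semivariogram
#'
#' Matheron moment estimator on binned pair distances.  For one variable,
#' `gamma(h) = sum (z_i - z_j)^2 / (2 N(h))` over the pairs whose distance
#' falls in the bin; for two collocated variables, the cross form
#' `sum (z1_i - z1_j)(z2_i - z2_j) / (2 N(h))`.  Default binning: `n_lags`
#' equal-width bins up to half the maximum inter-point distance.  Empty bins
#' are reported with `N = 0` and `gamma = NA` and are excluded from fitting.
#'
#' @param coords Two-column matrix `(lon, lat)` (or km if `method =
#'   "euclidean"`).
#' @param values Numeric vector (per-mil for delta-13C).
#' @param values2 Optional second collocated variable; when supplied the
#'   cross-semivariogram is returned.
#' @param n_lags Number of equal-width lag bins (default 12).
#' @param cutoff Maximum pair distance in km (default half the maximum
#'   inter-point distance).
#' @param method Distance metric, see [dist_matrix()].
#' @param duplicates `"error"` (default) or `"average"`: collocated points
#'   are either rejected or averaged (logged).
#' @return An `empirical_variogram` data frame: `lag_center` (mean pair
#'   distance per bin, km), `gamma`, `npairs`, plus attributes `kind`
#'   (`"direct"`/`"cross"`), `cutoff`, `breaks`.
#' @export
empirical_semivariogram <- function(coords, values, values2 = NULL,
                                    n_lags = 12, cutoff = NULL,
                                    method = c("haversine", "euclidean"),
                                    duplicates = c("error", "average")) {
  method <- match.arg(method)
  duplicates <- match.arg(duplicates)
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 2) stop("need at least 2 points")
  stopifnot(length(values) == n, is.null(values2) || length(values2) == n)

  key <- paste(coords[, 1], coords[, 2])
  if (anyDuplicated(key)) {
    if (duplicates == "error") {
      stop("duplicated coordinates; use duplicates = \"average\" to collapse")
    }
    iso_log("warn", "averaging %d collocated point(s)", sum(duplicated(key)))
    idx <- split(seq_len(n), factor(key, levels = unique(key)))
    values <- vapply(idx, function(i) mean(values[i]), 0)
    if (!is.null(values2)) {
      values2 <- vapply(idx, function(i) mean(values2[i]), 0)
    }
    coords <- coords[!duplicated(key), , drop = FALSE]
    n <- nrow(coords)
  }

  d <- dist_matrix(coords, method = method)
  ut <- upper.tri(d)
  pd <- d[ut]
  if (is.null(cutoff)) cutoff <- max(pd) / 2
  if (cutoff <= 0) stop("cutoff must be > 0")
  kind <- if (is.null(values2)) "direct" else "cross"
  sq <- if (kind == "direct") {
    outer(values, values, "-")[ut]^2
  } else {
    (outer(values, values, "-") * outer(values2, values2, "-"))[ut]
  }
  breaks <- seq(0, cutoff, length.out = n_lags + 1)
  keep <- pd <= cutoff & pd > 0
  bin <- cut(pd[keep], breaks, include.lowest = TRUE, labels = FALSE)
  npairs <- tabulate(bin, nbins = n_lags)
  gsum <- vapply(seq_len(n_lags), function(b) sum(sq[keep][bin == b]), 0)
  dmean <- vapply(seq_len(n_lags), function(b) {
    if (npairs[b] == 0) NA_real_ else mean(pd[keep][bin == b])
  }, 0)
  gamma <- ifelse(npairs > 0, gsum / (2 * npairs), NA_real_)
  lag_center <- ifelse(is.na(dmean), (breaks[-1] + breaks[-(n_lags + 1)]) / 2,
                       dmean)
  out <- data.frame(lag_center = lag_center, gamma = gamma, npairs = npairs)
  attr(out, "kind") <- kind
  attr(out, "cutoff") <- cutoff
  attr(out, "breaks") <- breaks
  attr(out, "sample_var") <- if (kind == "direct") stats::var(values) else NA
  class(out) <- c("empirical_variogram", "data.frame")
  out
}

#' @rdname empirical_semivariogram
#' @param z1,z2 Collocated variable pair for the cross-semivariogram.
#' @export
empirical_cross_semivariogram <- function(coords, z1, z2, n_lags = 12,
                                          cutoff = NULL,
                                          method = c("haversine", "euclidean"),
                                          duplicates = c("error", "average")) {
  empirical_semivariogram(coords, z1, values2 = z2, n_lags = n_lags,
                          cutoff = cutoff, method = method,
                          duplicates = duplicates)
}
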