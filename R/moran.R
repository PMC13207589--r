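#' Moran's I spatial autocorrelation with a permutation test
#'
#' `I = (n / S0) * sum_ij w_ij (z_i - zbar)(z_j - zbar) / sum_i (z_i -
#' zbar)^2` with `w_ii = 0` and `S0 = sum_ij w_ij`.  The default weights are
#' inverse-distance, row-standardized; k-nearest-neighbour binary weights or
#' a user-supplied weight matrix are also accepted.  Significance is
#' assessed by random permutation of the values: two-sided p-value
#' `(count + 1) / (n_perm + 1)` where `count` is the number of permutations
#' with `|I_perm - E[I]| >= |I_obs - E[I]|`, `E[I] = -1/(n-1)`.
#'
#' @param coords Two-column coordinate matrix.
#' @param values Numeric vector (variance must be > 0).
#' @param weight_scheme `"inverse_distance"` (default), `"knn"`, or a
#'   user-supplied n x n non-negative weight matrix (zero diagonal).
#' @param k Neighbour count for `"knn"` (default 4).
#' @param row_standardize Divide each row by its sum (default `TRUE`;
#'   ignored for a user matrix, which is used as given).
#' @param n_perm Number of permutations (default 999); 0 skips the test.
#' @param seed RNG seed for the permutations.
#' @param method Distance metric, see [dist_matrix()].
#' @return A `moran_result` list: `I`, `expected`, `p_value`,
#'   `n_permutations`, `weight_scheme`.
#' @export
morans_i <- function(coords, values, weight_scheme = "inverse_distance",
                     k = 4, row_standardize = TRUE, n_perm = 999,
                     seed = 20240457, method = c("haversine", "euclidean")) {
  method <- match.arg(method)
  n <- length(values)
  if (is.matrix(weight_scheme)) {
    W <- weight_scheme
    stopifnot(nrow(W) == n, ncol(W) == n)
    if (any(W < 0)) stop("weights must be non-negative")
    diag(W) <- 0
    scheme <- "matrix"
  } else {
    scheme <- match.arg(weight_scheme, c("inverse_distance", "knn"))
    if (n < 4) stop("need at least 4 points")
    d <- dist_matrix(as.matrix(coords), method = method)
    if (any(d[upper.tri(d)] == 0)) stop("duplicated coordinates")
    if (scheme == "inverse_distance") {
      W <- 1 / d
      diag(W) <- 0
    } else {
      W <- matrix(0, n, n)
      for (i in seq_len(n)) {
        nb <- order(d[i, ])[2:(k + 1)]
        W[i, nb] <- 1
      }
    }
    if (row_standardize) {
      rs <- rowSums(W)
      W <- W / ifelse(rs == 0, 1, rs)
    }
  }
  if (stats::var(values) == 0) stop("zero variance in values")
  z <- values - mean(values)
  s0 <- sum(W)
  denom <- sum(z^2)
  I_of <- function(zc) (n / s0) * drop(crossprod(zc, W %*% zc)) / sum(zc^2)
  I_obs <- (n / s0) * drop(crossprod(z, W %*% z)) / denom
  expected <- -1 / (n - 1)
  p <- NA_real_
  if (n_perm > 0) {
    count <- .with_seed(seed, {
      dev_obs <- abs(I_obs - expected)
      sum(vapply(seq_len(n_perm), function(i) {
        zp <- z[sample.int(n)]
        abs(I_of(zp) - expected) >= dev_obs
      }, NA))
    })
    p <- (count + 1) / (n_perm + 1)
  }
  structure(list(I = I_obs, expected = expected, p_value = p,
                 n_permutations = n_perm, weight_scheme = scheme),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (E[I] = %.4f), permutation p = %s (%d perms, %s weights)\n",
              x$I, x$expected,
              if (is.na(x$p_value)) "NA" else format(x$p_value, digits = 3),
              x$n_permutations, x$weight_scheme))
  invisible(x)
}
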