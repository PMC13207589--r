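# Shared brute-force oracles and small builders.  Each oracle is written as
# a direct transcription of the defining formula, independent of the package
# internals it checks.

options(isokrig.log_level = "off")

# all-pairs Matheron estimator by explicit double loop, binned like
# empirical_semivariogram: pairs with 0 < d <= cutoff, bin j when
# breaks[j] < d <= breaks[j+1] (first bin closed at zero)
bf_variogram <- function(coords, values, breaks, values2 = values,
                         method = "euclidean") {
  n <- nrow(coords)
  d <- isokrig::dist_matrix(coords, method = method)
  nb <- length(breaks) - 1
  gsum <- numeric(nb)
  np <- integer(nb)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      h <- d[i, j]
      if (h <= 0 || h > breaks[nb + 1]) next
      b <- max(1, findInterval(h, breaks, left.open = TRUE,
                               rightmost.closed = FALSE))
      if (b > nb) next
      gsum[b] <- gsum[b] +
        (values[i] - values[j]) * (values2[i] - values2[j])
      np[b] <- np[b] + 1L
    }
  }
  list(gamma = ifelse(np > 0, gsum / (2 * np), NA_real_), npairs = np)
}

# Moran's I by explicit double sums
bf_moran <- function(W, z) {
  n <- length(z)
  zc <- z - mean(z)
  num <- 0
  for (i in 1:n) for (j in 1:n) num <- num + W[i, j] * zc[i] * zc[j]
  (n / sum(W)) * num / sum(zc^2)
}

# independent dense augmented-matrix ordinary-kriging solve
bf_ok <- function(coords, values, model, target, method = "euclidean") {
  n <- nrow(coords)
  A <- matrix(0, n + 1, n + 1)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) {
      h <- isokrig::dist_matrix(coords[i, , drop = FALSE],
                                coords[j, , drop = FALSE], method = method)
      A[i, j] <- model_semivariance(model, h)
    }
  }
  A[n + 1, 1:n] <- 1; A[1:n, n + 1] <- 1
  b <- numeric(n + 1)
  for (i in seq_len(n)) {
    h <- isokrig::dist_matrix(coords[i, , drop = FALSE],
                              matrix(target, 1), method = method)
    b[i] <- model_semivariance(model, h)
  }
  b[n + 1] <- 1
  sol <- solve(A, b)
  list(weights = sol[1:n], lagrange = sol[n + 1],
       pred = sum(sol[1:n] * values),
       var = sum(sol[1:n] * b[1:n]) + sol[n + 1])
}

# independent dense augmented-matrix co-kriging solve (collocated design)
bf_ck <- function(coords, z1, z2, lmc, target, method = "euclidean") {
  n <- nrow(coords)
  g <- function(i, j, comp) {
    h <- isokrig::dist_matrix(coords[i, , drop = FALSE],
                              coords[j, , drop = FALSE], method = method)
    isokrig:::.lmc_semivariance(lmc, h, comp)
  }
  N <- 2 * n
  A <- matrix(0, N + 2, N + 2)
  for (i in 1:n) for (j in 1:n) {
    A[i, j] <- if (i == j) 0 else g(i, j, "11")
    A[i, n + j] <- g(i, j, "12")
    A[n + i, j] <- g(i, j, "12")
    A[n + i, n + j] <- if (i == j) 0 else g(i, j, "22")
  }
  A[N + 1, 1:n] <- 1; A[1:n, N + 1] <- 1
  A[N + 2, n + (1:n)] <- 1; A[n + (1:n), N + 2] <- 1
  b <- numeric(N + 2)
  for (i in 1:n) {
    h <- isokrig::dist_matrix(coords[i, , drop = FALSE],
                              matrix(target, 1), method = method)
    b[i] <- isokrig:::.lmc_semivariance(lmc, h, "11")
    b[n + i] <- isokrig:::.lmc_semivariance(lmc, h, "12")
  }
  b[N + 1] <- 1
  sol <- solve(A, b)
  list(lambda = sol[1:n], mu = sol[n + (1:n)],
       pred = sum(sol[1:n] * z1) + sum(sol[n + (1:n)] * z2),
       var = sum(sol[1:(2 * n)] * b[1:(2 * n)]) + sol[N + 1])
}

# exhaustive Fisher-Jenks: minimize SDCM over all contiguous partitions of
# the sorted data into k classes
bf_jenks_sdcm <- function(values, k) {
  x <- sort(values)
  n <- length(x)
  ssq <- function(v) sum((v - mean(v))^2)
  if (k == 1) return(ssq(x))
  cuts <- utils::combn(n - 1, k - 1)
  best <- Inf
  for (ci in seq_len(ncol(cuts))) {
    bounds <- c(0, cuts[, ci], n)
    tot <- 0
    for (j in 1:k) tot <- tot + ssq(x[(bounds[j] + 1):bounds[j + 1]])
    if (tot < best) best <- tot
  }
  best
}

# build an empirical_variogram object from explicit lag/gamma/npairs
# vectors (for fitting tests on noise-free curves)
make_emp <- function(h, gamma, npairs = rep(50, length(h))) {
  out <- data.frame(lag_center = h, gamma = gamma, npairs = npairs)
  attr(out, "breaks") <- c(0, h)
  attr(out, "kind") <- "direct"
  class(out) <- c("empirical_variogram", "data.frame")
  out
}

# random site coordinates in a ~L km square (euclidean, in km)
rand_sites_km <- function(n, L = 100) cbind(runif(n, 0, L), runif(n, 0, L))
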