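test_that("Matheron estimator matches hand enumeration and the all-pairs oracle", {
  # two points, equal then unequal values
  co2 <- cbind(c(0, 1), c(0, 0))
  e <- empirical_semivariogram(co2, c(5, 5), n_lags = 1, cutoff = 200,
                               method = "euclidean")
  expect_equal(e$gamma[1], 0)
  e2 <- empirical_semivariogram(co2, c(0, 2), n_lags = 1, cutoff = 200,
                                method = "euclidean")
  expect_equal(e2$gamma[1], 2)  # (2^2) / (2 * 1)

  # three collinear points at distances 1, 1, 2 with values 0, 1, 0
  co3 <- cbind(c(0, 1, 2), c(0, 0, 0))
  e3 <- empirical_semivariogram(co3, c(0, 1, 0), n_lags = 2, cutoff = 2,
                                method = "euclidean")
  expect_equal(e3$gamma, c(0.5, 0))
  expect_equal(e3$npairs, c(2L, 1L))

  # all-pairs brute-force oracle, n = 50 random points
  set.seed(5)
  co <- rand_sites_km(50)
  z <- rnorm(50)
  e4 <- empirical_semivariogram(co, z, n_lags = 12, method = "euclidean")
  bf <- bf_variogram(co, z, attr(e4, "breaks"))
  expect_equal(e4$npairs, bf$npairs)
  expect_equal(e4$gamma, bf$gamma, tolerance = 1e-12)

  expect_error(empirical_semivariogram(rbind(co3, c(0, 0)), rep(1, 4)),
               "duplicated")
})

test_that("cross-semivariogram reduces to the direct one and matches hand pairs", {
  set.seed(6)
  co <- rand_sites_km(30)
  z <- rnorm(30)
  d <- empirical_semivariogram(co, z, method = "euclidean")
  x_same <- empirical_cross_semivariogram(co, z, z, method = "euclidean")
  expect_equal(x_same$gamma, d$gamma, tolerance = 1e-14)
  x_neg <- empirical_cross_semivariogram(co, z, -z, method = "euclidean")
  expect_equal(x_neg$gamma, -d$gamma, tolerance = 1e-14)

  co3 <- cbind(c(0, 1, 2), c(0, 0, 0))
  xc <- empirical_cross_semivariogram(co3, c(0, 1, 0), c(0, 2, 0),
                                      n_lags = 2, cutoff = 2,
                                      method = "euclidean")
  expect_equal(xc$gamma[1], 1.0)

  # brute-force cross oracle
  z2 <- rnorm(30)
  xg <- empirical_cross_semivariogram(co, z, z2, method = "euclidean")
  bf <- bf_variogram(co, z, attr(xg, "breaks"), values2 = z2)
  expect_equal(xg$gamma, bf$gamma, tolerance = 1e-12)
})

test_that("model closed forms: origin, sills, and the exponential value at range", {
  for (fam in variogram_families()) {
    m <- variogram_model(fam, nugget = 0.1, psill = 0.9, range_param = 10)
    expect_identical(model_semivariance(m, 0), 0)
    # sill convergence: far beyond the effective range every family is at
    # (or, for the oscillating ones, near) the sill
    gfar <- model_semivariance(m, 1e4)
    expect_lt(abs(gfar - 1), 0.06)
  }
  ms <- variogram_model("spherical", 0.1, 0.9, 10)
  expect_equal(model_semivariance(ms, 12), 1.0)
  me <- variogram_model("exponential", 0, 1, 10)
  expect_equal(model_semivariance(me, 10), 1 - exp(-3), tolerance = 1e-12)
  mg <- variogram_model("gaussian", 0, 1, 10)
  expect_equal(model_semivariance(mg, 10), 1 - exp(-3), tolerance = 1e-12)
  mr <- variogram_model("rational_quadratic", 0, 1, 10)
  expect_equal(model_semivariance(mr, 10), 0.95, tolerance = 1e-12)
  mst <- variogram_model("stable", 0, 1, 10, shape = 2)
  expect_equal(model_semivariance(mst, 5),
               model_semivariance(mg, 5), tolerance = 1e-12)

  # decay term bounded in [0, 1] for the bounded families; hole effect and
  # j_bessel may overshoot the sill transiently but stay within 1 + c
  h <- seq(0.01, 50, by = 0.01)
  for (fam in setdiff(variogram_families(), c("hole_effect", "j_bessel"))) {
    m <- variogram_model(fam, 0, 1, 10)
    g <- model_semivariance(m, h)
    expect_true(all(g >= -1e-12 & g <= 1 + 1e-9), info = fam)
  }
  for (fam in c("hole_effect", "j_bessel")) {
    m <- variogram_model(fam, 0, 1, 10)
    g <- model_semivariance(m, h)
    expect_true(all(g >= -1e-12 & g <= 2), info = fam)
    # continuity: no jumps along a fine grid
    expect_lt(max(abs(diff(g))), 0.05)
  }

  expect_error(variogram_model("spherical", -0.1, 1, 10), "nugget")
  expect_error(variogram_model("stable", 0, 1, 10, shape = 2.5), "shape")
  expect_error(variogram_model("exponential", 0, 1, 0), "range")
  expect_error(model_semivariance(me, -1), ">= 0")
})

test_that("WLS fitting recovers noise-free curves and errors when under-determined", {
  mtrue <- variogram_model("spherical", 0, 1, 5)
  h <- seq(0.25, 10, length.out = 20)
  emp <- make_emp(h, model_semivariance(mtrue, h))
  fit <- fit_semivariogram(emp, "spherical")
  expect_lt(abs(fit$nugget - 0), 1e-6)
  expect_lt(abs(fit$psill - 1), 1e-6)
  expect_lt(abs(fit$range_param - 5), 1e-6)

  # with a nugget too
  mtrue2 <- variogram_model("exponential", 0.3, 0.7, 8)
  emp2 <- make_emp(h, model_semivariance(mtrue2, h))
  fit2 <- fit_semivariogram(emp2, "exponential")
  expect_lt(abs(fit2$nugget - 0.3), 1e-5)
  expect_lt(abs(fit2$range_param - 8), 1e-4)

  # spatially unstructured values: fitted curve is pure nugget at about
  # the sample variance
  set.seed(8)
  co <- rand_sites_km(200)
  z <- rnorm(200)
  e <- empirical_semivariogram(co, z, method = "euclidean")
  f3 <- fit_semivariogram(e, "spherical")
  sill_flat <- f3$nugget + f3$psill *
    mean(isokrig:::.g_decay("spherical", e$lag_center / f3$range_param))
  expect_lt(abs(sill_flat - var(z)) / var(z), 0.15)

  expect_error(fit_semivariogram(make_emp(1, 0.5), "spherical"),
               "usable lag")
})

test_that("fitting is invariant to lag order and rescales with distance units", {
  mtrue <- variogram_model("exponential", 0.2, 0.8, 12)
  h <- seq(0.5, 25, length.out = 15)
  g <- model_semivariance(mtrue, h)
  set.seed(9)
  gn <- g * (1 + rnorm(15, sd = 0.03))
  emp <- make_emp(h, gn)
  fit_a <- fit_semivariogram(emp, "exponential")
  perm <- sample(15)
  emp_p <- make_emp(h[perm], gn[perm])
  fit_b <- fit_semivariogram(emp_p, "exponential")
  expect_equal(fit_a$range_param, fit_b$range_param, tolerance = 1e-6)
  expect_equal(fit_a$nugget, fit_b$nugget, tolerance = 1e-6)

  emp_m <- make_emp(h * 1000, gn)  # metres instead of km
  fit_m <- fit_semivariogram(emp_m, "exponential")
  expect_equal(fit_m$range_param / 1000, fit_a$range_param,
               tolerance = 1e-4)
  expect_equal(fit_m$psill, fit_a$psill, tolerance = 1e-6)
})

test_that("the coregionalization fit recovers linked fields and stays PSD", {
  # secondary an exact multiple of the primary: b12 = 2 b11, b22 = 4 b11
  set.seed(10)
  co <- rand_sites_km(120)
  z1 <- simulate_field(co, variogram_model("exponential", 0.05, 0.95, 40),
                       seed = 101, method = "euclidean")
  z2 <- 2 * z1
  e11 <- empirical_semivariogram(co, z1, method = "euclidean")
  e22 <- empirical_semivariogram(co, z2, method = "euclidean")
  e12 <- empirical_cross_semivariogram(co, z1, z2, method = "euclidean")
  lmc <- suppressMessages(fit_lmc(e11, e22, e12, "exponential"))
  tot <- function(b) lmc$nugget[[b]] + lmc$sill[[b]]
  expect_equal(tot("b12") / tot("b11"), 2, tolerance = 0.01)
  expect_equal(tot("b22") / tot("b11"), 4, tolerance = 0.01)
  # PSD by construction
  expect_lte(lmc$sill[["b12"]]^2, lmc$sill[["b11"]] * lmc$sill[["b22"]])
  expect_lte(lmc$nugget[["b12"]]^2,
             lmc$nugget[["b11"]] * lmc$nugget[["b22"]])

  # independent fields: weak cross-structure
  ratios <- sapply(1:20, function(r) {
    set.seed(200 + r)
    co <- rand_sites_km(300, 150)
    m <- variogram_model("exponential", 0.05, 0.95, 25)
    a <- simulate_field(co, m, seed = 300 + r, method = "euclidean")
    b <- simulate_field(co, m, seed = 400 + r, method = "euclidean")
    l <- suppressMessages(fit_lmc(
      empirical_semivariogram(co, a, method = "euclidean"),
      empirical_semivariogram(co, b, method = "euclidean"),
      empirical_cross_semivariogram(co, a, b, method = "euclidean"),
      "exponential"))
    tt <- l$nugget + l$sill   # total coefficient per component
    abs(tt[["b12"]]) / sqrt(max(tt[["b11"]] * tt[["b22"]], 1e-12))
  })
  expect_lte(median(ratios), 0.2)

  # a fit demanding |b12| > sqrt(b11 b22) is projected, not returned raw
  expect_error(lmc_model("exponential", 10, nugget = c(0, 0, 0),
                         sill = c(1, 1, 1.5)), "positive semi-definite")
})

test_that("Moran's I matches the double-sum oracle and known exact cases", {
  # alternating values on a 4-node path with binary rook weights
  W <- matrix(0, 4, 4)
  W[cbind(1:3, 2:4)] <- 1; W[cbind(2:4, 1:3)] <- 1
  res <- morans_i(NULL, c(1, -1, 1, -1), weight_scheme = W, n_perm = 0)
  expect_equal(res$I, -1, tolerance = 1e-12)

  # two points, antisymmetric values
  W2 <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(morans_i(NULL, c(3, -3), weight_scheme = W2, n_perm = 0)$I,
               -1, tolerance = 1e-12)

  # brute-force double-sum oracle with inverse-distance weights
  set.seed(12)
  co <- rand_sites_km(15)
  z <- rnorm(15)
  d <- dist_matrix(co, method = "euclidean")
  W3 <- 1 / d; diag(W3) <- 0; W3 <- W3 / rowSums(W3)
  res3 <- morans_i(co, z, n_perm = 99, seed = 1, method = "euclidean")
  expect_equal(res3$I, bf_moran(W3, z), tolerance = 1e-12)
  expect_equal(res3$expected, -1 / 14)
  expect_true(res3$p_value > 0 && res3$p_value <= 1)

  expect_error(morans_i(co, rep(1, 15), n_perm = 0), "zero variance")
})
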