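test_that("ordinary kriging honors the unbiasedness constraint in closed cases", {
  m <- variogram_model("exponential", 0.1, 0.9, 20)
  # single site: constraint forces lambda = 1
  p1 <- ordinary_krige(matrix(c(10, 10), 1), 5.5, m, c(40, 40),
                       method = "euclidean")
  expect_equal(p1$value, 5.5)
  expect_equal(unname(p1$weights), 1)

  # target coinciding with a site, zero nugget: exact, zero variance
  m0 <- variogram_model("spherical", 0, 1, 15)
  co <- rbind(c(0, 0), c(10, 0), c(5, 8))
  z <- c(1.2, -0.7, 0.4)
  p2 <- ordinary_krige(co, z, m0, co[2, ], method = "euclidean")
  expect_lt(abs(p2$value - z[2]), 1e-8)
  expect_lt(p2$std_error, 1e-6)

  # two sites equidistant from the target: weights (0.5, 0.5)
  co2 <- rbind(c(-3, 0), c(3, 0))
  p3 <- ordinary_krige(co2, c(2, 6), m, c(0, 4), method = "euclidean")
  expect_equal(unname(p3$weights), c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(p3$value, 4)
})

test_that("kriging weights equal the independent dense solve on random configs", {
  set.seed(14)
  fams <- c("exponential", "spherical", "gaussian", "stable")
  for (r in 1:25) {
    n <- sample(2:8, 1)
    co <- rand_sites_km(n, 50)
    z <- rnorm(n)
    m <- variogram_model(sample(fams, 1), nugget = runif(1, 0, 0.5),
                         psill = runif(1, 0.2, 2),
                         range_param = runif(1, 5, 60))
    tg <- runif(2, 0, 50)
    got <- ordinary_krige(co, z, m, tg, method = "euclidean")
    bf <- bf_ok(co, z, m, tg)
    expect_equal(unname(got$weights), bf$weights, tolerance = 1e-8)
    expect_equal(got$value, bf$pred, tolerance = 1e-8)
    expect_equal(got$std_error, sqrt(max(bf$var, 0)), tolerance = 1e-8)
    expect_lt(abs(sum(got$weights) - 1), 1e-10)
  }
})

test_that("co-kriging decouples at b12 = 0 and matches the dense solve", {
  set.seed(15)
  for (r in 1:10) {
    n <- sample(4:8, 1)
    co <- rand_sites_km(n, 60)
    z <- rnorm(n); x <- rnorm(n)
    m <- variogram_model("exponential", 0.1, 0.9, 25)
    lmc0 <- lmc_model("exponential", 25, nugget = c(0.1, 0.2, 0),
                      sill = c(0.9, 1.4, 0))
    tg <- runif(2, 0, 60)
    pk <- ordinary_krige(co, z, m, tg, method = "euclidean")
    pc <- ordinary_cokrige(co, z, x, lmc0, tg, method = "euclidean")
    expect_equal(pc$value, pk$value, tolerance = 1e-8)
    expect_equal(pc$std_error, pk$std_error, tolerance = 1e-8)
    expect_lt(abs(sum(pc$weights) - 1), 1e-10)
    expect_lt(abs(sum(pc$mu)), 1e-10)

    # general cross-structure: match the independent dense solve
    lmc <- lmc_model("exponential", 25, nugget = c(0.1, 0.2, 0.05),
                     sill = c(0.9, 1.4, runif(1, -0.8, 0.8)))
    got <- ordinary_cokrige(co, z, x, lmc, tg, method = "euclidean")
    bf <- bf_ck(co, z, x, lmc, tg)
    expect_equal(unname(got$weights), bf$lambda, tolerance = 1e-8)
    expect_equal(unname(got$mu), bf$mu, tolerance = 1e-8)
    expect_equal(got$value, bf$pred, tolerance = 1e-8)
  }
})

test_that("a secondary identical to the primary reproduces ordinary kriging", {
  set.seed(16)
  co <- rand_sites_km(7, 40)
  z <- rnorm(7)
  m <- variogram_model("spherical", 0.05, 0.95, 30)
  # cross structure equal to the direct structure in both components
  eps <- 1e-9  # strictly inside the PSD cone to keep the system regular
  lmc <- lmc_model("spherical", 30, nugget = c(0.05, 0.05, 0.05 - eps),
                   sill = c(0.95, 0.95, 0.95 - eps))
  tg <- c(17, 23)
  pk <- ordinary_krige(co, z, m, tg, method = "euclidean")
  pc <- ordinary_cokrige(co, z, z, lmc, tg, method = "euclidean")
  expect_equal(pc$value, pk$value, tolerance = 1e-6)
})

test_that("kriging is translation-equivariant and smooths only off-site", {
  set.seed(17)
  co <- rand_sites_km(10, 50)
  z <- rnorm(10)
  m <- variogram_model("exponential", 0.2, 0.8, 20)
  tg <- c(25, 25)
  a <- ordinary_krige(co, z, m, tg, method = "euclidean")
  b <- ordinary_krige(co, z + 100, m, tg, method = "euclidean")
  expect_equal(b$value - a$value, 100, tolerance = 1e-9)
  expect_equal(b$std_error, a$std_error, tolerance = 1e-12)
  expect_gt(a$std_error, 0)  # smoothing off the data points
})

test_that("grid prediction equals per-cell point kriging and handles nodata", {
  set.seed(18)
  co <- cbind(runif(8, 100, 101), runif(8, 30, 31))
  z <- rnorm(8, -24, 0.4)
  m <- variogram_model("exponential", 0.05, 0.4, 60)
  gs <- grid_spec(100, 30, 0.2, 5, 5)
  g <- predict_grid(co, z, m, gs)
  cc <- grid_cell_centers(gs)
  for (i in c(1, 7, 13, 25)) {
    p <- ordinary_krige(co, z, m, cc[i, ])
    row <- ceiling(i / 5); col <- i - (row - 1) * 5
    expect_equal(g$prediction[row, col], p$value, tolerance = 1e-12)
    expect_equal(g$std_error[row, col], p$std_error, tolerance = 1e-12)
  }

  # constant site values give a constant surface
  gconst <- predict_grid(co, rep(-24, 8), m, gs)
  expect_true(all(abs(gconst$prediction + 24) < 1e-8))

  # cells at the sites, zero nugget: surface reproduces the site values
  m0 <- variogram_model("exponential", 0, 0.4, 60)
  gs1 <- grid_spec(co[1, 1] - 0.05, co[1, 2] - 0.05, 0.1, 1, 1)
  gx <- predict_grid(co, z, m0, gs1)
  expect_equal(gx$prediction[1, 1], z[1], tolerance = 1e-8)

  # extrapolation limit: far cells become nodata
  gs_far <- grid_spec(110, 40, 0.2, 2, 2)
  gfar <- suppressMessages(predict_grid(co, z, m, gs_far, max_dist = 100))
  expect_true(all(is.na(gfar$prediction)))
})

test_that("co-kriging prediction variance does not exceed ordinary kriging", {
  diffs <- sapply(1:20, function(r) {
    set.seed(600 + r)
    co <- rand_sites_km(12, 60)
    f <- isokrig:::.simulate_lmc_at(
      co, "exponential", 40, sill = c(b11 = 0.9, b22 = 1.1, b12 = 0.7),
      nugget = c(b11 = 0.1, b22 = 0.1, b12 = 0), method = "euclidean")
    lmc <- lmc_model("exponential", 40, nugget = c(0.1, 0.1, 0),
                     sill = c(0.9, 1.1, 0.7))
    m <- variogram_model("exponential", 0.1, 0.9, 40)
    tg <- runif(2, 0, 60)
    vk <- ordinary_krige(co, f$z1, m, tg, method = "euclidean")$std_error^2
    vc <- ordinary_cokrige(co, f$z1, f$z2, lmc, tg,
                           method = "euclidean")$std_error^2
    vc - vk
  })
  expect_lte(median(diffs), 1e-10)
})
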