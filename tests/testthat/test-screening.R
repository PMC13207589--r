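test_that("Pearson r and p match the product-moment and t-transform formulas", {
  d <- data.frame(x = c(1, 2, 3), y = c(2, 4, 6), z = c(3, 2, 1))
  res <- pearson_matrix(d, c("x", "y", "z"))
  expect_equal(res$r_matrix["x", "y"], 1)
  expect_equal(res$p_matrix["x", "y"], 0)
  expect_equal(res$r_matrix["x", "z"], -1)
  d2 <- data.frame(a = 1:4, b = c(1, 3, 2, 4))
  expect_equal(pearson_matrix(d2, c("a", "b"))$r_matrix["a", "b"], 0.8)

  # brute-force double-loop oracle on random data
  set.seed(11)
  m <- as.data.frame(matrix(rnorm(10 * 5), 10))
  names(m) <- paste0("v", 1:5)
  res <- pearson_matrix(m, names(m))
  for (i in 1:5) for (j in 1:5) {
    xi <- m[[i]] - mean(m[[i]]); yj <- m[[j]] - mean(m[[j]])
    r_bf <- sum(xi * yj) / sqrt(sum(xi^2) * sum(yj^2))
    expect_equal(res$r_matrix[i, j], r_bf, tolerance = 1e-12)
    if (i != j) {
      expect_equal(res$p_matrix[i, j],
                   stats::cor.test(m[[i]], m[[j]])$p.value,
                   tolerance = 1e-10)
    }
  }
  expect_error(pearson_matrix(data.frame(a = rep(1, 5), b = 1:5),
                              c("a", "b")), "zero-variance")
  expect_error(pearson_matrix(data.frame(a = 1:2, b = 2:1),
                              c("a", "b")), "at least 3")
})

test_that("block selection passes uncorrelated variables and picks the hub", {
  # one noise variable, three mutual copies (plus tiny jitter): noise
  # passes, a copy is representative
  set.seed(21)
  base <- rnorm(20)
  d <- data.frame(c1 = base, c2 = base + rnorm(20, sd = 1e-3),
                  c3 = base + rnorm(20, sd = 1e-3), noise = rnorm(20))
  sel <- select_by_collinearity(pearson_matrix(d, names(d)), alpha = 0.05)
  expect_equal(sel$passing, "noise")
  expect_true(sel$representative %in% c("c1", "c2", "c3"))

  # two uncorrelated variables: both pass, tie broken by name order
  d2 <- data.frame(b = c(0.3, -1, 0.5, 2, -0.8), a = c(1, 2, -1, 0.5, 0))
  sel2 <- select_by_collinearity(pearson_matrix(d2, c("b", "a")),
                                 alpha = 1e-6)
  expect_setequal(sel2$passing, c("a", "b"))
  expect_equal(sel2$representative, "a")
})

test_that("the printed temperature-block matrix selects Bio9 with Bio3 passing", {
  vars <- paste0("Bio", 1:11)
  r <- matrix(1, 11, 11, dimnames = list(vars, vars))
  # upper triangle of the published correlation matrix; stars encoded as
  # p levels (0.001 for p<0.01, 0.03 for p<0.05, 0.5 for none)
  vals <- list(
    c("Bio1","Bio2",-0.68,.03), c("Bio1","Bio3",0.28,.5),
    c("Bio1","Bio4",-0.87,.001), c("Bio1","Bio5",0.78,.001),
    c("Bio1","Bio6",0.97,.001), c("Bio1","Bio7",-0.89,.001),
    c("Bio1","Bio8",0.77,.001), c("Bio1","Bio9",0.98,.001),
    c("Bio1","Bio10",0.88,.001), c("Bio1","Bio11",0.98,.001),
    c("Bio2","Bio3",0.43,.5), c("Bio2","Bio4",0.54,.03),
    c("Bio2","Bio5",-0.46,.5), c("Bio2","Bio6",-0.73,.5),
    c("Bio2","Bio7",0.72,.001), c("Bio2","Bio8",-0.38,.5),
    c("Bio2","Bio9",-0.67,.001), c("Bio2","Bio10",-0.65,.5),
    c("Bio2","Bio11",-0.64,.03),
    c("Bio3","Bio4",-0.51,.5), c("Bio3","Bio5",-0.03,.5),
    c("Bio3","Bio6",0.24,.5), c("Bio3","Bio7",-0.30,.5),
    c("Bio3","Bio8",0.30,.5), c("Bio3","Bio9",0.30,.5),
    c("Bio3","Bio10",0.38,.5), c("Bio3","Bio11",-0.06,.5),
    c("Bio4","Bio5",-0.40,.5), c("Bio4","Bio6",-0.92,.001),
    c("Bio4","Bio7",0.97,.001), c("Bio4","Bio8",-0.62,.5),
    c("Bio4","Bio9",-0.92,.001), c("Bio4","Bio10",-0.55,.03),
    c("Bio4","Bio11",-0.94,.5),
    c("Bio5","Bio6",0.66,.03), c("Bio5","Bio7",-0.44,.5),
    c("Bio5","Bio8",0.67,.001), c("Bio5","Bio9",0.69,.001),
    c("Bio5","Bio10",0.96,.001), c("Bio5","Bio11",0.66,.001),
    c("Bio6","Bio7",-0.96,.001), c("Bio6","Bio8",0.71,.001),
    c("Bio6","Bio9",0.98,.001), c("Bio6","Bio10",0.80,.001),
    c("Bio6","Bio11",0.99,.001),
    c("Bio7","Bio8",-0.61,.03), c("Bio7","Bio9",-0.93,.001),
    c("Bio7","Bio10",-0.62,.03), c("Bio7","Bio11",-0.95,.001),
    c("Bio8","Bio9",0.73,.001), c("Bio8","Bio10",0.72,.001),
    c("Bio8","Bio11",0.74,.001),
    c("Bio9","Bio10",0.82,.001), c("Bio9","Bio11",0.99,.001),
    c("Bio10","Bio11",0.79,.001))
  p <- matrix(NA_real_, 11, 11, dimnames = list(vars, vars))
  for (v in vals) {
    i <- v[1]; j <- v[2]
    r[i, j] <- r[j, i] <- as.numeric(v[3])
    p[i, j] <- p[j, i] <- as.numeric(v[4])
  }
  screen <- list(variables = vars, r_matrix = r, p_matrix = p)
  sel <- select_by_collinearity(screen, alpha = 0.01)
  expect_equal(sel$representative, "Bio9")
  expect_true("Bio3" %in% sel$passing)
})

test_that("VIF matches an independent least-squares oracle", {
  # two orthogonal centred variables
  d <- data.frame(a = c(-1, 1, -1, 1), b = c(-1, -1, 1, 1))
  v <- vif_table(d, c("a", "b"))
  expect_equal(unname(v), c(1, 1))

  # perfect collinearity flags Inf, no crash
  d2 <- data.frame(x1 = 1:6, x2 = 2 * (1:6), x3 = rnorm(6))
  v2 <- suppressMessages(vif_table(d2, c("x1", "x2", "x3")))
  expect_true(is.infinite(v2[["x1"]]) && is.infinite(v2[["x2"]]))

  # constructed correlated triple vs 1/(1 - R^2) from an independent
  # QR-based least-squares fit
  set.seed(31)
  n <- 40
  f <- rnorm(n)
  d3 <- data.frame(u = f + rnorm(n), v = f + rnorm(n), w = f + rnorm(n))
  v3 <- vif_table(d3, c("u", "v", "w"))
  for (nm in names(d3)) {
    y <- d3[[nm]]
    X <- cbind(1, as.matrix(d3[setdiff(names(d3), nm)]))
    beta <- qr.solve(X, y)
    r2 <- 1 - sum((y - X %*% beta)^2) / sum((y - mean(y))^2)
    expect_equal(v3[[nm]], 1 / (1 - r2), tolerance = 1e-10)
  }
  expect_true(all(v3 >= 1))
})

test_that("target correlation reports r, adjusted R2, p and the shortlist", {
  fx <- make_fixture_table()
  tab <- as.data.frame(fx$sites)
  tab$self <- tab$d13c_mean
  res <- correlate_with_target(tab, c("self", "bio15", "bio21"),
                               alpha = 0.05)
  expect_equal(res$r[res$variable == "self"], 1)
  expect_true(res$significant[res$variable == "self"])
  expect_equal(attr(res, "shortlist")[1], "self")

  # r = 0.9 at n = 10 is significant at alpha = 0.01 (t ~ 5.84, df = 8):
  # construct exactly r = 0.9 by orthogonalized noise
  set.seed(41)
  x <- seq_len(10)
  e <- rnorm(10)
  e <- resid(lm(e ~ x))
  xs <- (x - mean(x)) / sd(x)
  y <- 0.9 * xs + sqrt(1 - 0.81) * e / sd(e)
  d <- data.frame(d13c_mean = y, pred = x)
  expect_equal(cor(d$pred, d$d13c_mean), 0.9, tolerance = 1e-10)
  r1 <- correlate_with_target(d, "pred", alpha = 0.01)
  expect_true(r1$p < 0.01 && r1$significant)
  # adjusted R2 below plain R2, and consistent with the closed form
  expect_equal(r1$adj_r2, 1 - (1 - r1$r^2) * 9 / 8, tolerance = 1e-12)
})
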