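# run expr with a temporarily seeded RNG, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Fit a semivariogram model by weighted least squares
#'
#' Minimizes `sum_k w_k (gamma_hat_k - gamma(h_k))^2` over the non-empty
#' lags of an empirical semivariogram, with `w_k = N(h_k)` (default) or the
#' Cressie weights `N(h_k) / gamma(h_k)^2`.  Optimization is bounded
#' multi-start L-BFGS-B: one moment-based start (nugget from the first lag,
#' sill from the curve maximum, range from the lag span) plus Latin
#' hypercube draws over the parameter box, followed by a Nelder-Mead polish
#' of the best start.  Deterministic given `seed`.
#'
#' @param emp An [empirical_semivariogram()].
#' @param family One of [variogram_families()].
#' @param weighting `"npairs"` (default) or `"cressie"`.
#' @param n_starts Number of starts (>= 1, default 8; the Latin hypercube
#'   supplies `n_starts - 1`).
#' @param seed RNG seed for the start draw (default 20240457).
#' @param shape Optional shape parameter.  Fixed when given; for the
#'   `stable` family a missing shape is fitted as a fourth parameter, for
#'   the Bessel families the constructor defaults are used.
#' @return A [variogram_model()] with attribute `diagnostics` (weighted SSE,
#'   number of usable lags, convergence codes).
#' @export
fit_semivariogram <- function(emp, family, weighting = c("npairs", "cressie"),
                              n_starts = 8, seed = 20240457, shape = NULL) {
  weighting <- match.arg(weighting)
  family <- match.arg(family, variogram_families())
  use <- !is.na(emp$gamma) & emp$npairs > 0
  h <- emp$lag_center[use]
  g_emp <- emp$gamma[use]
  np <- emp$npairs[use]
  fit_shape <- family == "stable" && is.null(shape)
  n_par <- 3 + as.integer(fit_shape)
  if (sum(use) < n_par) {
    stop("only ", sum(use), " usable lag(s) for ", n_par,
         " free parameter(s)")
  }
  shape_fixed <- if (family %in% c("k_bessel", "j_bessel", "stable") &&
                     !fit_shape) {
    # construct once to validate the shape and pick up the bessel scaling
    variogram_model(family, 0, 1, 1, shape = shape)$shape
  } else NULL

  gmax <- max(g_emp)
  hmax <- max(h)
  hmin <- min(h)
  lower <- c(0, 1e-10, hmin / 3)
  upper <- c(1.5 * gmax, 3 * gmax, 3 * hmax)
  if (fit_shape) { lower <- c(lower, 0.3); upper <- c(upper, 2) }

  obj <- function(par) {
    sh <- if (fit_shape) par[4] else shape_fixed
    gm <- par[1] + par[2] * .g_decay(family, h / par[3], sh)
    w <- if (weighting == "npairs") np else np / pmax(gm, 1e-12)^2
    sum(w * (g_emp - gm)^2)
  }

  starts <- .with_seed(seed, {
    heur <- c(max(min(g_emp), 0), max(gmax - min(g_emp), 1e-6 * gmax),
              hmax / 2)
    if (fit_shape) heur <- c(heur, 1.5)
    if (n_starts > 1) {
      u <- lhs::maximinLHS(n_starts - 1, length(lower))
      more <- t(t(u) * (upper - lower) + lower)
      rbind(heur, more)
    } else {
      matrix(heur, nrow = 1)
    }
  })

  best <- NULL
  codes <- integer(0)
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::optim(pmin(pmax(starts[i, ], lower), upper), obj,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(factr = 1e4, maxit = 500)),
      error = function(e) NULL)
    if (is.null(res)) next
    codes <- c(codes, res$convergence)
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best) || !any(codes == 0)) {
    stop("semivariogram fit did not converge in any of ", nrow(starts),
         " starts (family ", family, ")")
  }
  # polish: Nelder-Mead then a tight bounded refinement
  pol <- stats::optim(best$par, function(p) {
    if (any(p < lower) || any(p > upper)) return(Inf)
    obj(p)
  }, method = "Nelder-Mead",
     control = list(maxit = 2000, reltol = 1e-14))
  if (pol$value < best$value) best <- pol
  pol2 <- tryCatch(
    stats::optim(best$par, obj, method = "L-BFGS-B", lower = lower,
                 upper = upper, control = list(factr = 10, maxit = 1000)),
    error = function(e) NULL)
  if (!is.null(pol2) && pol2$value < best$value) best <- pol2

  par <- best$par
  model <- variogram_model(family, nugget = par[1], psill = par[2],
                           range_param = par[3],
                           shape = if (fit_shape) par[4] else shape)
  attr(model, "diagnostics") <- list(
    wsse = best$value, n_lags = sum(use), weighting = weighting,
    n_starts = nrow(starts), convergence = codes)
  model
}

#' Linear model of coregionalization
#'
#' `lmc_model()` builds a two-variable (primary delta-13C + one auxiliary)
#' coregionalization with a single shared structure: semivariance
#' `gamma_kl(h) = B0[k,l] * 1(h > 0) + B1[k,l] * g(h/a)`.  Both coefficient
#' matrices must be positive semi-definite (`b11, b22 >= 0`,
#' `b12^2 <= b11 * b22`); violations are rejected here.
#'
#' @param family Shared structure family.
#' @param range_param Shared effective range (km).
#' @param nugget Length-3 numeric `c(b11, b22, b12)` nugget coefficients.
#' @param sill Length-3 numeric `c(b11, b22, b12)` partial-sill coefficients.
#' @param shape Optional shared shape parameter.
#' @return An `lmc_model` object.
#' @export
lmc_model <- function(family, range_param, nugget, sill, shape = NULL) {
  tmpl <- variogram_model(family, 0, 1, range_param, shape = shape)
  chk <- function(b, what) {
    stopifnot(length(b) == 3)
    if (b[1] < 0 || b[2] < 0 || b[3]^2 > b[1] * b[2] + 1e-12) {
      stop(what, " coefficient matrix is not positive semi-definite")
    }
  }
  chk(nugget, "nugget")
  chk(sill, "sill")
  structure(list(family = tmpl$family, range_param = tmpl$range_param,
                 shape = tmpl$shape,
                 nugget = stats::setNames(as.numeric(nugget),
                                          c("b11", "b22", "b12")),
                 sill = stats::setNames(as.numeric(sill),
                                        c("b11", "b22", "b12"))),
            class = "lmc_model")
}

#' @export
print.lmc_model <- function(x, ...) {
  cat(sprintf(
    "lmc_model: %s  a = %.4g km\n  nugget b11 %.4g b22 %.4g b12 %.4g\n  sill   b11 %.4g b22 %.4g b12 %.4g\n",
    x$family, x$range_param, x$nugget[1], x$nugget[2], x$nugget[3],
    x$sill[1], x$sill[2], x$sill[3]))
  invisible(x)
}

# semivariance gamma_kl(h) for component which in {"11","22","12"}
.lmc_semivariance <- function(lmc, h, which = c("11", "22", "12")) {
  which <- match.arg(which)
  key <- switch(which, "11" = "b11", "22" = "b22", "12" = "b12")
  g <- .g_decay(lmc$family, h / lmc$range_param, lmc$shape)
  ifelse(h == 0, 0, lmc$nugget[[key]] + lmc$sill[[key]] * g)
}

# weighted linear LS of gamma_emp on (1, g); nonneg = clamp coefficients
# at zero (direct variograms)
.wls_nugget_sill <- function(g_emp, gdecay, w, nonneg) {
  X <- cbind(1, gdecay)
  A <- crossprod(X * w, X)
  b <- crossprod(X * w, g_emp)
  beta <- tryCatch(drop(solve(A, b)), error = function(e) c(0, 0))
  if (nonneg) {
    if (beta[2] < 0) {
      beta[2] <- 0
      beta[1] <- max(sum(w * g_emp) / sum(w), 0)
    }
    if (beta[1] < 0) {
      beta[1] <- 0
      beta[2] <- max(sum(w * gdecay * g_emp) / sum(w * gdecay^2), 0)
    }
  }
  beta
}

#' Fit a linear model of coregionalization
#'
#' Fits the shared-structure coregionalization to the two direct and one
#' cross empirical semivariograms computed on the same lag binning: the
#' shared range is profiled by one-dimensional minimization of the pooled
#' (scale-normalized) weighted SSE, the nugget/sill coefficients of each
#' component are then linear WLS solutions (non-negative for the direct
#' components).  Cross coefficients are clipped to `+/- sqrt(b11 * b22)`
#' when the fit demands a non-positive-semi-definite matrix; the projection
#' is logged.
#'
#' @param emp11,emp22 Direct empirical semivariograms of the primary and the
#'   auxiliary variable.
#' @param emp12 Their cross-semivariogram.
#' @param family Shared structure family.
#' @param shape Optional shared shape parameter.
#' @param weighting `"npairs"` (default) or `"cressie"`.
#' @return An [lmc_model()] with attribute `diagnostics`.
#' @export
fit_lmc <- function(emp11, emp22, emp12, family, shape = NULL,
                    weighting = c("npairs", "cressie")) {
  weighting <- match.arg(weighting)
  family <- match.arg(family, variogram_families())
  b1 <- attr(emp11, "breaks"); b2 <- attr(emp22, "breaks")
  b3 <- attr(emp12, "breaks")
  if (!isTRUE(all.equal(b1, b2)) || !isTRUE(all.equal(b1, b3))) {
    stop("the three empirical variograms must share one lag binning")
  }
  use <- !is.na(emp11$gamma) & !is.na(emp22$gamma) & !is.na(emp12$gamma) &
    emp11$npairs > 0
  if (sum(use) < 3) stop("fewer than 3 shared usable lags")
  h <- emp11$lag_center[use]
  np <- emp11$npairs[use]
  comps <- list(`11` = emp11$gamma[use], `22` = emp22$gamma[use],
                `12` = emp12$gamma[use])
  scales <- vapply(comps, function(g) max(mean(g^2), 1e-12), 0)
  shape_fixed <- if (family %in% c("k_bessel", "j_bessel", "stable")) {
    variogram_model(family, 0, 1, 1, shape = shape)$shape
  } else NULL

  fit_at <- function(a) {
    gd <- .g_decay(family, h / a, shape_fixed)
    sse <- 0
    betas <- list()
    for (k in names(comps)) {
      g_emp <- comps[[k]]
      w <- if (weighting == "npairs") np else np / pmax(abs(g_emp), 1e-8)^2
      beta <- .wls_nugget_sill(g_emp, gd, w, nonneg = k != "12")
      resid <- g_emp - (beta[1] + beta[2] * gd)
      sse <- sse + sum(w * resid^2) / scales[[k]]
      betas[[k]] <- beta
    }
    list(sse = sse, betas = betas)
  }

  opt <- stats::optimize(function(a) fit_at(a)$sse,
                         interval = c(min(h) / 3, 3 * max(h)),
                         tol = 1e-8)
  a_hat <- opt$minimum
  betas <- fit_at(a_hat)$betas

  clip_cross <- function(b11, b22, b12, what) {
    # clip strictly inside the PSD boundary: |b12| = sqrt(b11 b22) exactly
    # means perfectly correlated components, which makes the co-kriging
    # system singular
    lim <- sqrt(b11 * b22) * (1 - 1e-6)
    if (abs(b12) > lim) {
      iso_log("warn",
              "%s cross coefficient %.4g clipped to +/-%.4g (PSD projection)",
              what, b12, lim)
      b12 <- sign(b12) * lim
    }
    b12
  }
  nug <- c(betas[["11"]][1], betas[["22"]][1], betas[["12"]][1])
  sil <- c(betas[["11"]][2], betas[["22"]][2], betas[["12"]][2])
  nug[3] <- clip_cross(nug[1], nug[2], nug[3], "nugget")
  sil[3] <- clip_cross(sil[1], sil[2], sil[3], "sill")

  out <- lmc_model(family, a_hat, nugget = nug, sill = sil, shape = shape)
  attr(out, "diagnostics") <- list(wsse = opt$objective, n_lags = sum(use),
                                   weighting = weighting)
  out
}
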