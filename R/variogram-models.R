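#' The semivariogram model catalog
#'
#' Names of the eleven parametric semivariogram families supported by
#' [variogram_model()]: circular, spherical, tetraspherical,
#' pentaspherical, exponential, gaussian, rational_quadratic, hole_effect,
#' k_bessel, j_bessel, stable.
#'
#' @return Character vector of length 11.
#' @export
variogram_families <- function() {
  c("circular", "spherical", "tetraspherical", "pentaspherical",
    "exponential", "gaussian", "rational_quadratic", "hole_effect",
    "k_bessel", "j_bessel", "stable")
}

# Correlation-decay term g(u) per family, u = h / a with a the range
# parameter under the *effective-range* convention: bounded polynomial
# families reach the sill exactly at u = 1; asymptotic families
# (exponential, gaussian, stable, rational_quadratic, k_bessel, j_bessel)
# are scaled to reach 95% of the sill at u = 1 (hence the factor 3 in the
# exponentials and 19 in the rational quadratic).
#
# Reference closed forms for the three families whose formulas are
# conventions rather than universal:
#  * tetraspherical: the 4-dimensional spherical (ball-overlap) correlation,
#    g(u) = 1 - I_{1-u^2}(5/2, 1/2) via the regularized incomplete beta
#    function (pbeta), clipped at 1 for u > 1.  The same beta identity
#    reproduces circular (d=2), spherical (d=3) and pentaspherical (d=5).
#  * k_bessel: the Matern model 1 - (2^{1-s}/Gamma(s)) t^s K_s(t) with
#    shape s > 0, t = kappa_s * u and kappa_s calibrated at model
#    construction so that g(1) = 0.95.
#  * j_bessel: 1 - Gamma(s+1) (2/t)^s J_s(t), shape s >= 0, t = kappa_s * u
#    with kappa_s the solution of g = 0.95 before the first zero of J_s;
#    like the hole effect it oscillates about the sill at large u.
.g_decay <- function(family, u, shape = NULL) {
  u <- pmax(u, 0)
  switch(family,
    circular = {
      v <- pmin(u, 1)
      (2 / pi) * (v * sqrt(1 - v^2) + asin(v))
    },
    spherical = {
      v <- pmin(u, 1)
      1.5 * v - 0.5 * v^3
    },
    tetraspherical = {
      v <- pmin(u, 1)
      1 - stats::pbeta(1 - v^2, 5 / 2, 1 / 2)
    },
    pentaspherical = {
      v <- pmin(u, 1)
      (15 / 8) * v - (5 / 4) * v^3 + (3 / 8) * v^5
    },
    exponential = 1 - exp(-3 * u),
    gaussian = 1 - exp(-3 * u^2),
    rational_quadratic = 19 * u^2 / (1 + 19 * u^2),
    hole_effect = ifelse(u == 0, 0, 1 - sin(2 * pi * u) / (2 * pi * u)),
    stable = 1 - exp(-3 * u^shape),
    k_bessel = {
      s <- shape
      t <- attr(shape, "kappa") * u
      out <- ifelse(t == 0, 0,
                    1 - (2^(1 - s) / gamma(s)) * t^s * besselK(t, s))
      # besselK underflows to 0 for large t: correlation -> 0, g -> 1
      out[t > 700] <- 1
      out
    },
    j_bessel = {
      s <- shape
      t <- attr(shape, "kappa") * u
      ifelse(t == 0, 0, 1 - gamma(s + 1) * (2 / t)^s * besselJ(t, s))
    },
    stop("unknown family: ", family)
  )
}

# kappa scaling for the bessel families: solve corr(kappa) = 0.05 so the
# effective range lands at u = 1.
.bessel_kappa <- function(family, shape) {
  corr <- if (family == "k_bessel") {
    function(t) (2^(1 - shape) / gamma(shape)) * t^shape * besselK(t, shape)
  } else {
    function(t) gamma(shape + 1) * (2 / t)^shape * besselJ(t, shape)
  }
  upper <- if (family == "k_bessel") {
    50
  } else {
    # stay left of the first zero of J_s, where the correlation first
    # crosses zero
    t <- seq(0.05, 30, by = 0.05)
    t[which(corr(t) <= 0)[1]] - 0.05
  }
  stats::uniroot(function(t) corr(t) - 0.05, c(1e-8, upper),
                 tol = 1e-12)$root
}

#' Parametric semivariogram model
#'
#' Constructs a validated semivariogram model `gamma(h) = c0 + c * g(h/a)`
#' for `h > 0` and `gamma(0) = 0`, with nugget `c0 >= 0`, partial sill
#' `c >= 0`, and range parameter `a > 0` in km under the effective-range
#' convention (asymptotic families reach 95% of the sill at `h = a`).
#' Parameter domains are checked here, not at evaluation.
#'
#' @param family One of [variogram_families()].
#' @param nugget Nugget `c0` (>= 0).
#' @param psill Partial sill `c` (>= 0).
#' @param range_param Effective range `a` in km (> 0).
#' @param shape Optional shape: exponent in (0, 2] for `stable` (default
#'   1.5), smoothness > 0 for `k_bessel` (default 0.5) and >= 0 for
#'   `j_bessel` (default 1).
#' @return A `variogram_model` object.
#' @examples
#' m <- variogram_model("exponential", nugget = 0, psill = 1, range_param = 10)
#' model_semivariance(m, 10)  # 1 - exp(-3) ~ 0.9502
#' @export
variogram_model <- function(family, nugget, psill, range_param,
                            shape = NULL) {
  family <- match.arg(family, variogram_families())
  if (!is.numeric(nugget) || nugget < 0) stop("nugget must be >= 0")
  if (!is.numeric(psill) || psill < 0) stop("partial sill must be >= 0")
  if (!is.numeric(range_param) || range_param <= 0) {
    stop("range parameter must be > 0")
  }
  if (family == "stable") {
    if (is.null(shape)) shape <- 1.5
    if (shape <= 0 || shape > 2) stop("stable shape must be in (0, 2]")
  } else if (family == "k_bessel") {
    if (is.null(shape)) shape <- 0.5
    if (shape <= 0) stop("k_bessel shape must be > 0")
    attr(shape, "kappa") <- .bessel_kappa("k_bessel", shape)
  } else if (family == "j_bessel") {
    if (is.null(shape)) shape <- 1
    if (shape < 0) stop("j_bessel shape must be >= 0")
    attr(shape, "kappa") <- .bessel_kappa("j_bessel", shape)
  } else if (!is.null(shape)) {
    stop("family '", family, "' takes no shape parameter")
  }
  structure(list(family = family, nugget = as.numeric(nugget),
                 psill = as.numeric(psill),
                 range_param = as.numeric(range_param), shape = shape),
            class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("variogram_model: %s  c0 = %.4g  c = %.4g  a = %.4g km%s\n",
              x$family, x$nugget, x$psill, x$range_param,
              if (!is.null(x$shape)) sprintf("  shape = %.3g",
                                             as.numeric(x$shape)) else ""))
  invisible(x)
}

#' Evaluate a semivariogram model
#'
#' `gamma(0) = 0` by convention; for `h > 0`, `c0 + c * g(h/a)` with the
#' family decay `g` documented in [variogram_model()].
#'
#' @param model A [variogram_model()].
#' @param h Distances in km (vectorized, >= 0).
#' @return Semivariances, same length as `h`.
#' @export
model_semivariance <- function(model, h) {
  stopifnot(inherits(model, "variogram_model"))
  if (any(h < 0)) stop("h must be >= 0")
  g <- .g_decay(model$family, h / model$range_param, model$shape)
  ifelse(h == 0, 0, model$nugget + model$psill * g)
}

# Covariance counterpart for simulation: C(0) = c0 + c, C(h) = c*(1 - g)
# for h > 0.  Only meaningful for families that are valid covariances in
# the plane; the simulator checks positive-definiteness numerically anyway.
.model_covariance <- function(model, h) {
  g <- .g_decay(model$family, h / model$range_param, model$shape)
  ifelse(h == 0, model$nugget + model$psill, model$psill * (1 - g))
}
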