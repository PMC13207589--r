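# Solve the ordinary-kriging system (semivariance form) for one or more
# targets at once.  A = [[Gamma, 1], [1', 0]], rhs per target =
# [gamma(h_i0); 1].  Returns weights (n x m), lagrange (m), pred (m),
# var (m, clipped at 0 with a log).
.ok_solve <- function(coords, values, model, targets, method) {
  n <- nrow(coords)
  A <- matrix(0, n + 1, n + 1)
  if (n > 1) {
    D <- dist_matrix(coords, method = method)
    A[1:n, 1:n] <- model_semivariance(model, D)
  }
  A[n + 1, 1:n] <- 1
  A[1:n, n + 1] <- 1
  d0 <- dist_matrix(coords, targets, method = method)
  rhs <- rbind(matrix(model_semivariance(model, d0), nrow = n), 1)
  sol <- tryCatch(solve(A, rhs), error = function(e) {
    stop("ordinary kriging system is singular or ill-conditioned ",
         "(duplicate sites or a degenerate model?): ", conditionMessage(e))
  })
  lambda <- sol[1:n, , drop = FALSE]
  m <- sol[n + 1, ]
  pred <- drop(crossprod(lambda, values))
  v <- colSums(lambda * rhs[1:n, , drop = FALSE]) + m
  neg <- v < 0
  if (any(neg)) {
    iso_log("info", "clipped %d negative kriging variance(s) to 0 (round-off)",
            sum(neg))
    v[neg] <- 0
  }
  list(pred = pred, var = v, weights = lambda, lagrange = m)
}

# Ordinary co-kriging system for primary variable 1 observed at coords1 and
# auxiliary variable 2 at coords2 (usually collocated; coords2 may be a
# superset).  Constraints: sum(lambda) = 1, sum(mu) = 0.
.ck_solve <- function(coords1, z1, coords2, z2, lmc, targets, method) {
  n1 <- nrow(coords1); n2 <- nrow(coords2)
  N <- n1 + n2
  A <- matrix(0, N + 2, N + 2)
  A[1:n1, 1:n1] <- .lmc_semivariance(
    lmc, dist_matrix(coords1, method = method), "11")
  A[1:n1, n1 + (1:n2)] <- .lmc_semivariance(
    lmc, dist_matrix(coords1, coords2, method = method), "12")
  A[n1 + (1:n2), 1:n1] <- t(A[1:n1, n1 + (1:n2), drop = FALSE])
  A[n1 + (1:n2), n1 + (1:n2)] <- .lmc_semivariance(
    lmc, dist_matrix(coords2, method = method), "22")
  A[N + 1, 1:n1] <- 1; A[1:n1, N + 1] <- 1
  A[N + 2, n1 + (1:n2)] <- 1; A[n1 + (1:n2), N + 2] <- 1
  g10 <- matrix(.lmc_semivariance(
    lmc, dist_matrix(coords1, targets, method = method), "11"), nrow = n1)
  g20 <- matrix(.lmc_semivariance(
    lmc, dist_matrix(coords2, targets, method = method), "12"), nrow = n2)
  rhs <- rbind(g10, g20, 1, 0)
  sol <- tryCatch(solve(A, rhs), error = function(e) {
    stop("co-kriging system is singular or ill-conditioned: ",
         conditionMessage(e))
  })
  lambda <- sol[1:n1, , drop = FALSE]
  mu <- sol[n1 + (1:n2), , drop = FALSE]
  m1 <- sol[N + 1, ]
  pred <- drop(crossprod(lambda, z1) + crossprod(mu, z2))
  v <- colSums(lambda * g10) + colSums(mu * g20) + m1
  neg <- v < 0
  if (any(neg)) {
    iso_log("info", "clipped %d negative co-kriging variance(s) to 0",
            sum(neg))
    v[neg] <- 0
  }
  list(pred = pred, var = v, weights = lambda, mu = mu,
       lagrange = cbind(m1, sol[N + 2, ]))
}

#' Ordinary kriging point prediction
#'
#' Solves the ordinary-kriging system in semivariance form (usable with
#' unbounded models) with the unbiasedness constraint `sum(lambda) = 1`;
#' prediction `sum lambda_i z_i`, variance `sum lambda_i gamma(h_i0) +
#' lagrange`.  All sites enter every prediction (global neighbourhood; site
#' counts in this workflow are tens of points).
#'
#' @param coords Two-column site coordinates.
#' @param values Observed values at the sites (per-mil).
#' @param model A [variogram_model()].
#' @param target Length-2 coordinate of the prediction point.
#' @param method Distance metric, see [dist_matrix()].
#' @return A `kriging_prediction` list: `value`, `std_error`, `weights`,
#'   `lagrange`.
#' @export
ordinary_krige <- function(coords, values, model, target,
                           method = c("haversine", "euclidean")) {
  method <- match.arg(method)
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) >= 1, length(values) == nrow(coords),
            inherits(model, "variogram_model"))
  sol <- .ok_solve(coords, values, model, matrix(target, nrow = 1), method)
  structure(list(value = sol$pred[1], std_error = sqrt(sol$var[1]),
                 weights = drop(sol$weights), lagrange = sol$lagrange[1]),
            class = "kriging_prediction")
}

#' Ordinary co-kriging point prediction
#'
#' Ordinary co-kriging of the primary variable using one auxiliary variable
#' under a shared [lmc_model()], with constraints `sum(lambda) = 1` (primary
#' weights) and `sum(mu) = 0` (auxiliary weights).  The auxiliary is
#' normally collocated with the primary; a superset of auxiliary locations
#' is accepted (used by cross-validation, where the climate auxiliary is
#' still known at a held-out site).
#'
#' @param coords Primary site coordinates (two columns).
#' @param values Primary values.
#' @param aux_values Auxiliary values; length `nrow(coords)` when
#'   `aux_coords` is `NULL` (collocated), else length `nrow(aux_coords)`.
#' @param lmc An [lmc_model()].
#' @param target Length-2 coordinate of the prediction point.
#' @param aux_coords Optional auxiliary coordinates (default: collocated).
#' @param method Distance metric.
#' @return A `kriging_prediction` list with `weights` (lambda), `mu`, and
#'   two Lagrange multipliers.
#' @export
ordinary_cokrige <- function(coords, values, aux_values, lmc, target,
                             aux_coords = NULL,
                             method = c("haversine", "euclidean")) {
  method <- match.arg(method)
  coords <- as.matrix(coords)
  if (is.null(aux_coords)) aux_coords <- coords
  aux_coords <- as.matrix(aux_coords)
  stopifnot(inherits(lmc, "lmc_model"),
            length(values) == nrow(coords),
            length(aux_values) == nrow(aux_coords))
  sol <- .ck_solve(coords, values, aux_coords, aux_values, lmc,
                   matrix(target, nrow = 1), method)
  structure(list(value = sol$pred[1], std_error = sqrt(sol$var[1]),
                 weights = drop(sol$weights), mu = drop(sol$mu),
                 lagrange = drop(sol$lagrange[1, ])),
            class = "kriging_prediction")
}

#' @export
print.kriging_prediction <- function(x, ...) {
  cat(sprintf("kriging prediction: %.4f +/- %.4f (std. error)\n",
              x$value, x$std_error))
  invisible(x)
}

#' Predict an isoscape grid
#'
#' Kriges every cell centre of a [grid_spec()] from the site data, by
#' ordinary kriging (`model` a [variogram_model()]) or ordinary co-kriging
#' (`model` an [lmc_model()], `aux_values` required).  The per-cell result
#' is identical to calling [ordinary_krige()] cell by cell; one shared
#' factorization makes the grid pass fast.  Cells farther than `max_dist`
#' km from the nearest site become nodata (count logged).
#'
#' @inheritParams ordinary_krige
#' @param grid A [grid_spec()].
#' @param aux_values Auxiliary values at the sites (co-kriging only).
#' @param max_dist Maximum extrapolation distance in km (default `Inf`).
#' @return An [isoscape_grid()] with prediction and std_error layers.
#' @export
predict_grid <- function(coords, values, model, grid, aux_values = NULL,
                         max_dist = Inf,
                         method = c("haversine", "euclidean")) {
  method <- match.arg(method)
  stopifnot(inherits(grid, "grid_spec"))
  coords <- as.matrix(coords)
  if (nrow(coords) < 1) stop("no sites")
  centers <- grid_cell_centers(grid)
  keep <- rep(TRUE, nrow(centers))
  if (is.finite(max_dist)) {
    dmin <- apply(dist_matrix(centers, coords, method = method), 1, min)
    keep <- dmin <= max_dist
    if (any(!keep)) {
      iso_log("info", "%d cell(s) beyond max_dist = %g km set to nodata",
              sum(!keep), max_dist)
    }
  }
  pred <- se <- rep(NA_real_, nrow(centers))
  if (any(keep)) {
    tg <- centers[keep, , drop = FALSE]
    sol <- if (inherits(model, "lmc_model")) {
      if (is.null(aux_values)) stop("co-kriging needs aux_values")
      .ck_solve(coords, values, coords, aux_values, model, tg, method)
    } else {
      .ok_solve(coords, values, model, tg, method)
    }
    pred[keep] <- sol$pred
    se[keep] <- sqrt(sol$var)
  }
  to_mat <- function(v) matrix(v, nrow = grid$n_rows, ncol = grid$n_cols,
                               byrow = TRUE)
  isoscape_grid(grid, to_mat(pred), std_error = to_mat(se))
}
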