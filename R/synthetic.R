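#' Synthetic coregionalized field specification
#'
#' Study conditions for the synthetic generator: a shared spatial structure
#' (family + effective range) with 2x2 nugget and sill coefficient matrices
#' for the delta-13C field and one covariate field, mean surfaces, and the
#' site-sampling/replicate-noise design.  Defaults emulate the statistical
#' structure the analysis assumes: strong spatial autocorrelation
#' (exponential structure with effective range comparable to the sampled
#' domain), a ~1 per-mil east-west gradient in delta-13C with total
#' field variance 0.09 per-mil^2 on top, covariate cross-correlation 0.6,
#' and 5 replicates per site with 0.1 per-mil replicate noise.
#'
#' @param grid A [grid_spec()] (default 30 x 30 cells of 0.04 degrees from
#'   (102, 26), roughly a 120 km square).
#' @param family Shared structure (default `"exponential"`).
#' @param range_param Shared effective range, km (default 150).
#' @param sill,nugget Length-3 `c(b11, b22, b12)` coefficient matrices
#'   (per-mil^2 for b11; the covariate field is unit-scaled).
#' @param d13c_base Mean delta-13C (default -24 per-mil).
#' @param gradient_west_east Total west-to-east drop of the mean surface
#'   across the grid, per-mil (default 1; the west edge is heavier).
#' @param n_sites Sites drawn by [sample_sites()] (default 60).
#' @param replicate_sd Within-site replicate noise sd, per-mil (default
#'   0.1).
#' @param replicate_n Replicates per site (default 5).
#' @param seed Mandatory RNG seed.
#' @return A `synthetic_field_spec` object.
#' @export
synthetic_field_spec <- function(grid = grid_spec(102, 26, 0.04, 30, 30),
                                 family = "exponential", range_param = 150,
                                 sill = c(b11 = 0.08, b22 = 0.99,
                                          b12 = 0.6 * sqrt(0.08 * 0.99)),
                                 nugget = c(b11 = 0.01, b22 = 0.01,
                                            b12 = 0),
                                 d13c_base = -24, gradient_west_east = 1,
                                 n_sites = 60, replicate_sd = 0.1,
                                 replicate_n = 5, seed) {
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    stop("seed is mandatory")
  }
  stopifnot(inherits(grid, "grid_spec"), replicate_sd >= 0,
            replicate_n >= 1)
  chk <- function(b) b[1] >= 0 && b[2] >= 0 && b[3]^2 <= b[1] * b[2] + 1e-12
  if (!chk(sill) || !chk(nugget)) {
    stop("sill and nugget matrices must be positive semi-definite")
  }
  if (grid$n_rows * grid$n_cols * 2 > 2e4) {
    stop("grid too large for dense simulation (cap 1e4 joint dimensions)")
  }
  structure(list(grid = grid, family = family, range_param = range_param,
                 sill = sill, nugget = nugget, d13c_base = d13c_base,
                 gradient_west_east = gradient_west_east, n_sites = n_sites,
                 replicate_sd = replicate_sd, replicate_n = replicate_n,
                 seed = as.integer(seed)),
            class = "synthetic_field_spec")
}

# joint dense simulation of the two fields at arbitrary points under the
# shared-structure covariance C_kl(h) = sill_kl (1 - g(h/a)) + nugget_kl 1(h=0)
.simulate_lmc_at <- function(coords, family, range_param, sill, nugget,
                             shape = NULL, method = "haversine") {
  tmpl <- variogram_model(family, 0, 1, range_param, shape = shape)
  sill <- unname(sill)      # positional (b11, b22, b12)
  nugget <- unname(nugget)
  n <- nrow(coords)
  D <- dist_matrix(coords, method = method)
  corr <- 1 - .g_decay(tmpl$family, D / range_param, tmpl$shape)
  eye <- diag(n)
  cross <- sill[3] * corr + nugget[3] * eye
  C <- rbind(cbind(sill[1] * corr + nugget[1] * eye, cross),
             cbind(cross, sill[2] * corr + nugget[2] * eye))
  if (max(abs(C)) == 0) {
    # degenerate spec (all sills and nuggets zero): the field is its mean
    return(list(z1 = numeric(n), z2 = numeric(n)))
  }
  L <- NULL
  jitter <- 0
  for (j in c(0, 1e-10, 1e-8, 1e-6)) {
    L <- tryCatch(chol(C + j * diag(2 * n)), error = function(e) NULL)
    if (!is.null(L)) { jitter <- j; break }
  }
  if (is.null(L)) stop("joint covariance is not positive semi-definite ",
                       "even after numerical jitter")
  if (jitter > 0) iso_log("info", "added %g jitter to the joint covariance",
                          jitter)
  z <- drop(crossprod(L, stats::rnorm(2 * n)))
  list(z1 = z[1:n], z2 = z[n + (1:n)])
}

#' Simulate a single Gaussian field at point locations
#'
#' Draws one realization of a zero-mean Gaussian random field with the
#' covariance implied by a semivariogram model (`C(h) = c0 + c - gamma(h)`)
#' at arbitrary coordinates, by dense Cholesky factorization.
#' Deterministic given `seed`.
#'
#' @param coords Two-column coordinates.
#' @param model A [variogram_model()] (bounded family).
#' @param seed RNG seed.
#' @param mean Constant or per-point mean added to the realization.
#' @param method Distance metric.
#' @return Numeric vector of field values.
#' @export
simulate_field <- function(coords, model, seed, mean = 0,
                           method = c("haversine", "euclidean")) {
  method <- match.arg(method)
  coords <- as.matrix(coords)
  .with_seed(seed, {
    z <- .simulate_lmc_at(coords, model$family, model$range_param,
                          sill = c(b11 = model$psill, b22 = 1, b12 = 0),
                          nugget = c(b11 = model$nugget, b22 = 1, b12 = 0),
                          shape = model$shape, method = method)$z1
    z + mean
  })
}

#' Simulate the coregionalized truth grids
#'
#' Draws one jointly Gaussian realization of the delta-13C field and the
#' covariate field on the spec's grid (dense factorization of the joint
#' covariance), adds the mean surfaces (base + linear west-to-east
#' gradient for delta-13C; zero for the unit-scaled covariate), and returns
#' both layers.  Deterministic given the spec's seed.
#'
#' @param spec A [synthetic_field_spec()].
#' @param method Distance metric.
#' @return List: `d13c` and `covariate` ([isoscape_grid()]s, prediction
#'   layer = truth), `spec`.
#' @export
simulate_coregionalized_field <- function(spec,
                                          method = c("haversine",
                                                     "euclidean")) {
  method <- match.arg(method)
  stopifnot(inherits(spec, "synthetic_field_spec"))
  g <- spec$grid
  centers <- grid_cell_centers(g)
  z <- .with_seed(spec$seed,
    .simulate_lmc_at(centers, spec$family, spec$range_param, spec$sill,
                     spec$nugget, method = method))
  xs <- centers[, 1]
  span <- max(xs) - min(xs)
  trend <- if (span > 0) {
    spec$d13c_base + spec$gradient_west_east * (0.5 - (xs - min(xs)) / span)
  } else rep(spec$d13c_base, length(xs))
  to_mat <- function(v) matrix(v, nrow = g$n_rows, ncol = g$n_cols,
                               byrow = TRUE)
  list(d13c = isoscape_grid(g, to_mat(z$z1 + trend)),
       covariate = isoscape_grid(g, to_mat(z$z2)),
       spec = spec)
}

#' Sample a synthetic site table from truth grids
#'
#' Picks `n_sites` distinct cells (uniformly at random, or a regular grid
#' design), reads the true delta-13C and covariate values, simulates
#' `replicate_n` specimens per site with `N(truth, replicate_sd)` noise, and
#' stores the replicate mean and sd.  The covariate layer is written to one
#' `bio` column (affine-scaled to a realistic range); the remaining
#' covariate columns are filled with independent noise so the table is
#' read-compatible with [read_site_table()].
#'
#' @param truth Result of [simulate_coregionalized_field()].
#' @param n_sites Number of sites (<= number of cells); default from the
#'   spec.
#' @param design `"random"` (default) or `"grid"` (evenly spaced cells).
#' @param replicate_sd,replicate_n Replicate noise; defaults from the spec.
#' @param seed RNG seed; default spec seed + 1.
#' @param aux_name Column receiving the covariate field (default
#'   `"bio15"`).
#' @param aux_scale Length-2 `c(center, scale)` affine transform applied to
#'   the unit covariate field (default `c(70, 9)`, a precipitation-
#'   seasonality-like range).
#' @return A validated `site_table`, with attribute `cells` (sampled cell
#'   indices, row-major from the top row).
#' @export
sample_sites <- function(truth, n_sites = NULL, design = c("random", "grid"),
                         replicate_sd = NULL, replicate_n = NULL,
                         seed = NULL, aux_name = "bio15",
                         aux_scale = c(70, 9)) {
  design <- match.arg(design)
  spec <- truth$spec
  if (is.null(n_sites)) n_sites <- spec$n_sites
  if (is.null(replicate_sd)) replicate_sd <- spec$replicate_sd
  if (is.null(replicate_n)) replicate_n <- spec$replicate_n
  if (is.null(seed)) seed <- spec$seed + 1L
  g <- spec$grid
  n_cells <- g$n_rows * g$n_cols
  if (n_sites > n_cells) {
    stop("n_sites (", n_sites, ") exceeds the cell count (", n_cells, ")")
  }
  centers <- grid_cell_centers(g)
  truth_d13c <- as.vector(t(truth$d13c$prediction))   # row-major, top row
  truth_cov <- as.vector(t(truth$covariate$prediction))
  .with_seed(seed, {
    cells <- if (design == "random") {
      sort(sample.int(n_cells, n_sites))
    } else {
      unique(round(seq(1, n_cells, length.out = n_sites)))
    }
    reps <- matrix(stats::rnorm(length(cells) * replicate_n,
                                mean = rep(truth_d13c[cells],
                                           each = replicate_n),
                                sd = replicate_sd),
                   nrow = replicate_n)
    site_mean <- colMeans(reps)
    site_sd <- if (replicate_n > 1) apply(reps, 2, stats::sd) else
      rep(0, length(cells))
    tab <- data.frame(
      site_id = sprintf("S%03d", seq_along(cells)),
      place = "synthetic",
      lon = centers[cells, 1], lat = centers[cells, 2],
      elevation_m = 500, d13c_mean = site_mean, d13c_sd = site_sd,
      n = replicate_n, stringsAsFactors = FALSE)
    for (b in bio_names()) {
      tab[[b]] <- if (b == aux_name) {
        aux_scale[1] + aux_scale[2] * truth_cov[cells]
      } else {
        stats::rnorm(length(cells))   # independent filler covariates
      }
    }
    out <- validate_site_table(tab)
    attr(out, "cells") <- cells
    out
  })
}

#' Packaged reference fixtures
#'
#' Returns the ten-site reference table (site-mean delta-13C plus 21
#' covariates) and the three validation samples shipped with the package.
#'
#' @return List: `sites` (validated `site_table`, 10 rows), `validation`
#'   (data frame of 3 samples: `sample_id`, `place`, `lon`, `lat`,
#'   `elevation_m`, `d13c`).
#' @export
make_fixture_table <- function() {
  sites <- read_site_table(system.file("extdata", "table2_sites.csv",
                                       package = "isokrig", mustWork = TRUE))
  validation <- utils::read.csv(
    system.file("extdata", "table9_samples.csv", package = "isokrig",
                mustWork = TRUE),
    stringsAsFactors = FALSE)
  list(sites = sites, validation = validation)
}
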