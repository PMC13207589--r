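#' Regular grid over the bounding box of a site table
#'
#' @param sites Site table (needs `lon`, `lat`).
#' @param cell_size Cell size in degrees (default 0.25).
#' @param pad Extra margin in cells around the bounding box (default 0).
#' @param nodata Sentinel (default -9999).
#' @return A [grid_spec()] covering all sites.
#' @export
bbox_grid <- function(sites, cell_size = 0.25, pad = 0, nodata = -9999) {
  lon <- sites$lon; lat <- sites$lat
  x0 <- min(lon) - pad * cell_size
  y0 <- min(lat) - pad * cell_size
  n_cols <- max(1L, ceiling((max(lon) - x0) / cell_size + 1e-9)) + pad
  n_rows <- max(1L, ceiling((max(lat) - y0) / cell_size + 1e-9)) + pad
  grid_spec(x0, y0, cell_size, n_rows, n_cols, nodata)
}

#' Run the full isoscape workflow
#'
#' Chains the whole traceability pipeline on a site table: (1) covariate
#' screening — Pearson collinearity screen of the temperature
#' (`bio1..bio11`) and precipitation (`bio12..bio19`) blocks, VIF of the
#' screened set plus CO2 and solar radiation, and correlation of all
#' candidates with delta-13C to pick the co-kriging auxiliary; (2) Moran's
#' I check of spatial structure; (3) cross-validated comparison of the
#' model-family catalog under co-kriging with the chosen auxiliary and
#' selection of the best family; (4) grid prediction over the site
#' bounding box; (5) Fisher-Jenks classification into `n_classes` regions;
#' (6) assignment of any validation samples.
#'
#' @param sites Validated site table.
#' @param validation Optional data frame of unknown samples (`sample_id`,
#'   `d13c`, optional `lon`/`lat`).
#' @param aux Auxiliary covariate; `NULL` (default) picks the top of the
#'   screened shortlist.
#' @param families Candidate model families (default all 11).
#' @param cell_size Grid cell size in degrees (default 0.25).
#' @param n_classes Jenks class count (default 3).
#' @param alpha Screening significance level (default 0.05).
#' @param max_dist Extrapolation limit in km (default `Inf`).
#' @param seed Seed for fitting starts and the Moran permutation test.
#' @param method Distance metric.
#' @return List: `screening` (blocks, vif, target correlation, aux),
#'   `moran`, `cv` (table, selected, models), `model`, `isoscape`
#'   (classified [isoscape_grid()]), `breaks`, `assignments`.
#' @export
build_isoscape <- function(sites, validation = NULL, aux = NULL,
                           families = variogram_families(),
                           cell_size = 0.25, n_classes = 3, alpha = 0.05,
                           max_dist = Inf, seed = 20240457,
                           method = c("haversine", "euclidean")) {
  method <- match.arg(method)
  sites <- validate_site_table(sites)
  coords <- as.matrix(sites[, c("lon", "lat")])

  temp_block <- select_by_collinearity(
    pearson_matrix(sites, paste0("bio", 1:11)), alpha = alpha)
  prec_block <- select_by_collinearity(
    pearson_matrix(sites, paste0("bio", 12:19)), alpha = alpha)
  screened <- unique(c(temp_block$passing, temp_block$representative,
                       prec_block$passing, prec_block$least_collinear,
                       prec_block$representative, "bio20", "bio21"))
  vif <- vif_table(sites, screened)
  target_cor <- correlate_with_target(
    sites, c("lon", "lat", "elevation_m", screened), alpha = alpha)
  shortlist <- setdiff(attr(target_cor, "shortlist"),
                       c("lon", "lat", "elevation_m"))
  if (is.null(aux)) {
    if (length(shortlist) == 0) {
      stop("no covariate is significantly correlated with d13c; ",
           "supply aux explicitly")
    }
    aux <- shortlist[1]
    iso_log("info", "auxiliary selected by screening: %s", aux)
  }

  moran <- morans_i(coords, sites$d13c_mean, n_perm = 999, seed = seed,
                    method = method)

  cv <- cv_model_catalog(sites, aux = aux, families = families,
                         method = method, seed = seed)
  model <- cv$models[[cv$selected]]

  grid <- bbox_grid(sites, cell_size = cell_size)
  iso <- predict_grid(coords, sites$d13c_mean, model, grid,
                      aux_values = sites[[aux]], max_dist = max_dist,
                      method = method)
  vals <- iso$prediction[!is.na(iso$prediction)]
  breaks <- jenks_breaks(vals, n_classes)
  iso <- classify_grid(iso, breaks)

  assignments <- NULL
  if (!is.null(validation)) {
    assignments <- lapply(seq_len(nrow(validation)), function(i) {
      co <- if (all(c("lon", "lat") %in% names(validation))) {
        c(validation$lon[i], validation$lat[i])
      } else NULL
      assign_sample(validation$sample_id[i], validation$d13c[i], iso,
                    breaks, coord = co)
    })
    names(assignments) <- validation$sample_id
  }

  list(
    screening = list(temperature = temp_block, precipitation = prec_block,
                     screened = screened, vif = vif,
                     target_correlation = target_cor, aux = aux),
    moran = moran, cv = cv[c("table", "selected")], models = cv$models,
    model = model, isoscape = iso, breaks = breaks,
    assignments = assignments
  )
}
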