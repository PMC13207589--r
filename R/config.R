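#' Pipeline configuration
#'
#' `iso_defaults()` returns the default settings used across the pipeline;
#' `read_config()` reads a flat key-value YAML file and merges it over the
#' defaults (unknown keys error, so typos are caught).
#'
#' Keys: `distance` ("haversine"/"euclidean"), `n_lags`, `lag_cutoff`
#' (km or NULL = half max distance), `families` (model catalog subset),
#' `alpha` (significance level for screening), `n_classes`, `cv_refit`
#' ("fixed"/"per_fold"), `max_dist` (km extrapolation limit, Inf = none),
#' `seed`.
#'
#' @param path YAML file path.
#' @return Named list of settings.
#' @export
iso_defaults <- function() {
  list(
    distance = "haversine",
    n_lags = 12L,
    lag_cutoff = NULL,
    families = variogram_families(),
    alpha = 0.05,
    n_classes = 3L,
    cv_refit = "fixed",
    max_dist = Inf,
    seed = 20240457L
  )
}

#' @rdname iso_defaults
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  defaults <- iso_defaults()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  utils::modifyList(defaults, cfg)
}
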