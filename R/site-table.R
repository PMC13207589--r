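#' Covariate column names
#'
#' The 21 covariates carried by a site table: the 19 WorldClim bioclimatic
#' variables `bio1`..`bio19`, plus `bio20` (CO2 concentration) and `bio21`
#' (solar radiation).
#'
#' @return Character vector of length 21.
#' @export
bio_names <- function() paste0("bio", 1:21)

.site_required_cols <- function() {
  c("site_id", "place", "lon", "lat", "elevation_m",
    "d13c_mean", "d13c_sd", "n", bio_names())
}

#' Validate a site table
#'
#' Checks the invariants of a table of sampling sites: coordinate ranges,
#' non-negative replicate standard deviations, at least one specimen per
#' site, presence of all 21 covariate columns (missing values are flagged
#' with a warning, never dropped), and plausibility of the delta-13C means
#' for a C3-plant food web (values outside -35..-15 per-mil warn, they do
#' not error).
#'
#' @param sites Data frame with the columns of [read_site_table()].
#' @return The validated data frame, with class `site_table`, invisibly
#'   usable as a plain data frame.
#' @export
validate_site_table <- function(sites) {
  sites <- as.data.frame(sites)
  req <- .site_required_cols()
  missing_cols <- setdiff(req, names(sites))
  if (length(missing_cols) > 0) {
    stop("site table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  num_cols <- setdiff(req, c("site_id", "place"))
  for (cl in num_cols) {
    if (!is.numeric(sites[[cl]])) {
      stop("site table column '", cl, "' is not numeric")
    }
  }
  bad_lat <- which(!is.na(sites$lat) & (sites$lat < -90 | sites$lat > 90))
  if (length(bad_lat) > 0) {
    stop("latitude out of range [-90, 90] in row(s): ",
         paste(bad_lat, collapse = ", "))
  }
  bad_lon <- which(!is.na(sites$lon) & (sites$lon < -180 | sites$lon > 180))
  if (length(bad_lon) > 0) {
    stop("longitude out of range [-180, 180] in row(s): ",
         paste(bad_lon, collapse = ", "))
  }
  if (any(sites$d13c_sd < 0, na.rm = TRUE)) {
    stop("d13c_sd must be >= 0")
  }
  if (any(sites$n < 1, na.rm = TRUE)) {
    stop("n (specimens per site) must be >= 1")
  }
  na_bio <- vapply(sites[bio_names()], function(x) sum(is.na(x)), 0L)
  if (any(na_bio > 0)) {
    warning("missing covariate values in: ",
            paste(names(na_bio)[na_bio > 0], collapse = ", "),
            " (flagged, not dropped)")
  }
  implaus <- which(sites$d13c_mean < -35 | sites$d13c_mean > -15)
  if (length(implaus) > 0) {
    warning("d13c_mean outside [-35, -15] per-mil (implausible for a ",
            "C3 food web) in row(s): ", paste(implaus, collapse = ", "))
  }
  class(sites) <- c("site_table", "data.frame")
  sites
}

#' Read a site table
#'
#' Reads a delimited site table (comma default, tab accepted) with a header
#' row naming at least `site_id, place, lon, lat, elevation_m, d13c_mean,
#' d13c_sd, n, bio1..bio21` and validates every row.  Some published site
#' lists print the longitude/latitude columns swapped; `swap_policy =
#' "auto_swap"` exchanges the two columns if and only if the swap makes all
#' rows valid, and logs that it did so.
#'
#' @param path File path.
#' @param swap_policy `"error"` (default): out-of-range coordinates are an
#'   error; `"auto_swap"`: swap lon/lat when that fixes every row.
#' @param sep Field separator; `","` default, `"\t"` accepted.
#' @return A validated `site_table` data frame.
#' @export
read_site_table <- function(path, swap_policy = c("error", "auto_swap"),
                            sep = ",") {
  swap_policy <- match.arg(swap_policy)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                         check.names = TRUE)
  names(raw) <- tolower(names(raw))
  req <- .site_required_cols()
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  num_cols <- setdiff(req, c("site_id", "place"))
  for (cl in num_cols) {
    x <- raw[[cl]]
    if (!is.numeric(x)) {
      conv <- suppressWarnings(as.numeric(x))
      bad <- which(is.na(conv) & !is.na(x) & x != "")
      if (length(bad) > 0) {
        stop("unparseable numeric in column '", cl, "', line(s): ",
             paste(bad + 1L, collapse = ", "))  # +1 for the header line
      }
      raw[[cl]] <- conv
    }
  }
  lat_ok <- function(x) all(is.na(x) | (x >= -90 & x <= 90))
  lon_ok <- function(x) all(is.na(x) | (x >= -180 & x <= 180))
  if (!lat_ok(raw$lat) || !lon_ok(raw$lon)) {
    if (swap_policy == "auto_swap" && lat_ok(raw$lon) && lon_ok(raw$lat)) {
      tmp <- raw$lat; raw$lat <- raw$lon; raw$lon <- tmp
      iso_log("warn", "lon/lat columns appear swapped; auto_swap exchanged them for all %d rows",
              nrow(raw))
    } else if (!lat_ok(raw$lat)) {
      stop("latitude out of range")
    } else {
      stop("longitude out of range")
    }
  }
  validate_site_table(raw)
}

#' Write a site table
#'
#' Inverse of [read_site_table()]: `read_site_table(write_site_table(x, f))`
#' is the identity on validated records.
#'
#' @param sites Validated site table.
#' @param path Output file path.
#' @param sep Field separator (default `","`).
#' @return `path`, invisibly.
#' @export
write_site_table <- function(sites, path, sep = ",") {
  sites <- validate_site_table(sites)
  utils::write.table(as.data.frame(sites)[, .site_required_cols()], path,
                     sep = sep, row.names = FALSE, quote = TRUE)
  invisible(path)
}
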