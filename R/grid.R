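#' Grid geometry
#'
#' Describes a regular lon/lat raster: lower-left corner, square cell size in
#' degrees, dimensions, and the nodata sentinel shared by all layers of one
#' grid (default -9999).
#'
#' @param x_origin,y_origin Lower-left corner (degrees).
#' @param cell_size Cell size (degrees), > 0.
#' @param n_rows,n_cols Dimensions, >= 1.
#' @param nodata Sentinel value for missing cells.
#' @return A `grid_spec` object.
#' @export
grid_spec <- function(x_origin, y_origin, cell_size, n_rows, n_cols,
                      nodata = -9999) {
  stopifnot(is.numeric(cell_size), cell_size > 0,
            n_rows >= 1, n_cols >= 1)
  structure(list(x_origin = as.numeric(x_origin),
                 y_origin = as.numeric(y_origin),
                 cell_size = as.numeric(cell_size),
                 n_rows = as.integer(n_rows),
                 n_cols = as.integer(n_cols),
                 nodata = as.numeric(nodata)),
            class = "grid_spec")
}

#' Cell-centre coordinates of a grid
#'
#' Returns an `n_rows*n_cols` by 2 matrix of `(lon, lat)` cell centres in
#' row-major order from the top row (matching the matrix layout used by
#' [isoscape_grid()] and the ESRI ASCII format).
#'
#' @param spec A [grid_spec()].
#' @return Two-column numeric matrix.
#' @export
grid_cell_centers <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  xs <- spec$x_origin + (seq_len(spec$n_cols) - 0.5) * spec$cell_size
  ys <- spec$y_origin + (spec$n_rows - seq_len(spec$n_rows) + 0.5) * spec$cell_size
  cbind(lon = rep(xs, times = spec$n_rows),
        lat = rep(ys, each = spec$n_cols))
}

#' Isoscape grid
#'
#' Bundles a prediction surface (per-mil), its kriging standard error
#' (per-mil, >= 0 where defined) and an optional integer class map on one
#' shared [grid_spec()].  Matrices are `n_rows` by `n_cols`, row 1 = top row.
#'
#' @param spec A [grid_spec()].
#' @param prediction Numeric matrix; `NA` marks nodata.
#' @param std_error Optional numeric matrix, same shape.
#' @param class_map Optional integer matrix, same shape.
#' @return An `isoscape_grid` object.
#' @export
isoscape_grid <- function(spec, prediction, std_error = NULL,
                          class_map = NULL) {
  stopifnot(inherits(spec, "grid_spec"))
  shape_ok <- function(m) is.matrix(m) &&
    nrow(m) == spec$n_rows && ncol(m) == spec$n_cols
  if (!shape_ok(prediction)) stop("prediction layer shape mismatch")
  if (!is.null(std_error)) {
    if (!shape_ok(std_error)) stop("std_error layer shape mismatch")
    if (any(std_error < 0, na.rm = TRUE)) stop("std_error must be >= 0")
  }
  if (!is.null(class_map) && !shape_ok(class_map)) {
    stop("class_map layer shape mismatch")
  }
  structure(list(spec = spec, prediction = prediction,
                 std_error = std_error, class_map = class_map),
            class = "isoscape_grid")
}

#' @export
print.isoscape_grid <- function(x, ...) {
  s <- x$spec
  cat(sprintf(
    "isoscape_grid: %d x %d cells of %g deg, origin (%g, %g)\n",
    s$n_rows, s$n_cols, s$cell_size, s$x_origin, s$y_origin))
  v <- x$prediction[!is.na(x$prediction)]
  if (length(v)) {
    cat(sprintf("  prediction: [%.4f, %.4f] per-mil, %d nodata cells\n",
                min(v), max(v), sum(is.na(x$prediction))))
  }
  if (!is.null(x$class_map)) {
    cat("  classes:", paste(sort(unique(stats::na.omit(c(x$class_map)))),
                            collapse = " "), "\n")
  }
  invisible(x)
}

# --- ESRI ASCII grid (single layer) ---------------------------------------

.write_asc_layer <- function(mat, spec, path) {
  hdr <- c(
    sprintf("ncols %d", spec$n_cols),
    sprintf("nrows %d", spec$n_rows),
    sprintf("xllcorner %.10g", spec$x_origin),
    sprintf("yllcorner %.10g", spec$y_origin),
    sprintf("cellsize %.10g", spec$cell_size),
    sprintf("NODATA_value %.10g", spec$nodata)
  )
  m <- mat
  m[is.na(m)] <- spec$nodata
  rows <- apply(m, 1, function(r) paste(sprintf("%.10g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

.read_asc_layer <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 7) stop("malformed ESRI ASCII grid: too few lines")
  hdr <- list()
  for (i in 1:6) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) != 2) stop("malformed ESRI ASCII header line: ", lines[i])
    hdr[[tolower(tok[1])]] <- as.numeric(tok[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% names(hdr)) || any(is.na(unlist(hdr[need])))) {
    stop("malformed ESRI ASCII header")
  }
  body <- lines[-(1:6)]
  body <- body[nzchar(trimws(body))]
  vals <- scan(text = paste(body, collapse = "\n"), quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    stop("malformed ESRI ASCII grid: expected ", hdr$ncols * hdr$nrows,
         " cells, found ", length(vals))
  }
  mat <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  mat[mat == hdr$nodata_value] <- NA
  list(mat = mat,
       spec = grid_spec(hdr$xllcorner, hdr$yllcorner, hdr$cellsize,
                        hdr$nrows, hdr$ncols, hdr$nodata_value))
}

#' Write / read an isoscape grid as ESRI ASCII
#'
#' `write_grid()` writes the prediction layer to `path` and, when present,
#' the standard-error and class layers to companion files with `_se` and
#' `_class` suffixes.  `read_grid()` reassembles whatever companions exist.
#' A write/read round trip reproduces values to 1e-6 and the geometry
#' exactly; `NA` cells travel as the `NODATA_value` sentinel.
#'
#' @param grid An [isoscape_grid()].
#' @param path Output `.asc` path (prediction layer).
#' @return `write_grid()`: the paths written, invisibly. `read_grid()`: an
#'   `isoscape_grid`.
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "isoscape_grid"))
  paths <- .write_asc_layer(grid$prediction, grid$spec, path)
  stem <- sub("\\.asc$", "", path)
  if (!is.null(grid$std_error)) {
    paths <- c(paths, .write_asc_layer(grid$std_error, grid$spec,
                                       paste0(stem, "_se.asc")))
  }
  if (!is.null(grid$class_map)) {
    paths <- c(paths, .write_asc_layer(grid$class_map, grid$spec,
                                       paste0(stem, "_class.asc")))
  }
  invisible(paths)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  pred <- .read_asc_layer(path)
  stem <- sub("\\.asc$", "", path)
  se_path <- paste0(stem, "_se.asc")
  cl_path <- paste0(stem, "_class.asc")
  se <- if (file.exists(se_path)) .read_asc_layer(se_path)$mat else NULL
  cl <- if (file.exists(cl_path)) {
    m <- .read_asc_layer(cl_path)$mat
    storage.mode(m) <- "integer"
    m
  } else NULL
  isoscape_grid(pred$spec, pred$mat, std_error = se, class_map = cl)
}
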