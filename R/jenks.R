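#' Fisher-Jenks natural breaks
#'
#' Exact dynamic-programming partition of one-dimensional values into `k`
#' classes minimizing the total within-class sum of squared deviations
#' (SDCM).  Deterministic; equals exhaustive search over all contiguous
#' partitions of the sorted data.
#'
#' Break intervals are lower-open / upper-closed, with the lowest interval
#' closed at both ends: a value `v` is in class `j` when
#' `breaks[j] < v <= breaks[j+1]` (and `breaks[1] <= v` for `j = 1`).
#'
#' @param values Numeric vector with at least `k` distinct values.
#' @param k Number of classes (>= 1).
#' @param labels Optional class labels; default `"low"`,... ,`"high"` for
#'   `k = 3`, otherwise `"class_1"`..., ordered by numeric value.
#' @return A `class_breaks` object: `k`, `breaks` (length `k + 1`, strictly
#'   increasing), `labels`, `goodness` (SDCM).
#' @examples
#' jenks_breaks(c(1, 2, 3, 10, 11, 12), 2)$breaks  # splits at the gap
#' @export
jenks_breaks <- function(values, k, labels = NULL) {
  values <- values[!is.na(values)]
  if (k < 1) stop("k must be >= 1")
  n_distinct <- length(unique(values))
  if (n_distinct < k) {
    stop("k (", k, ") exceeds the number of distinct values (", n_distinct,
         ")")
  }
  # run the DP over the distinct sorted values with multiplicity weights:
  # tied observations can never be split across classes, and the resulting
  # class boundaries are strictly increasing
  r <- rle(sort(values))
  x <- r$values
  w <- as.numeric(r$lengths)
  n <- length(x)
  s0 <- cumsum(w)
  s1 <- cumsum(w * x)
  s2 <- cumsum(w * x^2)
  # weighted ssq of x[a..b], 1-based inclusive, vectorized over a
  ssq <- function(a, b) {
    m <- s0[b] - c(0, s0)[a]
    sa1 <- s1[b] - c(0, s1)[a]
    sa2 <- s2[b] - c(0, s2)[a]
    pmax(sa2 - sa1^2 / m, 0)
  }
  # D[j, i]: min SDCM of x[1..i] in j classes; B[j, i]: first index of the
  # last class at the optimum
  D <- matrix(Inf, k, n)
  B <- matrix(1L, k, n)
  D[1, ] <- ssq(rep(1L, n), seq_len(n))
  if (k >= 2) {
    for (j in 2:k) {
      for (i in j:n) {
        m <- j:i  # candidate first index of the last class
        tot <- D[j - 1, m - 1] + ssq(m, rep(i, length(m)))
        best <- which.min(tot)
        D[j, i] <- tot[best]
        B[j, i] <- m[best]
      }
    }
  }
  # recover class boundaries
  upper <- integer(k)
  i <- n
  for (j in k:1) {
    upper[j] <- i
    i <- B[j, i] - 1L
  }
  # boundaries: data extremes at the ends, midpoints between adjacent
  # class extremes inside, so the breaks are strictly increasing and each
  # (lower-open, upper-closed] interval contains exactly its class
  inner <- if (k > 1) (x[upper[-k]] + x[upper[-k] + 1]) / 2 else numeric(0)
  breaks <- c(x[1], inner, x[n])
  stopifnot(all(diff(breaks) > 0))
  if (is.null(labels)) {
    labels <- if (k == 3) c("low", "medium", "high")
              else if (k == 1) "all"
              else paste0("class_", seq_len(k))
  }
  stopifnot(length(labels) == k)
  structure(list(k = as.integer(k), breaks = breaks, labels = labels,
                 goodness = D[k, n]),
            class = "class_breaks")
}

#' @export
print.class_breaks <- function(x, ...) {
  iv <- paste(sprintf("(%.4g, %.4g] %s", utils::head(x$breaks, -1),
                      x$breaks[-1], x$labels), collapse = "  ")
  cat(sprintf("class_breaks k = %d, SDCM = %.6g\n  %s\n", x$k, x$goodness,
              iv))
  invisible(x)
}

# class index (1..k) of values under breaks; values outside clamp to the
# end classes; returns list(idx, n_clamped)
.classify_values <- function(v, breaks) {
  k <- length(breaks) - 1
  idx <- findInterval(v, breaks, left.open = TRUE, rightmost.closed = FALSE)
  # findInterval(left.open): idx j means breaks[j] < v <= breaks[j+1];
  # v <= breaks[1] -> 0, v > breaks[k+1] -> k+1
  low <- !is.na(v) & v < breaks[1]
  high <- !is.na(v) & v > breaks[k + 1]
  idx[!is.na(v) & v == breaks[1]] <- 1L  # lowest interval closed both ends
  idx[low] <- 1L
  idx[high] <- k
  idx[is.na(v)] <- NA_integer_
  list(idx = as.integer(idx), n_clamped = sum(low) + sum(high))
}

#' Classify an isoscape grid
#'
#' Fills the `class_map` layer: every non-nodata cell gets the index
#' (1-based) of its break interval; values outside `[breaks[1],
#' breaks[k+1]]` clamp to the end classes (count logged).  Idempotent.
#'
#' @param grid An [isoscape_grid()].
#' @param breaks A [jenks_breaks()] result (or any `class_breaks`).
#' @return The grid with `class_map` filled.
#' @export
classify_grid <- function(grid, breaks) {
  stopifnot(inherits(grid, "isoscape_grid"), inherits(breaks, "class_breaks"))
  cl <- .classify_values(c(grid$prediction), breaks$breaks)
  if (cl$n_clamped > 0) {
    iso_log("info", "%d cell(s) outside the break range clamped to end classes",
            cl$n_clamped)
  }
  grid$class_map <- matrix(cl$idx, nrow = grid$spec$n_rows,
                           ncol = grid$spec$n_cols)
  grid
}

#' Assign an unknown sample to the isoscape
#'
#' Places a measured delta-13C value in the classified isoscape: its class
#' under the breaks, the fraction of non-nodata grid cells sharing that
#' class (`compatible_fraction`), and, when a hypothesized coordinate is
#' given, the consistency z-score `(observed - predicted) / std_error` at
#' that location's cell.  A value outside the grid's overall prediction
#' range is flagged out-of-range with `compatible_fraction` 0.
#'
#' @param sample_id Label for the sample.
#' @param d13c Measured value (per-mil).
#' @param grid A classified [isoscape_grid()] (see [classify_grid()]).
#' @param breaks The [jenks_breaks()] used to classify the grid.
#' @param coord Optional `(lon, lat)` hypothesized origin.
#' @param tolerance Optional per-mil half-width: when given,
#'   `compatible_fraction` counts cells with `|prediction - d13c| <=
#'   tolerance` instead of class membership.
#' @return An `assignment_result` list: `sample_id`, `d13c`, `class_index`
#'   (1-based or `NA` when out of range), `label`, `compatible_fraction`,
#'   `out_of_range`, and optionally `z_score`, `predicted`, `pred_std_error`.
#' @export
assign_sample <- function(sample_id, d13c, grid, breaks, coord = NULL,
                          tolerance = NULL) {
  stopifnot(inherits(grid, "isoscape_grid"), inherits(breaks, "class_breaks"))
  if (is.null(grid$class_map)) stop("grid is not classified; run classify_grid()")
  vals <- c(grid$prediction)
  cls <- c(grid$class_map)
  ok <- !is.na(vals)
  rng <- range(vals[ok])
  out_of_range <- d13c < rng[1] || d13c > rng[2]
  idx <- .classify_values(d13c, breaks$breaks)$idx
  compatible <- if (out_of_range) {
    0
  } else if (!is.null(tolerance)) {
    mean(abs(vals[ok] - d13c) <= tolerance)
  } else {
    mean(cls[ok] == idx)
  }
  res <- list(sample_id = sample_id, d13c = d13c,
              class_index = if (out_of_range) NA_integer_ else idx,
              label = if (out_of_range) "out of range"
                      else breaks$labels[idx],
              compatible_fraction = compatible,
              out_of_range = out_of_range)
  if (!is.null(coord)) {
    s <- grid$spec
    col <- floor((coord[1] - s$x_origin) / s$cell_size) + 1
    row <- s$n_rows - floor((coord[2] - s$y_origin) / s$cell_size)
    if (col >= 1 && col <= s$n_cols && row >= 1 && row <= s$n_rows &&
        !is.na(grid$prediction[row, col])) {
      p <- grid$prediction[row, col]
      se <- grid$std_error[row, col]
      res$predicted <- p
      res$pred_std_error <- se
      res$z_score <- if (!is.na(se) && se > 0) (d13c - p) / se
                     else if (!is.na(se) && d13c == p) 0
                     else NA_real_
    } else {
      iso_log("warn", "hypothesized coordinate for %s outside the grid",
              sample_id)
    }
  }
  structure(res, class = "assignment_result")
}

#' @export
print.assignment_result <- function(x, ...) {
  cat(sprintf(
    "sample %s: d13C %.4f -> class %s (%s), compatible fraction %.3f%s\n",
    x$sample_id, x$d13c,
    ifelse(is.na(x$class_index), "NA", x$class_index), x$label,
    x$compatible_fraction,
    if (!is.null(x$z_score)) sprintf(", z = %.3f", x$z_score) else ""))
  invisible(x)
}
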