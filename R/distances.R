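#' Pairwise site distances
#'
#' Distances between coordinate pairs, in kilometres.  Geographic coordinates
#' (degrees) use the haversine great-circle formula on a sphere of radius
#' 6371.0 km; projected/planar inputs can use plain Euclidean distance, in
#' which case the coordinate units are taken to be kilometres already.
#'
#' @param coords Two-column matrix or data frame, columns `(lon, lat)` in
#'   degrees (haversine) or `(x, y)` in km (euclidean).
#' @param coords2 Optional second coordinate set; defaults to `coords`
#'   (square matrix of all pairs).
#' @param method `"haversine"` (default) or `"euclidean"`.
#' @return Matrix of distances in km, `nrow(coords)` by `nrow(coords2)`.
#' @examples
#' dist_matrix(cbind(c(0, 1), c(0, 0)))  # ~111.2 km apart on the equator
#' @export
dist_matrix <- function(coords, coords2 = coords,
                        method = c("haversine", "euclidean")) {
  method <- match.arg(method)
  coords <- as.matrix(coords)
  coords2 <- as.matrix(coords2)
  stopifnot(ncol(coords) == 2, ncol(coords2) == 2)
  storage.mode(coords) <- "double"
  storage.mode(coords2) <- "double"
  if (method == "haversine") {
    # geosphere returns metres; radius fixed at 6371.0 km
    d <- geosphere::distm(coords, coords2,
      fun = function(p1, p2) geosphere::distHaversine(p1, p2, r = 6371000)
    ) / 1000
  } else {
    d <- sqrt(outer(coords[, 1], coords2[, 1], "-")^2 +
              outer(coords[, 2], coords2[, 2], "-")^2)
  }
  unname(d)
}
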