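# Inverse-distance-weighted interpolation of a population statistic onto a
# geographic grid.  This is a documented, reproducible replacement for
# proprietary contour-map interpolation: the value at a grid node is the
# distance-weighted mean of the data values with weights d^(-power), and
# the surface interpolates the data exactly and never leaves the data
# range.

#' Inverse-distance-weighted affinity surface
#'
#' Interpolates a per-population value (e.g. percent carriers of query
#' haplotypes, or FST against the query) onto a regular longitude/latitude
#' grid.  Distances are great-circle (haversine) kilometres.  A node
#' coinciding with a data point takes that point's value exactly;
#' coincident data points with different values are averaged with a
#' warning.  Populations without clear geography must be excluded by the
#' caller.
#'
#' @param points Data frame with columns `lat`, `lon`, `value` (one row
#'   per geographically anchored population; >= 3 rows).
#' @param grid List with `lon = c(min, max)`, `lat = c(min, max)` and `n`
#'   (nodes per axis, default 50).
#' @param power IDW exponent (default 2).
#' @return Data frame with columns `lon`, `lat`, `value` for every grid
#'   node.
#' @export
idw_surface <- function(points, grid = NULL, power = 2) {
  stopifnot(is.data.frame(points),
            all(c("lat", "lon", "value") %in% names(points)))
  if (nrow(points) < 3L) stop("idw_surface() needs >= 3 data points")
  key <- paste(points$lon, points$lat)
  if (anyDuplicated(key)) {
    warning("coincident data points averaged")
    agg <- stats::aggregate(value ~ lon + lat, data = points, FUN = mean)
    points <- agg
  }
  if (is.null(grid)) {
    grid <- list(lon = range(points$lon), lat = range(points$lat), n = 50L)
  }
  if (is.null(grid$n)) grid$n <- 50L
  lon_seq <- seq(grid$lon[1], grid$lon[2], length.out = grid$n)
  lat_seq <- seq(grid$lat[1], grid$lat[2], length.out = grid$n)
  nodes <- expand.grid(lon = lon_seq, lat = lat_seq,
                       KEEP.OUT.ATTRS = FALSE)
  d <- geosphere::distm(as.matrix(nodes),
                        as.matrix(points[c("lon", "lat")]),
                        fun = geosphere::distHaversine) / 1000
  w <- d^(-power)
  exact <- d == 0
  value <- as.vector((w %*% points$value) / rowSums(w))
  if (any(exact)) {
    hit <- which(exact, arr.ind = TRUE)
    value[hit[, 1]] <- points$value[hit[, 2]]
  }
  nodes$value <- value
  nodes
}
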