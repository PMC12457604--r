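#' Morphological city boundary polygon
#'
#' One city footprint with identifying attributes. Geometry is a (multi)
#' polygon in lon/lat: a list of *parts*, each part a list of rings (first
#' ring the outer boundary, any further rings holes), each ring a closed
#' two-column matrix of (lon, lat) vertices. The cell set of a multi-part
#' boundary is the union over its parts.
#'
#' @param city_id unique text id.
#' @param name city name.
#' @param continent one of Africa, Asia, Europe, North America,
#'   South America, Oceania.
#' @param polygon a single ring matrix, a list of rings (one part), or a
#'   list of parts (each a list of rings). Open rings are closed
#'   automatically.
#' @param crs_id CRS identifier, must match the grids it is used with.
#' @return An object of class `city_boundary`.
#' @export
city_boundary <- function(city_id, name, continent, polygon,
                          crs_id = "EPSG:4326") {
  continents <- c("Africa", "Asia", "Europe", "North America",
                  "South America", "Oceania")
  if (!continent %in% continents)
    stop("continent must be one of: ", paste(continents, collapse = ", "),
         " (got '", continent, "')")
  parts <- normalize_parts(polygon)
  for (p in parts) {
    a <- ring_area(p[[1L]])
    if (a <= 0) stop("outer ring of city '", city_id, "' has zero area")
  }
  structure(list(city_id = as.character(city_id), name = as.character(name),
                 continent = continent, parts = parts, crs_id = crs_id),
            class = "city_boundary")
}

# Coerce the accepted polygon formats to list-of-parts-of-rings, each ring a
# closed numeric matrix.
normalize_parts <- function(polygon) {
  close_ring <- function(r) {
    r <- as.matrix(r)
    if (ncol(r) != 2L) stop("rings must be two-column (lon, lat) matrices")
    storage.mode(r) <- "double"
    if (nrow(r) < 3L) stop("rings need at least 3 vertices")
    if (!isTRUE(all.equal(r[1L, ], r[nrow(r), ], check.attributes = FALSE)))
      r <- rbind(r, r[1L, ])
    if (nrow(r) < 4L) stop("invalid ring: fewer than 3 distinct vertices")
    r
  }
  if (is.matrix(polygon) || is.data.frame(polygon))
    return(list(list(close_ring(polygon))))
  if (is.list(polygon) && length(polygon) &&
      (is.matrix(polygon[[1L]]) || is.data.frame(polygon[[1L]])))
    return(list(lapply(polygon, close_ring)))
  if (is.list(polygon) && length(polygon) && is.list(polygon[[1L]]))
    return(lapply(polygon, function(p) lapply(p, close_ring)))
  stop("polygon must be a ring matrix, a list of rings, or a list of parts")
}

# Signed shoelace area of a closed ring (absolute value returned).
ring_area <- function(r) {
  n <- nrow(r)
  x <- r[, 1L]; y <- r[, 2L]
  abs(sum(x[-n] * y[-1L] - x[-1L] * y[-n])) / 2
}

#' @export
print.city_boundary <- function(x, ...) {
  cat(sprintf("<city_boundary> %s (%s, %s): %d part(s)\n",
              x$city_id, x$name, x$continent, length(x$parts)))
  invisible(x)
}

# --- point-in-polygon primitives ------------------------------------------

# Points exactly on a ring edge count as INSIDE (documented convention): a
# cell center on a boundary line is assigned to the city. Interior test is
# even-odd ray casting over all rings of a part, so holes are handled
# automatically.

# For each point, TRUE if it lies on any edge of the ring (within eps).
points_on_ring <- function(px, py, ring, eps = 1e-12) {
  n <- nrow(ring)
  on <- rep(FALSE, length(px))
  for (k in seq_len(n - 1L)) {
    x1 <- ring[k, 1L]; y1 <- ring[k, 2L]
    x2 <- ring[k + 1L, 1L]; y2 <- ring[k + 1L, 2L]
    cross <- (px - x1) * (y2 - y1) - (py - y1) * (x2 - x1)
    scale <- max(abs(c(x1, y1, x2, y2, 1)))
    coll <- abs(cross) <= eps * scale * scale
    within <- px >= pmin(x1, x2) - eps & px <= pmax(x1, x2) + eps &
      py >= pmin(y1, y2) - eps & py <= pmax(y1, y2) + eps
    on <- on | (coll & within)
  }
  on
}

# Even-odd crossing parity of points against one ring.
ring_crossings <- function(px, py, ring) {
  n <- nrow(ring)
  crossings <- integer(length(px))
  for (k in seq_len(n - 1L)) {
    x1 <- ring[k, 1L]; y1 <- ring[k, 2L]
    x2 <- ring[k + 1L, 1L]; y2 <- ring[k + 1L, 2L]
    straddles <- (y1 > py) != (y2 > py)
    if (any(straddles)) {
      xint <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      crossings <- crossings + as.integer(straddles & px < xint)
    }
  }
  crossings
}

# Inclusion of points in one multi-ring part (outer + holes), edge-inclusive.
points_in_part <- function(px, py, rings) {
  on_edge <- rep(FALSE, length(px))
  parity <- integer(length(px))
  for (r in rings) {
    on_edge <- on_edge | points_on_ring(px, py, r)
    parity <- parity + ring_crossings(px, py, r)
  }
  on_edge | (parity %% 2L == 1L)
}

#' Test points against a city boundary
#'
#' Edge-inclusive containment: points exactly on a ring edge are inside.
#' A point is inside a multi-part boundary if it is inside any part.
#'
#' @param boundary a [city_boundary()].
#' @param lon,lat numeric vectors of point coordinates.
#' @return Logical vector.
#' @export
points_in_boundary <- function(boundary, lon, lat) {
  inside <- rep(FALSE, length(lon))
  for (p in boundary$parts)
    inside <- inside | points_in_part(lon, lat, p)
  inside
}

#' Grid cells whose centers fall inside a boundary
#'
#' The pipeline's single cell-inclusion rule: a cell belongs to a city iff
#' its *center* lies inside (or exactly on the edge of) the city polygon.
#' Center containment guarantees each cell joins at most one city in a
#' non-overlapping boundary set, so population and GDP sums never
#' double-count. Only cells whose centers fall in the polygon's bounding box
#' are tested; the result is ordered row-major.
#'
#' @param grid a [geo_grid()] or [class_grid()].
#' @param boundary a [city_boundary()]; must share `crs_id` with the grid.
#' @return Integer matrix with columns `row`, `col` (possibly zero rows).
#' @export
cell_centers_in_polygon <- function(grid, boundary) {
  if (!identical(grid$crs_id, boundary$crs_id))
    stop("CRS mismatch: grid is '", grid$crs_id, "', boundary '",
         boundary$city_id, "' is '", boundary$crs_id,
         "'; reprojection is not supported")
  xs <- vapply(boundary$parts, function(p) range(p[[1L]][, 1L]), numeric(2))
  ys <- vapply(boundary$parts, function(p) range(p[[1L]][, 2L]), numeric(2))
  bbox <- c(min(xs), max(xs), min(ys), max(ys))
  # candidate rows/cols: centers within the bbox (inclusive, eps-padded)
  eps <- 1e-9
  col_lo <- max(1L, ceiling((bbox[1L] - grid$origin_lon) / grid$cell_size_lon + 0.5 - eps))
  col_hi <- min(grid$n_cols, floor((bbox[2L] - grid$origin_lon) / grid$cell_size_lon + 0.5 + eps))
  row_lo <- max(1L, ceiling((grid$origin_lat - bbox[4L]) / grid$cell_size_lat + 0.5 - eps))
  row_hi <- min(grid$n_rows, floor((grid$origin_lat - bbox[3L]) / grid$cell_size_lat + 0.5 + eps))
  empty <- matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("row", "col")))
  if (col_lo > col_hi || row_lo > row_hi) return(empty)
  rows <- row_lo:row_hi
  cols <- col_lo:col_hi
  # row-major ordering: row varies slowest
  rr <- rep(rows, each = length(cols))
  cc <- rep(cols, times = length(rows))
  ctr <- cell_center(grid, rr, cc)
  keep <- points_in_boundary(boundary, ctr[, 1L], ctr[, 2L])
  if (!any(keep)) return(empty)
  cbind(row = rr[keep], col = cc[keep])
}

# Values of a grid at an index matrix from cell_centers_in_polygon().
grid_values_at <- function(grid, idx) {
  if (nrow(idx) == 0L) return(grid$values[0L])
  grid$values[cbind(idx[, "row"], idx[, "col"])]
}
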