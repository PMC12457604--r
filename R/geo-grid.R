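#' Georeferenced continuous raster grid
#'
#' A `geo_grid` holds a regular north-up raster in geographic (lon/lat)
#' coordinates. Row 1 is the northernmost row and the origin is the
#' *northwest corner* of the grid; the center of cell `(i, j)` (1-based) is
#' `origin_lon + (j - 0.5) * cell_size_lon`,
#' `origin_lat - (i - 0.5) * cell_size_lat`.
#' Nodata cells are stored as `NA`; `nodata` is only the file sentinel used
#' on disk.
#'
#' @param values numeric matrix (rows north to south).
#' @param origin_lon,origin_lat northwest corner, decimal degrees.
#' @param cell_size_lon,cell_size_lat positive cell sizes, decimal degrees.
#' @param nodata sentinel written to / read from disk for `NA` cells.
#' @param crs_id text identifier of the geographic CRS (default
#'   `"EPSG:4326"`). Grids and boundaries must agree; there is no
#'   reprojection.
#' @return An object of class `geo_grid`.
#' @examples
#' g <- geo_grid(matrix(1:12, 3, 4), origin_lon = 0, origin_lat = 3,
#'               cell_size_lon = 1, cell_size_lat = 1)
#' cell_center(g, 1, 1)  # (0.5, 2.5)
#' @export
geo_grid <- function(values, origin_lon, origin_lat,
                     cell_size_lon, cell_size_lat,
                     nodata = -9999, crs_id = "EPSG:4326") {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  g <- structure(
    list(origin_lon = as.numeric(origin_lon),
         origin_lat = as.numeric(origin_lat),
         cell_size_lon = as.numeric(cell_size_lon),
         cell_size_lat = as.numeric(cell_size_lat),
         n_rows = nrow(values), n_cols = ncol(values),
         values = values, nodata = nodata, crs_id = crs_id),
    class = "geo_grid")
  validate_grid(g)
  g
}

#' Georeferenced categorical raster grid
#'
#' Like [geo_grid()] but holding integer class codes, used for Local Climate
#' Zone (LCZ) maps. Built classes are coded 1-10 and natural classes A-G are
#' coded 11-17 (A = 11 ... G = 17). Unclassified cells are `NA` internally
#' and `nodata_code` on disk.
#'
#' @inheritParams geo_grid
#' @param values integer matrix of class codes.
#' @param nodata_code integer sentinel for unclassified cells.
#' @param code_table named character vector mapping code to label; defaults
#'   to the 17 standard LCZ classes ([lcz_code_table()]).
#' @return An object of class `class_grid` (also inherits `geo_grid`
#'   georeferencing semantics).
#' @export
class_grid <- function(values, origin_lon, origin_lat,
                       cell_size_lon, cell_size_lat,
                       nodata_code = 0L, code_table = lcz_code_table(),
                       crs_id = "EPSG:4326") {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "integer"
  values[values == as.integer(nodata_code)] <- NA_integer_
  g <- structure(
    list(origin_lon = as.numeric(origin_lon),
         origin_lat = as.numeric(origin_lat),
         cell_size_lon = as.numeric(cell_size_lon),
         cell_size_lat = as.numeric(cell_size_lat),
         n_rows = nrow(values), n_cols = ncol(values),
         values = values, nodata_code = as.integer(nodata_code),
         code_table = code_table, crs_id = crs_id),
    class = c("class_grid", "geo_grid"))
  validate_grid(g)
  codes <- unique(g$values[!is.na(g$values)])
  unknown <- setdiff(codes, as.integer(names(code_table)))
  if (length(unknown))
    stop("class codes not in code_table: ", paste(unknown, collapse = ", "))
  g
}

validate_grid <- function(g) {
  if (g$cell_size_lon <= 0 || g$cell_size_lat <= 0)
    stop("cell sizes must be positive")
  if (g$n_rows < 1 || g$n_cols < 1)
    stop("grid must have at least one row and one column")
  if (!inherits(g, "class_grid")) {
    v <- g$values[!is.na(g$values)]
    if (any(!is.finite(v)))
      stop("non-nodata grid values must be finite")
  }
  invisible(g)
}

#' Standard LCZ code table
#'
#' The 17-class Local Climate Zone typology: built classes 1-10 and natural
#' classes A-G encoded as 11-17.
#'
#' @return Named character vector; names are the integer codes `"1"`-`"17"`,
#'   values the LCZ labels.
#' @export
lcz_code_table <- function() {
  c("1" = "LCZ 1 compact high-rise",  "2" = "LCZ 2 compact mid-rise",
    "3" = "LCZ 3 compact low-rise",   "4" = "LCZ 4 open high-rise",
    "5" = "LCZ 5 open mid-rise",      "6" = "LCZ 6 open low-rise",
    "7" = "LCZ 7 lightweight low-rise", "8" = "LCZ 8 large low-rise",
    "9" = "LCZ 9 sparsely built",     "10" = "LCZ 10 heavy industry",
    "11" = "LCZ A dense trees",       "12" = "LCZ B scattered trees",
    "13" = "LCZ C bush, scrub",       "14" = "LCZ D low plants",
    "15" = "LCZ E bare rock or paved", "16" = "LCZ F bare soil or sand",
    "17" = "LCZ G water")
}

#' Cell center coordinates
#'
#' @param grid a [geo_grid()] or [class_grid()].
#' @param row,col 1-based cell indices (vectors allowed).
#' @return A two-column matrix of (lon, lat) centers.
#' @export
cell_center <- function(grid, row, col) {
  cbind(lon = grid$origin_lon + (col - 0.5) * grid$cell_size_lon,
        lat = grid$origin_lat - (row - 0.5) * grid$cell_size_lat)
}

#' @export
print.geo_grid <- function(x, ...) {
  kind <- if (inherits(x, "class_grid")) "class_grid" else "geo_grid"
  cat(sprintf("<%s> %d x %d cells, cell size %g x %g deg, %s\n",
              kind, x$n_rows, x$n_cols, x$cell_size_lon, x$cell_size_lat,
              x$crs_id))
  cat(sprintf("  NW origin (%g, %g); %d nodata cells\n",
              x$origin_lon, x$origin_lat, sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.geo_grid <- function(x) c(x$n_rows, x$n_cols)
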