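#' Read a raster from an ESRI ASCII grid file
#'
#' Rasters are exchanged as ESRI ASCII grids (`.asc`) — the plain-text
#' raster format understood by GDAL, QGIS and ArcGIS. The header carries
#' `ncols`, `nrows`, the lower-left corner, the cell size (either a single
#' `cellsize` or the `dx`/`dy` extension for non-square cells) and
#' `NODATA_value`; rows follow north to south, which matches the package's
#' north-up convention. A sidecar `<path>.prj` text file, when present,
#' supplies the CRS identifier (first line); otherwise `"EPSG:4326"` is
#' assumed. ASCII grids are single-band: requesting `band > 1` is an error.
#'
#' @param path path to an existing `.asc` file.
#' @param band band index; only 1 is valid for this format.
#' @param categorical if `TRUE` return a [class_grid()] (integer codes),
#'   otherwise a [geo_grid()].
#' @param code_table code table for categorical grids.
#' @return A [geo_grid()] or [class_grid()].
#' @seealso [write_raster()]
#' @export
read_raster <- function(path, band = 1L, categorical = FALSE,
                        code_table = lcz_code_table()) {
  if (band != 1L)
    stop("ESRI ASCII grids are single-band; cannot read band ", band)
  if (!file.exists(path)) stop("raster file not found: ", path)
  lines <- readLines(path, n = 7L)
  hdr <- list()
  n_hdr <- 0L
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(tok) == 2L && is.na(suppressWarnings(as.numeric(tok[1L])))) {
      hdr[[tolower(tok[1L])]] <- as.numeric(tok[2L])
      n_hdr <- n_hdr + 1L
    } else break
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner")
  if (!all(need %in% names(hdr)))
    stop("malformed ASCII grid header in ", path, ": need ",
         paste(setdiff(need, names(hdr)), collapse = ", "))
  if (!is.null(hdr$cellsize)) {
    csx <- csy <- hdr$cellsize
  } else if (!is.null(hdr$dx) && !is.null(hdr$dy)) {
    csx <- hdr$dx; csy <- hdr$dy
  } else stop("ASCII grid header must contain cellsize or dx/dy: ", path)
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  vals <- scan(path, what = double(), skip = n_hdr, quiet = TRUE)
  if (length(vals) != nr * nc)
    stop("ASCII grid body has ", length(vals), " values, expected ",
         nr * nc, ": ", path)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA
  crs_id <- read_prj_sidecar(path)
  origin_lon <- hdr$xllcorner
  origin_lat <- hdr$yllcorner + nr * csy
  if (categorical) {
    if (any(abs(m - round(m)) > 0, na.rm = TRUE))
      stop("categorical raster contains non-integer codes: ", path)
    class_grid(m, origin_lon, origin_lat, csx, csy,
               nodata_code = as.integer(nodata), code_table = code_table,
               crs_id = crs_id)
  } else {
    geo_grid(m, origin_lon, origin_lat, csx, csy, nodata = nodata,
             crs_id = crs_id)
  }
}

#' Write a raster to an ESRI ASCII grid file
#'
#' Inverse of [read_raster()]: georeferencing metadata round-trips exactly,
#' values round-trip bit-exactly for integer grids and to 17 significant
#' digits for floats. Non-square cells are written with the `dx`/`dy`
#' header extension. The CRS id is written to a `<path>.prj` sidecar.
#'
#' @param grid a [geo_grid()] or [class_grid()].
#' @param path output `.asc` path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path) {
  nodata <- if (inherits(grid, "class_grid")) grid$nodata_code else grid$nodata
  hdr <- c(sprintf("ncols %d", grid$n_cols),
           sprintf("nrows %d", grid$n_rows),
           sprintf("xllcorner %.12g", grid$origin_lon),
           sprintf("yllcorner %.12g",
                   grid$origin_lat - grid$n_rows * grid$cell_size_lat))
  if (grid$cell_size_lon == grid$cell_size_lat) {
    hdr <- c(hdr, sprintf("cellsize %.12g", grid$cell_size_lon))
  } else {
    hdr <- c(hdr, sprintf("dx %.12g", grid$cell_size_lon),
             sprintf("dy %.12g", grid$cell_size_lat))
  }
  hdr <- c(hdr, sprintf("NODATA_value %.12g", as.numeric(nodata)))
  m <- grid$values
  m[is.na(m)] <- nodata
  fmt <- if (inherits(grid, "class_grid")) {
    function(row) paste(as.integer(row), collapse = " ")
  } else {
    function(row) paste(formatC(row, format = "g", digits = 17),
                        collapse = " ")
  }
  body <- vapply(seq_len(nrow(m)), function(i) fmt(m[i, ]), character(1))
  writeLines(c(hdr, body), path)
  writeLines(grid$crs_id, prj_path(path))
  invisible(path)
}

prj_path <- function(path) paste0(sub("\\.asc$", "", path), ".prj")

read_prj_sidecar <- function(path) {
  pp <- prj_path(path)
  if (file.exists(pp)) trimws(readLines(pp, n = 1L)) else "EPSG:4326"
}

#' Read city boundaries from GeoJSON
#'
#' Parses a GeoJSON FeatureCollection of Polygon / MultiPolygon features
#' into [city_boundary()] objects. Each feature must carry `city_id`,
#' `name` and `continent` properties; MultiPolygon features become
#' multi-part boundaries whose cell set is the union over parts.
#'
#' @param path path to a `.geojson` file.
#' @param crs_id CRS identifier to stamp on the boundaries.
#' @return Named list of [city_boundary()] (names are city ids).
#' @export
read_boundaries <- function(path, crs_id = "EPSG:4326") {
  if (!file.exists(path)) stop("boundary file not found: ", path)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection"))
    stop("expected a GeoJSON FeatureCollection in ", path)
  out <- vector("list", length(gj$features))
  ids <- character(length(gj$features))
  for (i in seq_along(gj$features)) {
    f <- gj$features[[i]]
    props <- f$properties
    for (field in c("city_id", "name", "continent"))
      if (is.null(props[[field]]))
        stop("feature ", i, " is missing required attribute '", field, "'")
    geom <- f$geometry
    ring_mat <- function(coords)
      do.call(rbind, lapply(coords, function(pt) c(pt[[1L]], pt[[2L]])))
    parts <- switch(
      geom$type,
      Polygon = list(lapply(geom$coordinates, ring_mat)),
      MultiPolygon = lapply(geom$coordinates,
                            function(p) lapply(p, ring_mat)),
      stop("feature ", i, ": unsupported geometry type '", geom$type, "'"))
    out[[i]] <- city_boundary(props$city_id, props$name, props$continent,
                              parts, crs_id = crs_id)
    ids[i] <- props$city_id
  }
  if (anyDuplicated(ids))
    stop("duplicate city_id values: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(out) <- ids
  out
}

#' Write city boundaries to GeoJSON
#'
#' @param boundaries list of [city_boundary()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_boundaries <- function(boundaries, path) {
  feat <- lapply(boundaries, function(b) {
    coords <- lapply(b$parts, function(p)
      lapply(p, function(r) lapply(seq_len(nrow(r)),
                                   function(i) c(r[i, 1L], r[i, 2L]))))
    geom <- if (length(b$parts) == 1L) {
      list(type = "Polygon", coordinates = coords[[1L]])
    } else {
      list(type = "MultiPolygon", coordinates = coords)
    }
    list(type = "Feature",
         properties = list(city_id = b$city_id, name = b$name,
                           continent = b$continent),
         geometry = geom)
  })
  gj <- list(type = "FeatureCollection", features = unname(feat))
  writeLines(jsonlite::toJSON(gj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}
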