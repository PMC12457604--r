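test_that("cell-center containment finds exactly the covered centers", {
  g <- unit_grid(4, 4)
  # rectangle covering the interior 2x2 block of centers
  b <- rect_boundary(1, 1, 3, 3)
  idx <- cell_centers_in_polygon(g, b)
  expect_equal(nrow(idx), 4L)
  # row-major ordering, rows 2:3 x cols 2:3
  expect_equal(idx, cbind(row = c(2L, 2L, 3L, 3L), col = c(2L, 3L, 2L, 3L)))
})

test_that("a polygon avoiding all centers yields an empty cell set", {
  g <- unit_grid(4, 4)
  b <- rect_boundary(0.6, 0.6, 1.4, 1.4)  # sits between the 0.5-offset centers
  idx <- cell_centers_in_polygon(g, b)
  expect_equal(nrow(idx), 0L)
  expect_equal(colnames(idx), c("row", "col"))
})

test_that("centers exactly on a polygon edge count as inside", {
  g <- unit_grid(4, 4)
  # west edge passes exactly through the column-1 centers (lon = 0.5)
  b <- rect_boundary(0.5, 0, 2, 4)
  idx <- cell_centers_in_polygon(g, b)
  expect_true(all(c(1, 2, 3, 4) %in% idx[idx[, "col"] == 1L, "row"]))
})

test_that("random polygons match a brute-force containment oracle", {
  set.seed(42)
  g <- unit_grid(20, 20)
  for (i in 1:50) {
    ring <- random_polygon(20, 20)
    b <- city_boundary(paste0("p", i), "p", "Africa", ring)
    got <- cell_centers_in_polygon(g, b)
    want <- oracle_cells(g, b)
    expect_equal(got[order(got[, 1], got[, 2]), , drop = FALSE],
                 want[order(want[, 1], want[, 2]), , drop = FALSE],
                 info = paste("polygon", i))
  }
})

test_that("nested polygons give nested cell sets", {
  set.seed(7)
  g <- unit_grid(20, 20)
  for (i in 1:20) {
    x0 <- runif(1, 0, 8); y0 <- runif(1, 0, 8)
    x1 <- x0 + runif(1, 4, 10); y1 <- y0 + runif(1, 4, 10)
    inner <- rect_boundary(x0 + 1, y0 + 1, x1 - 1, y1 - 1, "in")
    outer <- rect_boundary(x0, y0, x1, y1, "out")
    key <- function(m) paste(m[, 1], m[, 2])
    expect_true(all(key(cell_centers_in_polygon(g, inner)) %in%
                      key(cell_centers_in_polygon(g, outer))))
  }
})

test_that("CRS mismatch is an error naming both identifiers", {
  g <- unit_grid(4, 4)
  b <- city_boundary("c", "c", "Asia", rect_ring(1, 1, 3, 3),
                     crs_id = "EPSG:3857")
  expect_error(cell_centers_in_polygon(g, b), "EPSG:4326")
  expect_error(cell_centers_in_polygon(g, b), "EPSG:3857")
})

test_that("a polygon hole excludes the centers it covers", {
  g <- unit_grid(6, 6)
  outer <- rect_ring(0.2, 0.2, 5.8, 5.8)
  hole <- rect_ring(2.2, 2.2, 3.8, 3.8)   # swallows center (3.5, 3.5) area
  b <- city_boundary("h", "h", "Europe", list(outer, hole))
  idx <- cell_centers_in_polygon(g, b)
  key <- paste(idx[, "row"], idx[, "col"])
  # centers inside the hole (rows/cols 3:4 in the 2.5/3.5 band) are out
  expect_false("3 3" %in% key)
  expect_false("4 4" %in% key)
  expect_true("1 1" %in% key)
  expect_equal(idx, oracle_cells(g, b), ignore_attr = TRUE)
})

test_that("ASCII raster round-trip preserves metadata and values", {
  td <- withr::local_tempdir()
  f <- file.path(td, "g.asc")
  m <- matrix(c(1L, 2L, 3L, -4L, 0L, 7L), 2, 3)
  cg <- class_grid(matrix(sample(1:17, 12, TRUE), 3, 4), 10, 50, 0.5, 0.25)
  write_raster(cg, f)
  back <- read_raster(f, categorical = TRUE)
  expect_identical(back$values, cg$values)
  expect_equal(back$origin_lon, cg$origin_lon)
  expect_equal(back$origin_lat, cg$origin_lat)
  expect_equal(back$cell_size_lon, 0.5)
  expect_equal(back$cell_size_lat, 0.25)
  expect_equal(back$crs_id, "EPSG:4326")

  g <- geo_grid(matrix(c(27.125, NA, -3.5, 1e-7, 29.000001, 31), 2, 3),
                -10, 60, 1, 1, nodata = -9999)
  f2 <- file.path(td, "f.asc")
  write_raster(g, f2)
  back2 <- read_raster(f2)
  expect_equal(back2$values, g$values, tolerance = 1e-15)
  expect_true(is.na(back2$values[2, 1]))
})

test_that("nodata cells are flagged and excluded from statistics", {
  td <- withr::local_tempdir()
  vals <- matrix(runif(100), 10, 10)
  vals[sample(100, 23)] <- NA
  g <- geo_grid(vals, 0, 10, 1, 1)
  f <- file.path(td, "nd.asc")
  write_raster(g, f)
  back <- read_raster(f)
  expect_equal(sum(is.na(back$values)), 23L)
  b <- rect_boundary(0, 0, 10, 10)
  expect_equal(zonal_mean(back, b), mean(vals, na.rm = TRUE))
})

test_that("raster reader rejects bad inputs clearly", {
  expect_error(read_raster("no/such/file.asc"), "not found")
  expect_error(read_raster(tempfile(), band = 2), "single-band")
  td <- withr::local_tempdir()
  f <- file.path(td, "bad.asc")
  writeLines(c("ncols 2", "nrows 2", "1 2", "3 4"), f)
  expect_error(read_raster(f), "xllcorner")
})

test_that("GeoJSON boundaries round-trip with ids, names, continents", {
  td <- withr::local_tempdir()
  bs <- list(rect_boundary(0, 0, 2, 2, "a", "Africa"),
             rect_boundary(3, 0, 5, 2, "b", "Europe"),
             rect_boundary(0, 3, 2, 5, "c", "Oceania"))
  f <- file.path(td, "b.geojson")
  write_boundaries(bs, f)
  back <- read_boundaries(f)
  expect_equal(names(back), c("a", "b", "c"))
  expect_equal(back$b$continent, "Europe")
  expect_equal(back$a$parts[[1]][[1]], bs[[1]]$parts[[1]][[1]])
})

test_that("a feature missing a required attribute errors with its name", {
  td <- withr::local_tempdir()
  gj <- list(type = "FeatureCollection", features = list(list(
    type = "Feature",
    properties = list(city_id = "x", name = "X"),
    geometry = list(type = "Polygon",
                    coordinates = list(list(list(0, 0), list(1, 0),
                                            list(1, 1), list(0, 0)))))))
  f <- file.path(td, "bad.geojson")
  writeLines(jsonlite::toJSON(gj, auto_unbox = TRUE), f)
  expect_error(read_boundaries(f), "continent")
  expect_error(read_boundaries(f), "feature 1")
})

test_that("MultiPolygon cell set is the union of the per-part sets", {
  td <- withr::local_tempdir()
  g <- unit_grid(10, 10)
  p1 <- rect_ring(0.2, 0.2, 3.8, 3.8)
  p2 <- rect_ring(6.2, 6.2, 9.8, 9.8)
  multi <- city_boundary("m", "m", "Asia", list(list(p1), list(p2)))
  f <- file.path(td, "m.geojson")
  write_boundaries(list(multi), f)
  back <- read_boundaries(f)[["m"]]
  expect_length(back$parts, 2L)
  got <- cell_centers_in_polygon(g, back)
  u1 <- cell_centers_in_polygon(g, city_boundary("1", "1", "Asia", p1))
  u2 <- cell_centers_in_polygon(g, city_boundary("2", "2", "Asia", p2))
  want <- rbind(u1, u2)
  expect_setequal(paste(got[, 1], got[, 2]), paste(want[, 1], want[, 2]))
})

test_that("boundary constructor enforces its contract", {
  expect_error(city_boundary("x", "x", "Atlantis", rect_ring(0, 0, 1, 1)),
               "continent")
  degenerate <- rbind(c(0, 0), c(1, 1), c(2, 2), c(0, 0))
  expect_error(city_boundary("x", "x", "Asia", degenerate), "area")
})
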