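# Shared fixtures: tiny grids, random simple polygons, and an independent
# point-in-polygon oracle (mgcv::in.out) for brute-force cross-checks.

unit_grid <- function(nr = 4, nc = 4, origin_lat = nr, values = NULL) {
  if (is.null(values)) values <- matrix(seq_len(nr * nc), nr, nc)
  geo_grid(values, origin_lon = 0, origin_lat = origin_lat,
           cell_size_lon = 1, cell_size_lat = 1)
}

rect_ring <- function(x0, y0, x1, y1) {
  rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1), c(x0, y0))
}

rect_boundary <- function(x0, y0, x1, y1, id = "c1", continent = "Asia") {
  city_boundary(id, id, continent, rect_ring(x0, y0, x1, y1))
}

# Random star-shaped (hence simple) polygon around a random center.
random_polygon <- function(xmax, ymax, min_r = 1, max_r = NULL) {
  if (is.null(max_r)) max_r <- min(xmax, ymax) / 2.5
  cx <- runif(1, max_r, xmax - max_r)
  cy <- runif(1, max_r, ymax - max_r)
  k <- sample(4:9, 1)
  ang <- sort(runif(k, 0, 2 * pi))
  r <- runif(k, min_r, max_r)
  ring <- cbind(cx + r * cos(ang), cy + r * sin(ang))
  rbind(ring, ring[1, , drop = FALSE])
}

# Independent containment oracle over EVERY cell center of a grid.
oracle_cells <- function(grid, boundary) {
  skip_if_not_installed("mgcv")
  bnd <- do.call(rbind, lapply(boundary$parts, function(part) {
    loops <- do.call(rbind, lapply(part, function(r) rbind(r, c(NA, NA))))
    loops
  }))
  bnd <- bnd[-nrow(bnd), , drop = FALSE]  # trailing NA row
  rr <- rep(seq_len(grid$n_rows), each = grid$n_cols)
  cc <- rep(seq_len(grid$n_cols), times = grid$n_rows)
  ctr <- cell_center(grid, rr, cc)
  keep <- mgcv::in.out(bnd, ctr)
  cbind(row = rr[keep], col = cc[keep])
}

tiny_world_config <- function(n_cities = 16L, n_exceeders = 4L, seed = 11L,
                              ...) {
  world_config(n_cities = n_cities, n_exceeders = n_exceeders, seed = seed,
               coarse_cell_size = 0.1, fine_cell_size = 0.05, ...)
}
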