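#' Per-city economic capacity joined to terminal-period heat
#'
#' Sums the gridded GDP (PPP) raster within each city footprint and joins
#' the total 1:1 with the city's terminal-period MAT. GDP is held at its
#' mapping year (2020 in the source data) for all periods — it is a
#' capacity proxy, not a projection. A per-capita column is derived when a
#' `population` column is supplied, as total GDP alone does not capture
#' institutional strength.
#'
#' @param boundaries list of [city_boundary()].
#' @param gdp_grid GDP (PPP) [geo_grid()]; must cover the footprints.
#' @param mat_terminal named numeric vector of terminal-period MATs (names
#'   are city ids).
#' @param threshold degC exceedance cut for the `above_29` flag.
#' @param population optional named vector of city populations for the
#'   derived per-capita column.
#' @return data.frame: city_id, name, continent, gdp_ppp_total,
#'   mat_terminal, above_29 (and gdp_per_capita when population given).
#'   Cities with zero included GDP cells get total 0 with a warning.
#' @export
capacity_table <- function(boundaries, gdp_grid, mat_terminal,
                           threshold = 29, population = NULL) {
  ids <- vapply(boundaries, `[[`, character(1), "city_id")
  missing_mat <- setdiff(ids, names(mat_terminal))
  if (length(missing_mat))
    stop("no terminal-period MAT for city(ies): ",
         paste(utils::head(missing_mat, 5), collapse = ", "))
  gdp <- vapply(boundaries, function(b) zonal_sum(gdp_grid, b), numeric(1))
  out <- data.frame(
    city_id = ids,
    name = vapply(boundaries, `[[`, character(1), "name"),
    continent = vapply(boundaries, `[[`, character(1), "continent"),
    gdp_ppp_total = unname(gdp),
    mat_terminal = unname(mat_terminal[ids]),
    stringsAsFactors = FALSE, row.names = NULL)
  out$above_29 <- is.finite(out$mat_terminal) & out$mat_terminal > threshold
  if (!is.null(population))
    out$gdp_per_capita <- out$gdp_ppp_total / unname(population[ids])
  out
}

#' Continental GDP summary for exceeding cities
#'
#' Filters to cities strictly above the MAT threshold and summarizes their
#' GDP (PPP) totals per continent. Continents present in the input but
#' with no qualifying city are kept as `n = 0` rows with missing
#' quartiles — the "no city is plotted" case.
#'
#' @param records output of [capacity_table()].
#' @param threshold degC cut (default 29; `-Inf` includes every city).
#' @return data.frame: continent, n, q1, median, q3 (GDP currency units).
#' @export
capacity_summary <- function(records, threshold = 29) {
  continents <- sort(unique(records$continent))
  rows <- lapply(continents, function(ct) {
    g <- records$gdp_ppp_total[records$continent == ct &
                                 is.finite(records$mat_terminal) &
                                 records$mat_terminal > threshold]
    if (length(g) == 0L)
      return(data.frame(continent = ct, n = 0L, q1 = NA_real_,
                        median = NA_real_, q3 = NA_real_,
                        stringsAsFactors = FALSE))
    q <- stats::quantile(g, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(continent = ct, n = length(g), q1 = q[1L], median = q[2L],
               q3 = q[3L], stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
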