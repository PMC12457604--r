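#' Default period to population-year mapping
#'
#' Each 30-year projection period is represented by a single population
#' mapping year: 2011-2040 by 2025, 2041-2070 by 2070, 2071-2100 by 2100.
#' No within-period averaging is performed.
#'
#' @return Named integer vector (period label -> year).
#' @export
default_period_popmap <- function() {
  c("2011-2040" = 2025L, "2041-2070" = 2070L, "2071-2100" = 2100L)
}

#' Classify a mean annual temperature against niche thresholds
#'
#' The human-climate-niche screen uses 29 degC as the upper habitability
#' benchmark and 27 degC as a conservative sensitivity cut. "Exceed" is
#' strict: a city exactly at a threshold is *not* an exceeder, so
#' `mat = 29` falls in the 27-29 band.
#'
#' @param mat numeric vector of mean annual temperatures, degC.
#' @param low,high band thresholds, degC (`low < high`).
#' @return Character vector with levels `below_27`, `27_to_29`, `above_29`
#'   (names reflect the default thresholds); non-finite inputs give `NA`
#'   with a warning.
#' @export
classify_band <- function(mat, low = 27, high = 29) {
  stopifnot(low < high)
  bad <- !is.finite(mat)
  if (any(bad))
    warning(sum(bad), " non-finite MAT value(s) classified as missing")
  band <- ifelse(mat > high, "above_29",
                 ifelse(mat > low, "27_to_29", "below_27"))
  band[bad] <- NA_character_
  band
}

#' MAT change against the reference span
#'
#' @param mat_future,mat_reference finite temperatures, degC.
#' @return Exact elementwise difference `mat_future - mat_reference`.
#' @export
delta_mat <- function(mat_future, mat_reference) {
  if (any(!is.finite(mat_future)) || any(!is.finite(mat_reference)))
    stop("delta_mat requires finite inputs")
  mat_future - mat_reference
}

#' Per-city MAT records across scenarios and periods
#'
#' Runs [zonal_mean()] for every city over every scenario x period MAT
#' raster and the reference raster, and classifies each record into niche
#' bands.
#'
#' @param mat_rasters nested list `[[scenario]][[period]]` of [geo_grid()].
#' @param reference_raster reference-span MAT [geo_grid()].
#' @param boundaries list of [city_boundary()].
#' @param low,high niche thresholds passed to [classify_band()].
#' @return data.frame: city_id, name, continent, scenario, period, mat,
#'   reference_mat, delta_mat, band.
#' @export
city_mat_records <- function(mat_rasters, reference_raster, boundaries,
                             low = 27, high = 29) {
  ref <- vapply(boundaries, function(b) zonal_mean(reference_raster, b),
                numeric(1))
  rows <- list()
  for (s in names(mat_rasters)) {
    for (p in names(mat_rasters[[s]])) {
      g <- mat_rasters[[s]][[p]]
      matv <- vapply(boundaries, function(b) zonal_mean(g, b), numeric(1))
      rows[[paste(s, p)]] <- data.frame(
        city_id = vapply(boundaries, `[[`, character(1), "city_id"),
        name = vapply(boundaries, `[[`, character(1), "name"),
        continent = vapply(boundaries, `[[`, character(1), "continent"),
        scenario = s, period = p, mat = matv, reference_mat = ref,
        delta_mat = matv - ref,
        band = classify_band(matv, low, high),
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Screen cities and populations against niche thresholds
#'
#' For every scenario x period, counts cities per niche band and sums the
#' exposed population, overall and by continent. The population of a record
#' is taken from the single year its period maps to (see
#' [default_period_popmap()]).
#'
#' @param records output of [city_mat_records()].
#' @param populations data.frame city_id, year, population (long format;
#'   one row per city per mapping year).
#' @param popmap named vector period -> year.
#' @return data.frame: scenario, period, band, continent (including the
#'   pooled `"ALL"` rows), n_cities, population. Every band appears for
#'   every scenario x period (zero rows included for `"ALL"`).
#' @export
screen_exposure <- function(records, populations,
                            popmap = default_period_popmap()) {
  periods <- unique(records$period)
  missing_map <- setdiff(periods, names(popmap))
  if (length(missing_map))
    stop("popmap has no year for period(s): ",
         paste(missing_map, collapse = ", "))
  bands <- c("below_27", "27_to_29", "above_29")
  out <- list()
  for (p in periods) {
    yr <- popmap[[p]]
    popy <- populations[populations$year == yr, c("city_id", "population")]
    sub <- records[records$period == p & !is.na(records$band), ]
    no_pop <- setdiff(unique(sub$city_id), popy$city_id)
    if (length(no_pop))
      stop("no population for year ", yr, " for city(ies): ",
           paste(utils::head(no_pop, 5), collapse = ", "),
           if (length(no_pop) > 5) " ...")
    sub <- merge(sub, popy, by = "city_id")
    for (s in unique(sub$scenario)) {
      ssub <- sub[sub$scenario == s, ]
      for (b in bands) {
        bsub <- ssub[ssub$band == b, ]
        out[[length(out) + 1L]] <- data.frame(
          scenario = s, period = p, band = b, continent = "ALL",
          n_cities = nrow(bsub), population = sum(bsub$population),
          stringsAsFactors = FALSE)
        if (nrow(bsub)) {
          agg <- stats::aggregate(
            cbind(n_cities = rep(1L, nrow(bsub)),
                  population = bsub$population),
            by = list(continent = bsub$continent), FUN = sum)
          out[[length(out) + 1L]] <- data.frame(
            scenario = s, period = p, band = b, continent = agg$continent,
            n_cities = agg$n_cities, population = agg$population,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Continental summary of MAT change
#'
#' Median and quartiles of per-city delta MAT by continent and scenario,
#' the "more than 50% of European cities warm by more than X degC" style
#' statistic. Quartiles use linear interpolation between order statistics
#' (the R default, type 7).
#'
#' @param records output of [city_mat_records()].
#' @param period period label to summarize (default: the last period
#'   present).
#' @return data.frame: continent, scenario, period, n, q1, median, q3.
#'   Continents with zero cities are omitted with a warning.
#' @export
continental_summary <- function(records, period = NULL) {
  if (is.null(period)) period <- max(unique(records$period))
  sub <- records[records$period == period & is.finite(records$delta_mat), ]
  if (!nrow(sub)) {
    warning("no finite delta_mat records for period ", period)
    return(data.frame(continent = character(), scenario = character(),
                      period = character(), n = integer(), q1 = numeric(),
                      median = numeric(), q3 = numeric()))
  }
  combos <- unique(sub[, c("continent", "scenario")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    d <- sub$delta_mat[sub$continent == combos$continent[i] &
                         sub$scenario == combos$scenario[i]]
    q <- stats::quantile(d, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(continent = combos$continent[i],
               scenario = combos$scenario[i], period = period,
               n = length(d), q1 = q[1L], median = q[2L], q3 = q[3L],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  res[order(res$scenario, res$continent), , drop = FALSE]
}
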