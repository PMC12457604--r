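#' Zonal mean of a continuous raster within a city boundary
#'
#' Unweighted arithmetic mean over the non-nodata cells whose centers fall
#' inside the boundary. No cosine-latitude weighting is applied by default:
#' at city scale on ~1 km grids the within-city latitude variation is
#' negligible; set `latitude_weighted = TRUE` for a cos(lat) cell weighting.
#'
#' @param grid a [geo_grid()].
#' @param boundary a [city_boundary()].
#' @param latitude_weighted weight cells by cos(center latitude).
#' @return The mean, or `NA` (with a warning naming the city) when no
#'   non-nodata cell center falls inside.
#' @export
zonal_mean <- function(grid, boundary, latitude_weighted = FALSE) {
  idx <- cell_centers_in_polygon(grid, boundary)
  v <- grid_values_at(grid, idx)
  keep <- !is.na(v)
  if (!any(keep)) {
    warning("zonal_mean: no non-nodata cells for city '",
            boundary$city_id, "'; returning NA")
    return(NA_real_)
  }
  if (latitude_weighted) {
    lat <- cell_center(grid, idx[keep, "row"], idx[keep, "col"])[, "lat"]
    w <- cos(lat * pi / 180)
    sum(v[keep] * w) / sum(w)
  } else {
    mean(v[keep])
  }
}

#' Zonal sum of a continuous raster within a city boundary
#'
#' Sum over included cell centers; nodata cells contribute 0. Used for
#' population and GDP totals, where center-containment guarantees each cell
#' is counted for at most one city in a non-overlapping boundary set.
#'
#' @inheritParams zonal_mean
#' @return The sum (0 for an empty or all-nodata footprint, with a warning).
#' @export
zonal_sum <- function(grid, boundary) {
  idx <- cell_centers_in_polygon(grid, boundary)
  v <- grid_values_at(grid, idx)
  if (nrow(idx) == 0L || all(is.na(v))) {
    warning("zonal_sum: no non-nodata cells for city '",
            boundary$city_id, "'; returning 0")
    return(0)
  }
  sum(v, na.rm = TRUE)
}

#' LCZ class shares within a city boundary
#'
#' Computes S_LCZ, the share of each Local Climate Zone class of the city's
#' classified area: `share(c) = n cells of code c / n classified cells`,
#' counted over cell centers inside the boundary. Shares are reported as
#' explicit values for every code in the grid's code table (zeros for
#' classes absent from the city). Unclassified (nodata) cells shrink the
#' denominator; they never form a pseudo-class.
#'
#' @param grid a [class_grid()].
#' @param boundary a [city_boundary()].
#' @return An `lcz_profile`: list with `city_id`, `shares` (named numeric
#'   over all codes, summing to 1), and `n_cells` (classified cell count).
#'   `NULL` (with a warning) when no classified cell center falls inside.
#' @export
class_shares <- function(grid, boundary) {
  if (!inherits(grid, "class_grid"))
    stop("class_shares needs a class_grid")
  idx <- cell_centers_in_polygon(grid, boundary)
  v <- grid_values_at(grid, idx)
  v <- v[!is.na(v)]
  if (length(v) == 0L) {
    warning("class_shares: no classified cells for city '",
            boundary$city_id, "'; profile is missing")
    return(NULL)
  }
  codes <- names(grid$code_table)
  counts <- table(factor(as.character(v), levels = codes))
  shares <- as.numeric(counts) / length(v)
  names(shares) <- codes
  structure(list(city_id = boundary$city_id, shares = shares,
                 n_cells = length(v)),
            class = "lcz_profile")
}

#' Aggregate LCZ shares into named groups
#'
#' Group shares are sums of member-class shares; groups whose member codes
#' are absent from the city get 0. Groups must be disjoint.
#'
#' @param profile an `lcz_profile` from [class_shares()], or a bare named
#'   share vector.
#' @param grouping named list mapping group label to integer code vector;
#'   defaults to [lcz_default_grouping()].
#' @return Named numeric vector of group shares.
#' @export
group_shares <- function(profile, grouping = lcz_default_grouping()) {
  shares <- if (inherits(profile, "lcz_profile")) profile$shares else profile
  all_codes <- unlist(grouping, use.names = FALSE)
  if (anyDuplicated(all_codes))
    stop("grouping sets must be disjoint; duplicated code(s): ",
         paste(unique(all_codes[duplicated(all_codes)]), collapse = ", "))
  vapply(grouping, function(codes) {
    present <- as.character(codes)[as.character(codes) %in% names(shares)]
    if (length(present) == 0L) 0 else sum(shares[present])
  }, numeric(1))
}

#' Default LCZ grouping
#'
#' Groups the 17 LCZ classes into the morphology categories used for the
#' exceeder / non-exceeder comparison. Group *names* follow the field's
#' usage (compact, open, green spaces, low plants, bare natural surfaces);
#' the class memberships are the standard LCZ semantics: compact = 1-3,
#' open = 4-6, lightweight = 7, large low-rise = 8, sparse = 9,
#' industry = 10, green = A-C (11-13), low plants = D (14), bare natural =
#' E-F (15-16), water = G (17). Fully overridable wherever a grouping is
#' accepted.
#'
#' @return Named list of integer code vectors covering all 17 codes.
#' @export
lcz_default_grouping <- function() {
  list(compact = 1:3, open = 4:6, lightweight = 7L, large_lowrise = 8L,
       sparse = 9L, industry = 10L, green = 11:13, low_plants = 14L,
       bare_natural = 15:16, water = 17L)
}

#' LCZ profiles for a set of cities
#'
#' Applies [class_shares()] and [group_shares()] to every boundary and
#' binds the results into one table.
#'
#' @param grid a [class_grid()].
#' @param boundaries list of [city_boundary()].
#' @param grouping passed to [group_shares()].
#' @return data.frame with city_id, name, continent, n_cells, one
#'   `share_<code>` column per LCZ code and one column per group label.
#'   Cities with no classified cells are dropped (with the warning from
#'   [class_shares()]).
#' @export
lcz_profile_table <- function(grid, boundaries,
                              grouping = lcz_default_grouping()) {
  rows <- lapply(boundaries, function(b) {
    prof <- class_shares(grid, b)
    if (is.null(prof)) return(NULL)
    g <- group_shares(prof, grouping)
    df <- data.frame(city_id = b$city_id, name = b$name,
                     continent = b$continent, n_cells = prof$n_cells,
                     stringsAsFactors = FALSE)
    for (code in names(prof$shares))
      df[[paste0("share_", code)]] <- prof$shares[[code]]
    for (lab in names(g)) df[[lab]] <- g[[lab]]
    df
  })
  do.call(rbind, c(Filter(Negate(is.null), rows),
                   list(make.row.names = FALSE)))
}
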