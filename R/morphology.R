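#' Split cities at the niche threshold
#'
#' Partitions cities by their terminal-period MAT into a below-threshold
#' and a strictly-above-threshold group. A city exactly at the threshold is
#' assigned to the below group, consistent with the strict exceedance rule
#' of [classify_band()].
#'
#' @param mat named numeric vector of terminal-period MATs (names are city
#'   ids).
#' @param threshold degC cut (default 29).
#' @return List with character vectors `below` and `above` of city ids.
#' @export
split_groups <- function(mat, threshold = 29) {
  stopifnot(!is.null(names(mat)))
  keep <- is.finite(mat)
  list(below = names(mat)[keep & mat <= threshold],
       above = names(mat)[keep & mat > threshold])
}

#' Welch's two-sample t-test on share samples
#'
#' Two-sided t-test without the equal-variance assumption
#' (Welch-Satterthwaite degrees of freedom), delegating to
#' [stats::t.test()]. Degenerate inputs are resolved before delegation:
#' fewer than two observations in either sample gives a missing result;
#' two constant samples give `t = 0, p = 1` when the means agree and
#' `|t| = Inf, p = 0` when they differ.
#'
#' @param x,y numeric samples.
#' @return List with `t`, `df`, `p` (all `NA` when either n < 2).
#' @export
welch_t <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L)
    return(list(t = NA_real_, df = NA_real_, p = NA_real_))
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y))
      return(list(t = 0, df = nx + ny - 2, p = 1))
    return(list(t = sign(mean(x) - mean(y)) * Inf, df = nx + ny - 2, p = 0))
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Compare LCZ group shares between exceeding and non-exceeding cities
#'
#' The morphology contrast: cities are split at the 29 degC terminal-period
#' threshold and, for every LCZ group and every stratum (each continent
#' plus the pooled `"ALL"` stratum), the two groups' share distributions
#' are compared with Welch's t-test. p-values are raw (no multiple-testing
#' correction, matching the star-annotation convention); set
#' `correction = "BH"` for a Benjamini-Hochberg adjusted column used for
#' the significance flag instead.
#'
#' @param city_table data.frame with columns city_id, continent, mat
#'   (terminal-period MAT) and one numeric column per LCZ group label.
#' @param group_cols character vector of the group share column names
#'   (default: all [lcz_default_grouping()] labels present).
#' @param threshold degC split (default 29).
#' @param alpha significance level for the flag (default 0.05).
#' @param correction `"none"` (raw p) or `"BH"`.
#' @return data.frame: continent, lcz_group, n_below, n_above, mean_below,
#'   mean_above, t, df, p, significant. Strata with an empty group carry
#'   missing t/p and `significant = FALSE`.
#' @export
compare_all <- function(city_table, group_cols = NULL, threshold = 29,
                        alpha = 0.05, correction = c("none", "BH")) {
  correction <- match.arg(correction)
  if (is.null(group_cols))
    group_cols <- intersect(names(lcz_default_grouping()),
                            names(city_table))
  if (!length(group_cols)) stop("no LCZ group columns found")
  strata <- c("ALL", sort(unique(city_table$continent)))
  rows <- list()
  for (str in strata) {
    sub <- if (str == "ALL") city_table
           else city_table[city_table$continent == str, ]
    below <- sub[is.finite(sub$mat) & sub$mat <= threshold, ]
    above <- sub[is.finite(sub$mat) & sub$mat > threshold, ]
    for (gc in group_cols) {
      wt <- welch_t(below[[gc]], above[[gc]])
      rows[[length(rows) + 1L]] <- data.frame(
        continent = str, lcz_group = gc,
        n_below = nrow(below), n_above = nrow(above),
        mean_below = if (nrow(below)) mean(below[[gc]]) else NA_real_,
        mean_above = if (nrow(above)) mean(above[[gc]]) else NA_real_,
        t = wt$t, df = wt$df, p = wt$p, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  p_eff <- if (correction == "BH") stats::p.adjust(res$p, "BH") else res$p
  res$significant <- !is.na(p_eff) & p_eff < alpha
  res
}

#' Median-position diagnostic for exceeding cities
#'
#' For each city strictly above the threshold, compares its share of one
#' LCZ group to the median share of *all* cities of its continent
#' (exceeders included; set `median_population = "non_exceeders"` to
#' median over the complement instead). Returns the fraction of exceeders
#' strictly on the stated side of their continent-specific median; ties
#' count as not satisfying the strict comparison, so a single-city
#' continent (whose share equals its own median) never counts.
#'
#' @param city_table as in [compare_all()].
#' @param group_col one LCZ group column name.
#' @param direction `"above"` or `"below"`.
#' @param threshold degC cut (default 29).
#' @param median_population `"all"` (default) or `"non_exceeders"`.
#' @return Fraction in \[0, 1\]; `NA` with a warning when there are no
#'   exceeders.
#' @export
median_position_diagnostic <- function(city_table, group_col,
                                       direction = c("above", "below"),
                                       threshold = 29,
                                       median_population = c("all",
                                                             "non_exceeders")) {
  direction <- match.arg(direction)
  median_population <- match.arg(median_population)
  stopifnot(group_col %in% names(city_table))
  exc <- is.finite(city_table$mat) & city_table$mat > threshold
  if (!any(exc)) {
    warning("no exceeding cities; diagnostic undefined")
    return(NA_real_)
  }
  ref <- if (median_population == "all") city_table else city_table[!exc, ]
  med <- tapply(ref[[group_col]], ref$continent, stats::median)
  ex <- city_table[exc, ]
  m <- med[ex$continent]
  hit <- if (direction == "above") ex[[group_col]] > m else ex[[group_col]] < m
  hit[is.na(m)] <- FALSE   # continent with no reference cities
  mean(hit)
}
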