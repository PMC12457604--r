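#' The expert LCZ-by-measure suitability matrix
#'
#' Binary weights stating which built LCZ classes each heat-adaptation
#' measure targets. Columns cover the six built classes the expert mapping
#' addresses (LCZ 1, 2, 3, 4, 8 and 10); all other LCZ classes (5, 6, 7, 9
#' and the natural classes A-G) carry implicit weight 0 and are expanded to
#' explicit zero columns when scoring, so the dot product is total over all
#' 17 classes. Ten measures are defined, from urban-openness and
#' densification controls through reflective materials, greening and water
#' bodies to industrial-heat controls.
#'
#' @param path optional CSV override with header
#'   `measure,LCZ1,LCZ2,LCZ3,LCZ4,LCZ8,LCZ10` and 0/1 entries; validated
#'   and substituted for the built-in defaults.
#' @return A `measure_matrix`: list with `measures` (ordered labels),
#'   `lcz_columns` (`c(1,2,3,4,8,10)`) and `weights` (binary matrix,
#'   measures x columns).
#' @export
load_measure_matrix <- function(path = NULL) {
  lcz_cols <- c(1L, 2L, 3L, 4L, 8L, 10L)
  if (is.null(path)) {
    w <- rbind(
      "Optimize Urban Openness"                    = c(1, 1, 1, 0, 0, 0),
      "Regulate Densification"                     = c(1, 1, 1, 0, 0, 0),
      "Restrict Building Height"                   = c(1, 0, 0, 1, 0, 0),
      "Raise Pervious Surface Fraction Ratio"      = c(1, 1, 1, 0, 1, 0),
      "Use Reflective Building Materials"          = c(1, 1, 1, 1, 1, 1),
      "Increase Green Space and Vegetation Cover"  = c(1, 1, 1, 1, 1, 1),
      "Increase Water Bodies"                      = c(1, 1, 1, 1, 1, 1),
      "Reduce Environmental Pollution"             = c(1, 0, 0, 0, 1, 1),
      "Control Heat Emissions from Factories"      = c(1, 0, 0, 0, 1, 1),
      "Promote Sustainable Urban Forms"            = c(0, 0, 0, 0, 1, 1))
  } else {
    df <- utils::read.csv(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
    expected <- c("measure", paste0("LCZ", lcz_cols))
    if (!identical(names(df), expected))
      stop("measure matrix override must have header ",
           paste(expected, collapse = ","), "; got ",
           paste(names(df), collapse = ","))
    w <- as.matrix(df[, -1L])
    rownames(w) <- df$measure
    bad <- which(!(w %in% c(0, 1)), arr.ind = FALSE)
    if (length(bad)) {
      rc <- arrayInd(bad[1L], dim(w))
      stop("non-binary weight '", w[bad[1L]], "' at measure '",
           rownames(w)[rc[1L]], "', column ", colnames(df)[-1L][rc[2L]])
    }
  }
  colnames(w) <- as.character(lcz_cols)
  structure(list(measures = rownames(w), lcz_columns = lcz_cols,
                 weights = w),
            class = "measure_matrix")
}

#' @export
print.measure_matrix <- function(x, ...) {
  cat("<measure_matrix>", length(x$measures), "measures x LCZ",
      paste(x$lcz_columns, collapse = ","), "\n")
  print(x$weights)
  invisible(x)
}

# Expand the 6-column binary matrix to all 17 LCZ codes (zeros elsewhere).
full_weight_matrix <- function(matrix) {
  w <- matrix(0, length(matrix$measures), 17L,
              dimnames = list(matrix$measures, as.character(1:17)))
  w[, as.character(matrix$lcz_columns)] <- matrix$weights
  w
}

#' Score a city's responsiveness to each adaptation measure
#'
#' The weighted score per measure is the dot product of the city's LCZ
#' share vector with the measure's binary suitability column:
#' `score(m) = sum over LCZ of S_LCZ * w(m, LCZ)`. Shares of LCZ classes
#' the matrix does not target contribute 0, and scores are applied to
#' whole-city shares without renormalizing by built-area fraction, so
#' every score lies in \[0, 1\]: 1 means the entire classified city area
#' sits in classes the measure targets.
#'
#' @param profile an `lcz_profile` from [class_shares()], or a named share
#'   vector (names are LCZ codes).
#' @param matrix a `measure_matrix` from [load_measure_matrix()].
#' @return Named numeric vector, one score per measure.
#' @export
score_city <- function(profile, matrix = load_measure_matrix()) {
  shares <- if (inherits(profile, "lcz_profile")) profile$shares else profile
  w <- full_weight_matrix(matrix)
  s <- stats::setNames(numeric(17L), as.character(1:17))
  common <- intersect(names(shares), names(s))
  s[common] <- shares[common]
  drop(w %*% s)
}

#' Score a table of city LCZ profiles
#'
#' @param profile_table output of [lcz_profile_table()] (needs the
#'   `share_<code>` columns).
#' @param matrix a `measure_matrix`.
#' @return data.frame: city_id, name, continent, one column per measure.
#' @export
score_cities <- function(profile_table, matrix = load_measure_matrix()) {
  share_cols <- paste0("share_", 1:17)
  missing <- setdiff(share_cols, names(profile_table))
  if (length(missing))
    stop("profile table lacks columns: ", paste(missing, collapse = ", "))
  sh <- as.matrix(profile_table[, share_cols])
  colnames(sh) <- as.character(1:17)
  scores <- sh %*% t(full_weight_matrix(matrix))
  cbind(profile_table[, intersect(c("city_id", "name", "continent"),
                                  names(profile_table)), drop = FALSE],
        as.data.frame(scores, check.names = FALSE))
}

#' Aggregate adaptation scores by continent
#'
#' Sums (total adaptation potential) or averages (per-city potential) the
#' measure scores over the cities of each continent. By default the input
#' is restricted to exceeding cities — the population the scores are meant
#' to prioritize — via the logical `exceeder` column when present.
#'
#' @param scores_table output of [score_cities()], optionally with a
#'   logical `exceeder` column.
#' @param mode `"sum"` or `"mean"`.
#' @param exceeders_only restrict to rows with `exceeder == TRUE` (ignored
#'   when the column is absent).
#' @return data.frame: continent, mode, n_cities, one column per measure.
#'   Continents left with zero cities are omitted with a warning.
#' @export
aggregate_scores <- function(scores_table, mode = c("sum", "mean"),
                             exceeders_only = TRUE) {
  mode <- match.arg(mode)
  tab <- scores_table
  if (exceeders_only && "exceeder" %in% names(tab)) {
    dropped <- setdiff(unique(tab$continent),
                       unique(tab$continent[tab$exceeder]))
    if (length(dropped))
      warning("continent(s) with no exceeding cities omitted: ",
              paste(dropped, collapse = ", "))
    tab <- tab[tab$exceeder, ]
  }
  if (!nrow(tab)) stop("no cities to aggregate")
  measure_cols <- setdiff(names(tab),
                          c("city_id", "name", "continent", "exceeder"))
  f <- if (mode == "sum") sum else mean
  agg <- stats::aggregate(tab[, measure_cols, drop = FALSE],
                          by = list(continent = tab$continent), FUN = f)
  n <- stats::aggregate(list(n_cities = rep(1L, nrow(tab))),
                        by = list(continent = tab$continent), FUN = sum)
  out <- merge(n, agg, by = "continent")
  out$mode <- mode
  out[, c("continent", "mode", "n_cities", measure_cols)]
}
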