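#' Configuration for the synthetic study region
#'
#' Bundles every knob of the synthetic-world generator: how many cities,
#' where they sit, their baseline climate and scenario warming, their
#' populations, Local Climate Zone (LCZ) make-up and economic weight. The
#' defaults describe a 120-city world with three emission scenarios
#' (SSP1-2.6 / SSP3-7.0 / SSP5-8.5), three 30-year periods against a
#' 1981-2010 reference, and two LCZ regimes: cities planted above the 29
#' degC end-of-century niche threshold draw their LCZ composition from a
#' "hot" regime with more bare surface (LCZ E/F) and less vegetation
#' (LCZ A-D) than the "cool" regime.
#'
#' @param n_cities number of cities.
#' @param continent_weights named sampling weights over the six continents.
#' @param scenarios,periods,reference_period scenario and period labels.
#' @param pop_years population mapping years, aligned with `periods`.
#' @param baseline_mat 6 x 2 matrix (`mean`, `sd` columns, continent rows)
#'   of reference-period mean annual temperature, degC.
#' @param warming_mean scenarios x periods matrix of mean warming vs. the
#'   reference period, degC; `warming_sd` the common draw sd.
#' @param threshold_high niche threshold (degC) used for exceeder planting
#'   and the hot-regime rule.
#' @param hot_scenario scenario whose terminal-period MAT drives the
#'   hot-regime rule (and exceeder planting).
#' @param n_exceeders when non-`NULL`, exactly this many cities are planted
#'   strictly above `threshold_high` for `hot_scenario` in the terminal
#'   period, all others strictly below.
#' @param mat_noise_sd sd of optional iid cell noise added to MAT rasters
#'   inside city footprints (0 = exact planted values).
#' @param lcz_hot,lcz_cool Dirichlet concentration vectors (length 17) for
#'   the two LCZ regimes. Expected shares are `conc / sum(conc)`; the total
#'   concentration controls between-city spread.
#' @param lcz_mode `"largest_remainder"` realizes each city's drawn share
#'   vector exactly on its fine cells; `"multinomial"` samples cell counts.
#' @param pop_meanlog,pop_sdlog,pop_min log-normal parameters and floor
#'   (persons) for first-mapping-year city population.
#' @param growth_meanlog,growth_sdlog named log-normal growth factors
#'   between successive mapping years.
#' @param gdp_shape,gdp_scale gamma parameters for per-capita GDP (PPP,
#'   currency units per person); `gdp_scale` named per continent.
#' @param coarse_cell_size,fine_cell_size cell sizes in degrees; the fine
#'   (LCZ) size must divide the coarse size exactly.
#' @param city_cells_range inclusive range of city side lengths in coarse
#'   cells (minimum 2, so every city contains >= 4 coarse cell centers).
#' @param origin_lon west edge of the world, degrees.
#' @param seed integer seed; the generator is a pure function of
#'   (config, seed).
#' @return A validated `world_config` list.
#' @export
world_config <- function(
    n_cities = 120L,
    continent_weights = c("Africa" = 0.25, "Asia" = 0.35, "Europe" = 0.12,
                          "North America" = 0.10, "South America" = 0.12,
                          "Oceania" = 0.06),
    scenarios = c("SSP1-2.6", "SSP3-7.0", "SSP5-8.5"),
    periods = c("2011-2040", "2041-2070", "2071-2100"),
    reference_period = "1981-2010",
    pop_years = c(2025L, 2070L, 2100L),
    baseline_mat = default_baseline_mat(),
    warming_mean = default_warming_mean(scenarios, periods),
    warming_sd = 0.4,
    threshold_high = 29,
    hot_scenario = "SSP5-8.5",
    n_exceeders = NULL,
    mat_noise_sd = 0,
    lcz_hot = default_lcz_concentration("hot"),
    lcz_cool = default_lcz_concentration("cool"),
    lcz_mode = c("largest_remainder", "multinomial"),
    pop_meanlog = log(7e5), pop_sdlog = 0.8, pop_min = 3e5,
    growth_meanlog = c("2070" = log(1.35), "2100" = log(1.15)),
    growth_sdlog = 0.3,
    gdp_shape = 4,
    gdp_scale = c("Africa" = 1200, "Asia" = 5000, "Europe" = 14000,
                  "North America" = 16000, "South America" = 4200,
                  "Oceania" = 13000),
    coarse_cell_size = 0.1, fine_cell_size = 0.02,
    city_cells_range = c(2L, 4L),
    origin_lon = 0,
    seed = 1L) {
  lcz_mode <- match.arg(lcz_mode)
  cfg <- as.list(environment())
  class(cfg) <- "world_config"
  validate_world_config(cfg)
  cfg
}

validate_world_config <- function(cfg) {
  stopifnot(cfg$n_cities >= 1, all(cfg$continent_weights >= 0),
            cfg$warming_sd >= 0, cfg$mat_noise_sd >= 0,
            cfg$pop_sdlog >= 0, cfg$growth_sdlog >= 0)
  if (length(cfg$periods) != length(cfg$pop_years))
    stop("pop_years must align one-to-one with periods")
  if (any(cfg$lcz_hot <= 0) || any(cfg$lcz_cool <= 0))
    stop("Dirichlet concentrations must be > 0")
  if (length(cfg$lcz_hot) != 17L || length(cfg$lcz_cool) != 17L)
    stop("LCZ concentration vectors must have length 17")
  ratio <- cfg$coarse_cell_size / cfg$fine_cell_size
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("fine_cell_size must divide coarse_cell_size exactly (got ratio ",
         ratio, ")")
  if (any(cfg$baseline_mat[, "sd"] < 0)) stop("baseline sd must be >= 0")
  if (!cfg$hot_scenario %in% cfg$scenarios)
    stop("hot_scenario must be one of the configured scenarios")
  if (cfg$city_cells_range[1L] < 2L)
    stop("cities must span at least 2 coarse cells per side")
  if (!is.null(cfg$n_exceeders) && cfg$n_exceeders > cfg$n_cities)
    stop("n_exceeders cannot exceed n_cities")
  invisible(cfg)
}

#' @rdname world_config
#' @export
default_baseline_mat <- function() {
  m <- rbind("Africa" = c(25, 2.5), "Asia" = c(20, 5), "Europe" = c(10, 3),
             "North America" = c(13, 5), "South America" = c(21, 4),
             "Oceania" = c(18, 3))
  colnames(m) <- c("mean", "sd")
  m
}

#' @rdname world_config
#' @export
default_warming_mean <- function(scenarios = c("SSP1-2.6", "SSP3-7.0",
                                               "SSP5-8.5"),
                                 periods = c("2011-2040", "2041-2070",
                                             "2071-2100")) {
  m <- rbind(c(0.8, 1.2, 1.3),   # low emissions: warming plateaus
             c(1.0, 2.2, 3.5),   # intermediate, high growth
             c(1.2, 2.7, 4.3))   # high emissions
  dimnames(m) <- list(scenarios, periods)
  m
}

#' Default LCZ Dirichlet concentrations
#'
#' Expected shares times a total concentration of 55, which gives a
#' between-city spread of about 4 percentage points on a class with a 10%
#' expected share. The hot regime carries more bare surface (E+F: 17% vs
#' 7%) and less vegetation (A-C: 9% vs 18%; D: 9% vs 12%) than the cool
#' regime, the morphology contrast the exceeder comparison is designed to
#' detect.
#'
#' @param regime `"hot"` or `"cool"`.
#' @param total total Dirichlet concentration.
#' @return Numeric vector of length 17, names `"1"`-`"17"`.
#' @export
default_lcz_concentration <- function(regime = c("cool", "hot"),
                                      total = 55) {
  regime <- match.arg(regime)
  shares <- switch(regime,
    cool = c(0.01, 0.03, 0.08, 0.03, 0.06, 0.18, 0.03, 0.07, 0.08, 0.02,
             0.08, 0.06, 0.04, 0.12, 0.03, 0.04, 0.04),
    hot  = c(0.01, 0.04, 0.09, 0.03, 0.06, 0.17, 0.05, 0.08, 0.07, 0.02,
             0.04, 0.03, 0.02, 0.09, 0.07, 0.10, 0.03))
  stats::setNames(shares * total, as.character(1:17))
}

# Run code with a private RNG stream seeded from `seed`, restoring the
# caller's RNG state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  code
}

#' Largest-remainder integer allocation
#'
#' Allocates `n` units to categories proportionally to `weights`: each
#' category gets the floor of its exact quota, and the leftover units go to
#' the categories with the largest fractional remainders (ties broken by
#' lowest index). Deterministic, and exact whenever the quotas are whole
#' numbers — which is why the generator uses it to realize LCZ share
#' vectors on fine cells.
#'
#' @param weights non-negative weights (at least one positive).
#' @param n total units to allocate.
#' @return Integer vector summing to `n`.
#' @export
allocate_largest_remainder <- function(weights, n) {
  stopifnot(all(weights >= 0), sum(weights) > 0, n >= 0)
  q <- weights / sum(weights) * n
  base <- floor(q + 1e-9)          # guard against 49.999999... quotas
  rem <- as.integer(round(n - sum(base)))
  if (rem > 0L) {
    ord <- order(-(q - base), seq_along(q))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Draw per-city LCZ share vectors for a regime
#'
#' Dirichlet draws from the configured concentration vector. Uses the
#' current RNG state; seed externally for reproducibility.
#'
#' @param config a [world_config()].
#' @param regime `"hot"` or `"cool"`.
#' @param n number of cities to draw.
#' @return n x 17 matrix of share vectors (rows sum to 1).
#' @export
sample_lcz_shares <- function(config, regime = c("cool", "hot"), n) {
  regime <- match.arg(regime)
  conc <- if (regime == "hot") config$lcz_hot else config$lcz_cool
  g <- matrix(stats::rgamma(n * 17L, shape = rep(conc, each = n)),
              nrow = n, ncol = 17L)
  sh <- g / rowSums(g)
  colnames(sh) <- as.character(1:17)
  sh
}

#' Shift the hot-regime expected share of one LCZ class
#'
#' Returns a config whose hot-regime *expected* share of `target_class` is
#' raised by `delta`, with the remaining classes scaled down proportionally
#' so expected shares still sum to 1. Total Dirichlet concentration (hence
#' between-city spread) is preserved. Used to plant effect sizes for power
#' studies of the exceeder / non-exceeder share comparison.
#'
#' @param config a [world_config()].
#' @param delta share-point shift, `0 <= delta <= 1 - current share`.
#' @param target_class integer LCZ code (1-17).
#' @return A modified `world_config`.
#' @export
perturb_group_shares <- function(config, delta, target_class) {
  stopifnot(target_class %in% 1:17)
  if (isTRUE(delta == 0)) return(config)
  conc <- config$lcz_hot
  total <- sum(conc)
  p <- conc / total
  t <- as.integer(target_class)
  if (delta < 0 || p[t] + delta > 1)
    stop("infeasible delta ", delta, ": target share is ", signif(p[t], 4),
         ", shift must lie in [0, ", signif(1 - p[t], 4), "]")
  p_new <- p * (1 - p[t] - delta) / (1 - p[t])
  p_new[t] <- p[t] + delta
  config$lcz_hot <- stats::setNames(p_new * total, names(conc))
  validate_world_config(config)
  config
}

#' Truth-table column name for a scenario x period MAT
#' @param scenario,period labels.
#' @return Column name string.
#' @export
mat_col_name <- function(scenario, period) paste0("mat_", scenario, "_", period)

#' Generate a synthetic study region with planted ground truth
#'
#' Builds a complete synthetic world: non-overlapping axis-aligned city
#' footprints snapped to coarse cell boundaries, coarse continuous rasters
#' (MAT per scenario x period plus reference, population per mapping year,
#' GDP), a fine categorical LCZ raster nested inside the coarse grid, and a
#' truth table holding every planted quantity. Within each footprint the
#' MAT raster is constant at the planted value (plus optional cell noise);
#' population and GDP totals are allocated to cells integer-exactly
#' (remainder to the first cell, row-major), so downstream zonal sums have
#' an exact expected value; the LCZ raster realizes each city's drawn share
#' vector by deterministic largest-remainder allocation. The same seed
#' gives bit-identical output.
#'
#' @param config a [world_config()].
#' @return A `synthetic_world`: list with `config`, `boundaries` (named
#'   list of [city_boundary()]), `truth` (data.frame, one row per city),
#'   and `rasters` (`mat[[scenario]][[period]]`, `mat_reference`,
#'   `population[[year]]`, `gdp`, `lcz`).
#' @export
generate_world <- function(config) {
  validate_world_config(config)
  with_seed(config$seed, generate_world_impl(config))
}

generate_world_impl <- function(cfg) {
  n <- as.integer(cfg$n_cities)
  continents <- sample(names(cfg$continent_weights), n, replace = TRUE,
                       prob = cfg$continent_weights)
  k <- sample(seq(cfg$city_cells_range[1L], cfg$city_cells_range[2L]),
              n, replace = TRUE)                      # rows (coarse cells)
  m <- sample(seq(cfg$city_cells_range[1L], cfg$city_cells_range[2L]),
              n, replace = TRUE)                      # cols

  # -- layout: one city per slot on a square-ish slot grid, 1-cell gaps --
  slot_cells <- max(cfg$city_cells_range) + 1L
  n_slot_cols <- ceiling(sqrt(n))
  n_slot_rows <- ceiling(n / n_slot_cols)
  nr <- n_slot_rows * slot_cells + 1L                 # coarse grid dims
  nc <- n_slot_cols * slot_cells + 1L
  width <- nc * cfg$coarse_cell_size
  height <- nr * cfg$coarse_cell_size
  if (width > 350 || height > 170)
    stop("cannot place ", n, " non-overlapping cities at cell size ",
         cfg$coarse_cell_size,
         " within geographic bounds; use a larger extent ",
         "(smaller cells or fewer cities)")
  origin_lon <- cfg$origin_lon
  origin_lat <- height                                 # yllcorner at 0

  slot_row <- (seq_len(n) - 1L) %/% n_slot_cols        # 0-based
  slot_col <- (seq_len(n) - 1L) %% n_slot_cols
  r0 <- slot_row * slot_cells + 1L                     # 0-based coarse offset
  c0 <- slot_col * slot_cells + 1L

  city_id <- sprintf("city_%03d", seq_len(n))
  boundaries <- vector("list", n)
  for (i in seq_len(n)) {
    lon_w <- origin_lon + c0[i] * cfg$coarse_cell_size
    lon_e <- lon_w + m[i] * cfg$coarse_cell_size
    lat_n <- origin_lat - r0[i] * cfg$coarse_cell_size
    lat_s <- lat_n - k[i] * cfg$coarse_cell_size
    ring <- rbind(c(lon_w, lat_s), c(lon_e, lat_s), c(lon_e, lat_n),
                  c(lon_w, lat_n), c(lon_w, lat_s))
    boundaries[[i]] <- city_boundary(city_id[i],
                                     sprintf("City %03d", i),
                                     continents[i], ring)
  }
  names(boundaries) <- city_id

  # -- planted climate ------------------------------------------------
  baseline <- stats::rnorm(n, cfg$baseline_mat[continents, "mean"],
                           cfg$baseline_mat[continents, "sd"])
  n_per <- length(cfg$periods)
  terminal <- cfg$periods[n_per]
  mat <- array(NA_real_, c(n, length(cfg$scenarios), n_per),
               dimnames = list(city_id, cfg$scenarios, cfg$periods))
  for (s in cfg$scenarios)
    for (p in cfg$periods)
      mat[, s, p] <- baseline +
        stats::rnorm(n, cfg$warming_mean[s, p], cfg$warming_sd)

  if (!is.null(cfg$n_exceeders)) {
    # plant the exceeder set exactly: chosen cities strictly above the
    # threshold for hot_scenario in the terminal period, the rest strictly
    # below
    exc <- sample(n, cfg$n_exceeders)
    thr <- cfg$threshold_high
    mat[exc, cfg$hot_scenario, terminal] <-
      thr + 0.2 + stats::rexp(length(exc), rate = 1 / 1.2)
    if (length(exc)) {
      # keep warming increments realistic for planted exceeders: re-derive
      # their baseline from the planted terminal MAT and shift every other
      # (scenario, period) MAT coherently
      new_base <- mat[exc, cfg$hot_scenario, terminal] -
        stats::rnorm(length(exc),
                     cfg$warming_mean[cfg$hot_scenario, terminal],
                     cfg$warming_sd)
      shift <- new_base - baseline[exc]
      baseline[exc] <- new_base
      for (s in cfg$scenarios)
        for (p in cfg$periods)
          if (!(s == cfg$hot_scenario && p == terminal))
            mat[exc, s, p] <- mat[exc, s, p] + shift
    }
    rest <- setdiff(seq_len(n), exc)
    too_hot <- rest[mat[rest, cfg$hot_scenario, terminal] > thr - 0.1]
    if (length(too_hot))
      mat[too_hot, cfg$hot_scenario, terminal] <-
        thr - 0.1 - stats::runif(length(too_hot), 0, 1.5)
  }

  term_mat <- matrix(mat[, , terminal], nrow = n,
                     dimnames = list(city_id, cfg$scenarios))
  exceeds <- term_mat > cfg$threshold_high
  hot <- exceeds[, cfg$hot_scenario]

  # -- LCZ shares (drawn per city in id order) ------------------------
  shares_drawn <- matrix(NA_real_, n, 17L,
                         dimnames = list(city_id, as.character(1:17)))
  for (i in seq_len(n)) {
    regime <- if (hot[i]) "hot" else "cool"
    shares_drawn[i, ] <- sample_lcz_shares(cfg, regime, 1L)
  }

  # -- population and GDP ---------------------------------------------
  yrs <- as.character(cfg$pop_years)
  pop <- matrix(NA_real_, n, length(yrs), dimnames = list(city_id, yrs))
  pop[, 1L] <- pmax(cfg$pop_min,
                    round(stats::rlnorm(n, cfg$pop_meanlog, cfg$pop_sdlog)))
  for (j in seq_along(yrs)[-1L]) {
    gm <- cfg$growth_meanlog[yrs[j]]
    if (is.na(gm)) gm <- 0
    pop[, j] <- round(pop[, j - 1L] *
                        stats::rlnorm(n, gm, cfg$growth_sdlog))
  }
  gdp_percap <- stats::rgamma(n, shape = cfg$gdp_shape,
                              scale = cfg$gdp_scale[continents])
  gdp_total <- round(gdp_percap * pop[, 1L])

  # -- rasterization ---------------------------------------------------
  make_coarse <- function(fill = NA_real_)
    geo_grid(matrix(fill, nr, nc), origin_lon, origin_lat,
             cfg$coarse_cell_size, cfg$coarse_cell_size)
  mat_rasters <- lapply(cfg$scenarios, function(s) {
    per <- lapply(cfg$periods, function(p) {
      g <- make_coarse()
      for (i in seq_len(n)) {
        rows <- (r0[i] + 1L):(r0[i] + k[i]); cols <- (c0[i] + 1L):(c0[i] + m[i])
        v <- mat[i, s, p]
        if (cfg$mat_noise_sd > 0)
          v <- v + stats::rnorm(k[i] * m[i], 0, cfg$mat_noise_sd)
        g$values[rows, cols] <- v
      }
      g
    })
    names(per) <- cfg$periods
    per
  })
  names(mat_rasters) <- cfg$scenarios
  ref <- make_coarse()
  for (i in seq_len(n)) {
    rows <- (r0[i] + 1L):(r0[i] + k[i]); cols <- (c0[i] + 1L):(c0[i] + m[i])
    v <- baseline[i]
    if (cfg$mat_noise_sd > 0)
      v <- v + stats::rnorm(k[i] * m[i], 0, cfg$mat_noise_sd)
    ref$values[rows, cols] <- v
  }

  # integer-exact totals: each cell gets the quotient, first cell (row-major
  # within the footprint) also the remainder
  allocate_total <- function(g, i, total) {
    rows <- (r0[i] + 1L):(r0[i] + k[i]); cols <- (c0[i] + 1L):(c0[i] + m[i])
    ncell <- k[i] * m[i]
    q <- total %/% ncell; rrem <- total %% ncell
    block <- matrix(q, k[i], m[i])
    block[1L, 1L] <- q + rrem
    g$values[rows, cols] <- block
    g
  }
  pop_rasters <- lapply(yrs, function(y) {
    g <- make_coarse(0)
    for (i in seq_len(n)) g <- allocate_total(g, i, pop[i, y])
    g
  })
  names(pop_rasters) <- yrs
  gdp_raster <- make_coarse(0)
  for (i in seq_len(n)) gdp_raster <- allocate_total(gdp_raster, i, gdp_total[i])

  # fine LCZ raster, nested inside the coarse grid
  f <- as.integer(round(cfg$coarse_cell_size / cfg$fine_cell_size))
  lcz_vals <- matrix(NA_integer_, nr * f, nc * f)
  shares_real <- matrix(NA_real_, n, 17L,
                        dimnames = list(city_id, as.character(1:17)))
  for (i in seq_len(n)) {
    frows <- (r0[i] * f + 1L):((r0[i] + k[i]) * f)
    fcols <- (c0[i] * f + 1L):((c0[i] + m[i]) * f)
    n_fine <- length(frows) * length(fcols)
    counts <- if (cfg$lcz_mode == "largest_remainder") {
      allocate_largest_remainder(shares_drawn[i, ], n_fine)
    } else {
      as.integer(stats::rmultinom(1L, n_fine, shares_drawn[i, ]))
    }
    codes <- rep.int(1:17, counts)
    lcz_vals[frows, fcols] <- matrix(codes, length(frows), length(fcols),
                                     byrow = TRUE)
    shares_real[i, ] <- counts / n_fine
  }
  lcz_raster <- class_grid(lcz_vals, origin_lon, origin_lat,
                           cfg$fine_cell_size, cfg$fine_cell_size)

  # -- truth table ------------------------------------------------------
  truth <- data.frame(city_id = city_id,
                      name = sprintf("City %03d", seq_len(n)),
                      continent = continents,
                      baseline_mat = baseline,
                      stringsAsFactors = FALSE, check.names = FALSE)
  for (s in cfg$scenarios)
    for (p in cfg$periods)
      truth[[mat_col_name(s, p)]] <- mat[, s, p]
  for (y in yrs) truth[[paste0("pop_", y)]] <- pop[, y]
  truth$gdp_total <- gdp_total
  for (code in 1:17) truth[[paste0("share_", code)]] <- shares_real[, code]
  for (s in cfg$scenarios)
    truth[[paste0("exceeds29_", s)]] <- exceeds[, s]

  structure(list(config = cfg, boundaries = boundaries, truth = truth,
                 rasters = list(mat = mat_rasters, mat_reference = ref,
                                population = pop_rasters, gdp = gdp_raster,
                                lcz = lcz_raster)),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("<synthetic_world> %d cities, %d scenarios x %d periods, seed %d\n",
              nrow(x$truth), length(x$config$scenarios),
              length(x$config$periods), x$config$seed))
  invisible(x)
}
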