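#' Write a synthetic world to disk in pipeline input format
#'
#' Generates (or accepts) a synthetic world and writes it in the same
#' formats real-data mode consumes: ESRI ASCII rasters under `rasters/`,
#' boundaries as GeoJSON, the planted truth table as CSV, plus a
#' `world.json` index naming every layer. Idempotent for a fixed seed:
#' rerunning produces byte-identical files.
#'
#' @param config a [world_config()], or an already generated
#'   `synthetic_world`.
#' @param out_dir output directory (created if needed).
#' @return The `synthetic_world`, invisibly.
#' @export
simulate_world <- function(config, out_dir) {
  world <- if (inherits(config, "synthetic_world")) config
           else generate_world(config)
  cfg <- world$config
  rdir <- file.path(out_dir, "rasters")
  dir.create(rdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(rdir)) stop("cannot create output directory: ", out_dir)
  layers <- list(mat = list(), population = list())
  for (s in cfg$scenarios) {
    layers$mat[[s]] <- list()
    for (p in cfg$periods) {
      fn <- file.path("rasters", paste0("mat_", s, "_", p, ".asc"))
      write_raster(world$rasters$mat[[s]][[p]], file.path(out_dir, fn))
      layers$mat[[s]][[p]] <- fn
    }
  }
  write_raster(world$rasters$mat_reference,
               file.path(out_dir, "rasters", "mat_reference.asc"))
  layers$mat_reference <- "rasters/mat_reference.asc"
  for (y in names(world$rasters$population)) {
    fn <- file.path("rasters", paste0("pop_", y, ".asc"))
    write_raster(world$rasters$population[[y]], file.path(out_dir, fn))
    layers$population[[y]] <- fn
  }
  write_raster(world$rasters$gdp, file.path(out_dir, "rasters", "gdp.asc"))
  layers$gdp <- "rasters/gdp.asc"
  write_raster(world$rasters$lcz, file.path(out_dir, "rasters", "lcz.asc"))
  layers$lcz <- "rasters/lcz.asc"
  write_boundaries(world$boundaries, file.path(out_dir, "boundaries.geojson"))
  layers$boundaries <- "boundaries.geojson"
  utils::write.csv(world$truth, file.path(out_dir, "truth.csv"),
                   row.names = FALSE)
  layers$truth <- "truth.csv"
  idx <- list(scenarios = cfg$scenarios, periods = cfg$periods,
              reference_period = cfg$reference_period,
              pop_years = cfg$pop_years, seed = cfg$seed, layers = layers)
  writeLines(jsonlite::toJSON(idx, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             file.path(out_dir, "world.json"))
  invisible(world)
}

#' Load pipeline inputs written by [simulate_world()] (or assembled by hand)
#'
#' @param in_dir directory containing `world.json` and the layers it names.
#' @return List with `scenarios`, `periods`, `pop_years`, `rasters`,
#'   `boundaries`.
#' @export
load_world_inputs <- function(in_dir) {
  idx_path <- file.path(in_dir, "world.json")
  if (!file.exists(idx_path))
    stop("no world.json index in ", in_dir)
  idx <- jsonlite::fromJSON(idx_path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  need_layer <- function(fn, what) {
    path <- file.path(in_dir, fn)
    if (is.null(fn) || !file.exists(path))
      stop("missing input layer '", what, "' (", fn, ") in ", in_dir)
    path
  }
  mat <- lapply(idx$scenarios, function(s) {
    per <- lapply(idx$periods, function(p)
      read_raster(need_layer(idx$layers$mat[[s]][[p]],
                             paste("mat", s, p))))
    names(per) <- idx$periods
    per
  })
  names(mat) <- idx$scenarios
  pop <- lapply(as.character(idx$pop_years), function(y)
    read_raster(need_layer(idx$layers$population[[y]], paste("pop", y))))
  names(pop) <- as.character(idx$pop_years)
  list(scenarios = idx$scenarios, periods = idx$periods,
       pop_years = idx$pop_years,
       rasters = list(
         mat = mat,
         mat_reference = read_raster(need_layer(idx$layers$mat_reference,
                                                "mat_reference")),
         population = pop,
         gdp = read_raster(need_layer(idx$layers$gdp, "gdp")),
         lcz = read_raster(need_layer(idx$layers$lcz, "lcz"),
                           categorical = TRUE)),
       boundaries = read_boundaries(need_layer(idx$layers$boundaries,
                                               "boundaries")))
}

#' Run the full screening, morphology, scoring and capacity pipeline
#'
#' Orchestrates every analysis stage in dependency order: per-city zonal
#' MAT records with niche bands and delta MAT, population exposure
#' accounting, continental delta-MAT summaries, LCZ profiles and grouped
#' shares, the exceeder / non-exceeder Welch comparison, median-position
#' diagnostics, adaptation-measure scores with continental aggregation,
#' and the GDP capacity overlay. All stage outputs are written as CSV
#' under `out_dir` together with a `manifest.json` recording an md5 hash
#' per file and an overall run hash; identical inputs and options give
#' byte-identical outputs.
#'
#' @param input a `synthetic_world`, or a directory path readable by
#'   [load_world_inputs()].
#' @param out_dir output directory for the result bundle.
#' @param focal_scenario scenario used for the morphology comparison,
#'   scores and capacity overlay (default: last scenario).
#' @param low,high niche thresholds (degC).
#' @param alpha significance level for the comparison flags.
#' @param grouping LCZ grouping (default [lcz_default_grouping()]).
#' @param popmap period to population-year map.
#' @param correction p-value correction mode for [compare_all()].
#' @return List of the result tables (also on disk), invisibly.
#' @export
run_pipeline <- function(input, out_dir, focal_scenario = NULL,
                         low = 27, high = 29, alpha = 0.05,
                         grouping = lcz_default_grouping(),
                         popmap = default_period_popmap(),
                         correction = "none") {
  inputs <- if (inherits(input, "synthetic_world")) {
    list(scenarios = input$config$scenarios, periods = input$config$periods,
         pop_years = input$config$pop_years, rasters = input$rasters,
         boundaries = input$boundaries)
  } else load_world_inputs(input)
  if (is.null(focal_scenario))
    focal_scenario <- inputs$scenarios[length(inputs$scenarios)]
  if (!focal_scenario %in% inputs$scenarios)
    stop("focal_scenario '", focal_scenario, "' not among inputs: ",
         paste(inputs$scenarios, collapse = ", "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  terminal <- inputs$periods[length(inputs$periods)]
  bnd <- inputs$boundaries

  records <- city_mat_records(inputs$rasters$mat,
                              inputs$rasters$mat_reference, bnd,
                              low = low, high = high)
  populations <- do.call(rbind, lapply(names(inputs$rasters$population),
    function(y) data.frame(
      city_id = vapply(bnd, `[[`, character(1), "city_id"),
      year = as.integer(y),
      population = vapply(bnd, function(b)
        zonal_sum(inputs$rasters$population[[y]], b), numeric(1)),
      stringsAsFactors = FALSE, row.names = NULL)))
  exposure <- screen_exposure(records, populations, popmap = popmap)
  continental <- continental_summary(records, period = terminal)

  profiles <- lcz_profile_table(inputs$rasters$lcz, bnd, grouping = grouping)
  term <- records[records$scenario == focal_scenario &
                    records$period == terminal,
                  c("city_id", "mat")]
  city_table <- merge(profiles, term, by = "city_id")
  comparison <- compare_all(city_table, group_cols = names(grouping),
                            threshold = high, alpha = alpha,
                            correction = correction)
  diagnostics <- data.frame(
    diagnostic = c("bare_natural_above_median", "green_below_median",
                   "low_plants_below_median"),
    fraction = c(
      median_position_diagnostic(city_table, "bare_natural", "above", high),
      median_position_diagnostic(city_table, "green", "below", high),
      median_position_diagnostic(city_table, "low_plants", "below", high)),
    stringsAsFactors = FALSE)

  scores <- score_cities(profiles)
  scores$exceeder <- scores$city_id %in% term$city_id[term$mat > high]
  if (any(scores$exceeder)) {
    scores_sum <- suppressWarnings(aggregate_scores(scores, "sum"))
    scores_mean <- suppressWarnings(aggregate_scores(scores, "mean"))
  } else {
    # no exceeders anywhere: emit empty tables rather than failing the run
    empty <- aggregate_scores(scores, "sum", exceeders_only = FALSE)[0, ]
    scores_sum <- scores_mean <- empty
  }

  mat_terminal <- stats::setNames(term$mat, term$city_id)
  capacity <- capacity_table(bnd, inputs$rasters$gdp, mat_terminal,
                             threshold = high)
  capacity_sum <- capacity_summary(capacity, threshold = high)

  tables <- list(records = records, populations = populations,
                 exposure = exposure, continental_delta = continental,
                 lcz_profiles = profiles, comparison = comparison,
                 median_diagnostics = diagnostics, scores = scores,
                 scores_continent_sum = scores_sum,
                 scores_continent_mean = scores_mean,
                 capacity = capacity, capacity_summary = capacity_sum)
  files <- character(0)
  for (nm in names(tables)) {
    fn <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], fn, row.names = FALSE)
    files[nm] <- fn
  }
  hashes <- tools::md5sum(unname(files))
  names(hashes) <- basename(names(hashes))
  run_hash <- md5_of_string(paste(names(hashes), hashes, collapse = "\n"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("urbanheat")),
    options = list(focal_scenario = focal_scenario, low = low, high = high,
                   alpha = alpha, correction = correction,
                   terminal_period = terminal,
                   popmap = as.list(popmap)),
    files = as.list(hashes), run_hash = run_hash)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             file.path(out_dir, "manifest.json"))
  invisible(tables)
}

md5_of_string <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(x, tf)
  unname(tools::md5sum(tf))
}

#' Render a result bundle as a markdown report
#'
#' Summarizes a [run_pipeline()] bundle in the reporting shape of the
#' underlying analysis: exceeder counts and exposed populations per
#' scenario / period / band, continental delta-MAT medians, significant
#' LCZ contrasts, median-position diagnostics and the top-scoring measures
#' per continent. Missing tables are flagged as gaps rather than failing.
#'
#' @param bundle_dir directory written by [run_pipeline()].
#' @param path optional output path (default `report.md` in the bundle).
#' @return Character vector of report lines, invisibly.
#' @export
render_report <- function(bundle_dir, path = file.path(bundle_dir,
                                                       "report.md")) {
  rd <- function(nm) {
    fn <- file.path(bundle_dir, paste0(nm, ".csv"))
    if (file.exists(fn)) utils::read.csv(fn, check.names = FALSE,
                                         stringsAsFactors = FALSE)
    else NULL
  }
  L <- c("# Urban heat screening report", "")
  exposure <- rd("exposure")
  if (is.null(exposure)) {
    L <- c(L, "*GAP: exposure table missing*", "")
  } else {
    L <- c(L, "## Niche exceedance", "")
    above <- exposure[exposure$band == "above_29" &
                        exposure$continent == "ALL", ]
    if (sum(above$n_cities) == 0L) {
      L <- c(L, "No city exceeds the upper threshold in any scenario/period.",
             "")
    } else {
      for (i in seq_len(nrow(above)))
        L <- c(L, sprintf("- %s %s: %d cities above threshold, %.0f exposed residents",
                          above$scenario[i], above$period[i],
                          above$n_cities[i], above$population[i]))
      L <- c(L, "")
    }
  }
  cont <- rd("continental_delta")
  if (is.null(cont)) {
    L <- c(L, "*GAP: continental delta table missing*", "")
  } else {
    L <- c(L, "## Continental MAT change (terminal period, median [IQR])", "")
    for (i in seq_len(nrow(cont)))
      L <- c(L, sprintf("- %s, %s: +%.2f degC [%.2f, %.2f] (n=%d)",
                        cont$continent[i], cont$scenario[i], cont$median[i],
                        cont$q1[i], cont$q3[i], cont$n[i]))
    L <- c(L, "")
  }
  comparison <- rd("comparison")
  if (is.null(comparison)) {
    L <- c(L, "*GAP: comparison table missing*", "")
  } else {
    sig <- comparison[comparison$significant %in% TRUE, ]
    L <- c(L, "## Significant LCZ share contrasts (exceeders vs rest)", "")
    if (!nrow(sig)) L <- c(L, "None at the configured alpha.", "")
    else {
      for (i in seq_len(nrow(sig)))
        L <- c(L, sprintf("- %s / %s: mean %.3f (below) vs %.3f (above), p = %.2g",
                          sig$continent[i], sig$lcz_group[i],
                          sig$mean_below[i], sig$mean_above[i], sig$p[i]))
      L <- c(L, "")
    }
  }
  diag <- rd("median_diagnostics")
  if (!is.null(diag)) {
    L <- c(L, "## Median-position diagnostics (exceeding cities)", "")
    for (i in seq_len(nrow(diag)))
      L <- c(L, sprintf("- %s: %.1f%%", diag$diagnostic[i],
                        100 * diag$fraction[i]))
    L <- c(L, "")
  }
  sc <- rd("scores_continent_mean")
  if (is.null(sc)) {
    L <- c(L, "*GAP: continental scores missing*", "")
  } else {
    L <- c(L, "## Top adaptation measures per continent (mean score)", "")
    measure_cols <- setdiff(names(sc), c("continent", "mode", "n_cities"))
    for (i in seq_len(nrow(sc))) {
      v <- unlist(sc[i, measure_cols])
      top <- sort(v, decreasing = TRUE)[1:3]
      L <- c(L, sprintf("- %s: %s", sc$continent[i],
                        paste(sprintf("%s (%.2f)", names(top), top),
                              collapse = "; ")))
    }
    L <- c(L, "")
  }
  writeLines(L, path)
  invisible(L)
}
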