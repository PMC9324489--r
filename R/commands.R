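# file-name layout shared by the commands
run_paths <- function(cfg) {
  d <- cfg$output_dir
  list(
    dir = d,
    config = file.path(d, "config_used.yaml"),
    pop = file.path(d, "population.asc"),
    districts = file.path(d, "districts.asc"),
    district_info = file.path(d, "district_info.csv"),
    landuse = file.path(d, "landuse.asc"),
    weather = function(season) file.path(d, paste0("weather_", season, ".csv")),
    per_person = file.path(d, "per_person.csv"),
    district_season = file.path(d, "district_season.csv"),
    annual_summary = file.path(d, "annual_summary.csv"),
    intensity = file.path(d, "intensity_mm.asc"),
    compare_csv = file.path(d, "comparison_report.csv"),
    compare_txt = file.path(d, "comparison_report.txt"),
    sensitivity_grid = file.path(d, "sensitivity_grid.csv"),
    sensitivity_summary = file.path(d, "sensitivity_summary.csv")
  )
}

ensure_outdir <- function(paths, quiet) {
  if (!dir.exists(paths$dir)) {
    dir.create(paths$dir, recursive = TRUE)
    if (!quiet) message("created output directory ", paths$dir)
  }
}

log_flags <- function(cfg, quiet) {
  if (quiet) return(invisible(NULL))
  f <- cfg$flags
  message(sprintf(
    "model flags in effect: icl_unit=%s ie_grouping=%s vp_unit=%s hr=%g LR=%g seed=%d",
    f$icl_unit, f$ie_grouping, f$vp_unit, f$hr, f$lewis_ratio, cfg$seed))
}

#' Generate synthetic input fixtures for a run
#'
#' Writes the synthetic city (population, district labels and land-use
#' grids plus the district table) and the four seasonal weather series to
#' the configured output directory. Idempotent under a fixed seed: the same
#' configuration always produces byte-identical files.
#'
#' @param config A run configuration (YAML path, list, or `run_config`).
#' @param quiet Suppress progress messages.
#' @return Named list of the written file paths, invisibly.
#' @export
cmd_generate <- function(config = default_run_config(), quiet = FALSE) {
  cfg <- read_run_config(config)
  paths <- run_paths(cfg)
  ensure_outdir(paths, quiet)
  log_flags(cfg, quiet)
  city <- generate_city(config_city_spec(cfg))
  weather <- generate_weather(config_weather_spec(cfg), cfg$year)
  write_esri_ascii(city$pop, paths$pop)
  write_esri_ascii(evap_raster(city$districts$labels,
                               cellsize = city$districts$cellsize),
                   paths$districts)
  utils::write.csv(city$districts$info, paths$district_info,
                   row.names = FALSE)
  write_esri_ascii(evap_raster(city$landuse$codes + 0,
                               cellsize = city$landuse$cellsize),
                   paths$landuse)
  for (season in names(weather)) {
    utils::write.csv(weather[[season]], paths$weather(season),
                     row.names = FALSE)
  }
  write_run_config(cfg, paths$config)
  if (!quiet) message("synthetic inputs written to ", paths$dir)
  invisible(paths)
}

read_run_inputs <- function(cfg) {
  paths <- run_paths(cfg)
  need <- c(paths$pop, paths$districts, paths$district_info,
            vapply(c("spring", "summer", "autumn", "winter"),
                   paths$weather, character(1)))
  missing <- need[!file.exists(need)]
  if (length(missing) > 0) {
    stop("missing input file(s); run cmd_generate first: ",
         paste(missing, collapse = ", "))
  }
  pop_r <- read_esri_ascii(paths$pop)
  pop <- population_raster(pop_r$values, pop_r$cellsize, pop_r$xll,
                           pop_r$yll, pop_r$nodata)
  lab_r <- read_esri_ascii(paths$districts)
  info <- utils::read.csv(paths$district_info, stringsAsFactors = FALSE)
  districts <- district_map(matrix(as.integer(lab_r$values),
                                   nrow(lab_r$values)),
                            info, cellsize = lab_r$cellsize)
  weather <- lapply(c(spring = "spring", summer = "summer",
                      autumn = "autumn", winter = "winter"),
                    function(s) read_weather_csv(paths$weather(s)))
  list(pop = pop, districts = districts, weather = weather, paths = paths)
}

#' Run the evaporation pipeline
#'
#' Reads the generated inputs, integrates the per-person model over the
#' schedule and weather, upscales over the population raster, and writes
#' the per-person seasonal rates, the district-by-season table, the annual
#' summary and the per-cell intensity raster (mm/year).
#'
#' @inheritParams cmd_generate
#' @return List with `per_person` (litres/person by season + annual),
#'   `city` (the `city_result`), `annual_m3` and `intensity`
#'   (the mm/year raster), invisibly.
#' @export
cmd_run <- function(config = default_run_config(), quiet = FALSE) {
  cfg <- read_run_config(config)
  inputs <- read_run_inputs(cfg)
  paths <- inputs$paths
  log_flags(cfg, quiet)
  constants <- config_constants(cfg)
  person <- person_profile(cfg$person$ad)
  per_person <- annual_person_evaporation(
    inputs$weather, config_schedule(cfg), config_season_configs(cfg),
    person, default_activities(), constants)
  seasonal <- per_person[setdiff(names(per_person), "annual")]
  city <- district_totals(seasonal, inputs$districts, inputs$pop)
  annual_m3 <- annual_city_total(city)
  intensity <- intensity_raster(inputs$pop, per_person[["annual"]])

  utils::write.csv(
    data.frame(season = names(per_person),
               litres_per_person = as.numeric(per_person)),
    paths$per_person, row.names = FALSE)
  utils::write.csv(as.data.frame(city), paths$district_season,
                   row.names = FALSE)
  ui <- unit_area_intensity(annual_m3, cfg$comparison$city_area_km2)
  utils::write.csv(
    data.frame(quantity = c("annual_total_m3", "city_area_km2",
                            "intensity_m3_per_km2", "intensity_mm"),
               value = c(annual_m3, cfg$comparison$city_area_km2,
                         ui$m3_per_km2, ui$mm)),
    paths$annual_summary, row.names = FALSE)
  write_esri_ascii(intensity, paths$intensity)
  if (!quiet) {
    message(sprintf("annual city total: %.0f m^3 (%.2f mm over %.0f km^2)",
                    annual_m3, ui$mm, cfg$comparison$city_area_km2))
  }
  invisible(list(per_person = per_person, city = city,
                 annual_m3 = annual_m3, intensity = intensity))
}

#' Equivalence-accounting report for a finished run
#'
#' Computes the comparison block (equivalent forest area, green-space
#' parity, fraction of natural evapotranspiration, water-use multiples)
#' from a run's annual total and the generated land-use grid, and writes it
#' as CSV and readable text.
#'
#' @inheritParams cmd_generate
#' @param annual_m3 Annual total to compare; defaults to the value stored by
#'   [cmd_run()] in the output directory.
#' @return The report data frame, invisibly.
#' @export
cmd_compare <- function(config = default_run_config(), annual_m3 = NULL,
                        quiet = FALSE) {
  cfg <- read_run_config(config)
  paths <- run_paths(cfg)
  if (is.null(annual_m3)) {
    if (!file.exists(paths$annual_summary)) {
      stop("no annual summary found; run cmd_run first or pass annual_m3")
    }
    summ <- utils::read.csv(paths$annual_summary, stringsAsFactors = FALSE)
    annual_m3 <- summ$value[summ$quantity == "annual_total_m3"]
  }
  report <- comparison_report(annual_m3, cfg$comparison$city_area_km2,
                              cfg$comparison$natural_et_mm)
  if (file.exists(paths$landuse)) {
    lu_r <- read_esri_ascii(paths$landuse)
    lu <- land_use_grid(matrix(as.integer(lu_r$values), nrow(lu_r$values)),
                        cellsize = lu_r$cellsize)
    green <- green_space_evaporation(lu,
                                     green_codes = as.integer(cfg$comparison$green_codes))
    ratio <- human_vs_green_ratio(annual_m3, green$m3)
    report <- rbind(report, data.frame(
      metric = c("green_space_km2", "green_space_m3", "human_vs_green_pct"),
      value = c(green$green_km2, green$m3, ratio$percent),
      reported = c(round(green$green_km2, 3), round(green$m3),
                   ratio$percent_reported),
      units = c("km2", "m3", "%"),
      stringsAsFactors = FALSE))
    if (annual_m3 > 0) {
      # the matching density is undefined for a zero human volume
      dens <- equivalent_population_density(cfg$comparison$current_density,
                                            green$m3, annual_m3)
      report <- rbind(report, data.frame(
        metric = "equivalent_density", value = dens$density,
        reported = dens$density_reported, units = "people/km2",
        stringsAsFactors = FALSE))
    }
  }
  ensure_outdir(paths, quiet)
  utils::write.csv(report, paths$compare_csv, row.names = FALSE)
  writeLines(c("Equivalence accounting report",
               sprintf("annual human-body evaporation: %.0f m^3", annual_m3),
               sprintf("%-28s %14s %14s %s", "metric", "value", "reported",
                       "units"),
               sprintf("%-28s %14.4f %14.4f %s", report$metric, report$value,
                       report$reported, report$units)),
             paths$compare_txt)
  if (!quiet) message("comparison report written to ", paths$compare_csv)
  invisible(report)
}

#' Schedule sensitivity analysis for a run
#'
#' Re-evaluates the annual per-person total over the plausible
#' (sleep, moderate) grid and writes the grid and the extreme relative
#' changes.
#'
#' @inheritParams cmd_generate
#' @return The [schedule_sensitivity()] result, invisibly.
#' @export
cmd_sensitivity <- function(config = default_run_config(), quiet = FALSE) {
  cfg <- read_run_config(config)
  inputs <- read_run_inputs(cfg)
  paths <- inputs$paths
  sens <- schedule_sensitivity(inputs$weather, config_season_configs(cfg),
                               config_schedule(cfg),
                               person = person_profile(cfg$person$ad),
                               constants = config_constants(cfg))
  utils::write.csv(sens$grid, paths$sensitivity_grid, row.names = FALSE)
  utils::write.csv(
    data.frame(quantity = c("min_pct", "max_pct", "baseline_annual_l"),
               value = c(sens$min_pct, sens$max_pct, sens$baseline_annual)),
    paths$sensitivity_summary, row.names = FALSE)
  if (!quiet) {
    message(sprintf("schedule sensitivity: %+.2f%% to %+.2f%% of baseline",
                    sens$min_pct, sens$max_pct))
  }
  invisible(sens)
}
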