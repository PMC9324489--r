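# allowed keys per config section; unknown keys are rejected so that a
# misspelled model-interpretation flag can never be ignored silently
config_schema <- function() {
  list(
    top = c("schema_version", "seed", "year", "output_dir", "person",
            "schedule", "flags", "city", "weather", "seasons", "comparison"),
    person = c("ad"),
    schedule = c("sleep", "light", "moderate"),
    flags = c("icl_unit", "ie_grouping", "vp_unit", "hr", "lewis_ratio"),
    city = c("n_districts", "population", "nrow", "ncol", "cellsize",
             "density_scale", "density_noise", "green_fraction",
             "landuse_cellsize"),
    weather = c("means", "amplitudes", "noise_sd"),
    season = c("rh", "indoor_mode", "setpoint", "clip"),
    comparison = c("city_area_km2", "natural_et_mm", "green_codes",
                   "current_density")
  )
}

#' Default run configuration
#'
#' The full configuration of a pipeline run as a nested list, the same
#' structure the YAML config file carries. Defaults reproduce the package's
#' reference setup: the representative daily schedule, seasonal indoor
#' rules, default model-interpretation flags, a megacity-scale synthetic
#' city and monsoon-climate synthetic weather.
#'
#' @param seed Integer seed for all randomness of the run.
#' @param output_dir Directory where commands write their files.
#' @return Nested list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L, output_dir = "bodyevap-out") {
  structure(list(
    schema_version = 1L,
    seed = as.integer(seed),
    year = 2020L,
    output_dir = output_dir,
    person = list(ad = 1.8),
    schedule = list(sleep = 8, light = 14, moderate = 2),
    flags = list(icl_unit = "clo", ie_grouping = "quotient",
                 vp_unit = "kPa", hr = 4.7, lewis_ratio = 16.5),
    city = list(n_districts = 16L, population = 21890000, nrow = 128L,
                ncol = 128L, cellsize = 1000, density_scale = 0.35,
                density_noise = 0.3, green_fraction = 0.25,
                landuse_cellsize = 100),
    weather = list(means = list(spring = 13.5, summer = 26.0, autumn = 13.0,
                                winter = -1.5),
                   amplitudes = list(spring = 7, summer = 2, autumn = 8,
                                     winter = 3),
                   noise_sd = 2),
    seasons = list(
      spring = list(rh = 0.40, indoor_mode = "clipped", clip = c(16, 30)),
      summer = list(rh = 0.60, indoor_mode = "clipped", clip = c(16, 30)),
      autumn = list(rh = 0.50, indoor_mode = "clipped", clip = c(16, 30)),
      winter = list(rh = 0.30, indoor_mode = "fixed", setpoint = 22)
    ),
    comparison = list(city_area_km2 = 16410.54, natural_et_mm = 348,
                      green_codes = c(10L, 30L), current_density = 21800)
  ), class = "run_config")
}

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra) > 0) {
    stop("unknown configuration key(s) in ", where, ": ",
         paste(extra, collapse = ", "))
  }
}

# overlay user values onto the defaults, rejecting unknown keys
merge_config <- function(user) {
  sch <- config_schema()
  check_keys(user, sch$top, "config")
  cfg <- unclass(default_run_config())
  for (k in names(user)) {
    if (is.list(cfg[[k]]) && is.list(user[[k]])) {
      section <- if (k == "seasons") NULL else sch[[k]]
      if (k == "seasons") {
        check_keys(user$seasons, c("spring", "summer", "autumn", "winter"),
                   "seasons")
        for (s in names(user$seasons)) {
          check_keys(user$seasons[[s]], sch$season, paste0("seasons$", s))
          cfg$seasons[[s]][names(user$seasons[[s]])] <- user$seasons[[s]]
        }
      } else if (k == "weather") {
        check_keys(user$weather, sch$weather, "weather")
        for (w in names(user$weather)) cfg$weather[[w]] <- user$weather[[w]]
      } else {
        check_keys(user[[k]], section, k)
        cfg[[k]][names(user[[k]])] <- user[[k]]
      }
    } else {
      cfg[[k]] <- user[[k]]
    }
  }
  if (!identical(as.integer(cfg$schema_version), 1L)) {
    stop("unsupported config schema_version: ", cfg$schema_version)
  }
  structure(cfg, class = "run_config")
}

#' Read and validate a run configuration
#'
#' Accepts a YAML file path, a plain nested list, or an existing
#' `run_config`. User values are overlaid on [default_run_config()];
#' unknown keys anywhere in the document are errors.
#'
#' @param config Path to a YAML file, a list, or a `run_config`.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(config) {
  if (inherits(config, "run_config")) return(config)
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a YAML path or a list")
  merge_config(config)
}

#' Write a run configuration to YAML
#'
#' @param cfg A `run_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# derived model objects from a config ------------------------------------

config_constants <- function(cfg) {
  model_constants(hr = cfg$flags$hr, lewis_ratio = cfg$flags$lewis_ratio,
                  icl_unit = cfg$flags$icl_unit,
                  ie_grouping = cfg$flags$ie_grouping,
                  vp_unit = cfg$flags$vp_unit)
}

config_season_configs <- function(cfg, clothing = default_clothing()) {
  out <- lapply(names(cfg$seasons), function(s) {
    sc <- cfg$seasons[[s]]
    season_config(s, clothing[[s]], rh = sc$rh, indoor_mode = sc$indoor_mode,
                  setpoint = sc$setpoint,
                  clip = if (is.null(sc$clip)) c(16, 30) else as.numeric(sc$clip))
  })
  names(out) <- names(cfg$seasons)
  out
}

config_schedule <- function(cfg) {
  daily_schedule(cfg$schedule$sleep, cfg$schedule$light,
                 cfg$schedule$moderate)
}

config_city_spec <- function(cfg) {
  city_spec(n_districts = cfg$city$n_districts,
            population = cfg$city$population,
            nrow = cfg$city$nrow, ncol = cfg$city$ncol,
            cellsize = cfg$city$cellsize,
            density_scale = cfg$city$density_scale,
            density_noise = cfg$city$density_noise,
            green_fraction = cfg$city$green_fraction,
            landuse_cellsize = cfg$city$landuse_cellsize,
            seed = cfg$seed)
}

config_weather_spec <- function(cfg) {
  weather_spec(means = unlist(cfg$weather$means),
               amplitudes = unlist(cfg$weather$amplitudes),
               noise_sd = cfg$weather$noise_sd, seed = cfg$seed)
}
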