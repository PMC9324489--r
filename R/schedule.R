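#' Daily activity schedule
#'
#' Hours per day spent in each of the three activity classes. The default is
#' the representative urban day: 8 h sleep, 14 h light work, 2 h moderate
#' work. Hours must be non-negative and sum to 24 exactly.
#'
#' @param sleep,light,moderate Hours per day in each activity class.
#' @return Object of class `evap_schedule`.
#' @export
daily_schedule <- function(sleep = 8, light = 14, moderate = 2) {
  h <- c(sleep = sleep, light = light, moderate = moderate)
  if (any(!is.finite(h)) || any(h < 0)) stop("hours must be non-negative")
  if (abs(sum(h) - 24) > 1e-9) {
    stop("schedule hours must sum to 24, got ", sum(h))
  }
  structure(as.list(h), class = "evap_schedule")
}

#' Seasonal model configuration
#'
#' Bundles the clothing ensemble, indoor-temperature rule and indoor relative
#' humidity that apply throughout one season.
#'
#' @param season Season label (spring/summer/autumn/winter).
#' @param clothing A [clothing_ensemble()] object.
#' @param rh Indoor relative humidity, fraction in \[0, 1\].
#' @param indoor_mode How indoor temperature follows the outdoor daily mean:
#'   `"fixed"` (always `setpoint`, e.g. central heating), `"follow"`
#'   (indoor = outdoor mean), or `"clipped"` (outdoor mean bounded to
#'   `clip`).
#' @param setpoint Fixed indoor temperature, degC (required for
#'   `indoor_mode = "fixed"`).
#' @param clip Length-2 numeric bounds for `"clipped"` mode, degC.
#' @return Object of class `evap_season`.
#' @export
season_config <- function(season, clothing, rh,
                          indoor_mode = c("clipped", "fixed", "follow"),
                          setpoint = NULL, clip = c(16, 30)) {
  season <- match.arg(season, c("spring", "summer", "autumn", "winter"))
  indoor_mode <- match.arg(indoor_mode)
  stopifnot(inherits(clothing, "pw_clothing"))
  if (rh < 0 || rh > 1) stop("seasonal relative humidity must lie in [0, 1]")
  if (indoor_mode == "fixed") {
    if (is.null(setpoint) || !is.finite(setpoint)) {
      stop("fixed indoor mode requires a setpoint temperature")
    }
  }
  if (indoor_mode == "clipped") {
    if (length(clip) != 2L || clip[1] > clip[2]) {
      stop("clip must be an increasing length-2 interval")
    }
  }
  structure(list(season = season, clothing = clothing, rh = rh,
                 indoor_mode = indoor_mode, setpoint = setpoint, clip = clip),
            class = "evap_season")
}

#' Default seasonal configurations
#'
#' Winter uses a fixed 22 degC setpoint (district heating keeps indoor
#' temperatures high regardless of the outdoor cold) with dry air
#' (rh 0.30); the other seasons follow the outdoor daily mean clipped to
#' \[16, 30\] degC, with rh 0.40 (spring), 0.60 (summer) and 0.50 (autumn).
#'
#' @param clothing Named list of seasonal ensembles
#'   (default [default_clothing()]).
#' @return Named list of [season_config()] objects.
#' @export
default_season_configs <- function(clothing = default_clothing()) {
  list(
    spring = season_config("spring", clothing$spring, rh = 0.40, indoor_mode = "clipped"),
    summer = season_config("summer", clothing$summer, rh = 0.60, indoor_mode = "clipped"),
    autumn = season_config("autumn", clothing$autumn, rh = 0.50, indoor_mode = "clipped"),
    winter = season_config("winter", clothing$winter, rh = 0.30, indoor_mode = "fixed",
                           setpoint = 22)
  )
}

#' Meteorological season calendar for a year
#'
#' Seasons are the meteorological ones: spring Mar-May, summer Jun-Aug,
#' autumn Sep-Nov, winter Jan-Feb plus December of the same calendar year,
#' so the four day counts always sum to 365 or 366.
#'
#' @param year Calendar year.
#' @return Named list (spring, summer, autumn, winter) of `Date` vectors.
#' @examples
#' lengths(season_days(2020)) # 92 92 91 91
#' @export
season_days <- function(year) {
  d1 <- function(m, d) as.Date(sprintf("%d-%02d-%02d", year, m, d))
  seq_d <- function(from, to) seq(from, to, by = "day")
  list(
    spring = seq_d(d1(3, 1), d1(5, 31)),
    summer = seq_d(d1(6, 1), d1(8, 31)),
    autumn = seq_d(d1(9, 1), d1(11, 30)),
    winter = c(seq_d(d1(1, 1), d1(3, 1) - 1), seq_d(d1(12, 1), d1(12, 31)))
  )
}

#' Indoor temperature from the outdoor daily mean
#'
#' @param outdoor_mean Outdoor daily mean temperature, degC (vectorised).
#' @param cfg A [season_config()] object.
#' @return Indoor air temperature, degC, per the season's indoor rule.
#' @export
indoor_temperature <- function(outdoor_mean, cfg) {
  stopifnot(inherits(cfg, "evap_season"))
  switch(cfg$indoor_mode,
    fixed   = rep(cfg$setpoint, length(outdoor_mean)),
    follow  = outdoor_mean,
    clipped = pmin(pmax(outdoor_mean, cfg$clip[1]), cfg$clip[2]),
    stop("unknown indoor mode: ", cfg$indoor_mode)
  )
}

# per-activity whole-day gram totals for one indoor state; internal
activity_day_grams <- function(ta_indoor, schedule, cfg, person,
                               activities, constants) {
  env <- environment_state(ta_indoor, cfg$rh, tr = ta_indoor,
                           constants = constants)
  rates <- vapply(
    activities[c("sleep", "light_work", "moderate_work")],
    function(a) heat_balance(env, a, cfg$clothing, person, constants)$msw,
    numeric(1)
  )
  hours <- c(schedule$sleep, schedule$light, schedule$moderate)
  person_evaporation_mass(rates, person$AD, hours)
}

#' Per-person evaporation over one day
#'
#' Sums whole-body evaporated mass over the three activity blocks of the
#' daily schedule, all at the day's indoor state (indoor temperature derived
#' from the outdoor daily mean via the season's indoor rule, seasonal
#' humidity and clothing).
#'
#' @param schedule A [daily_schedule()] object.
#' @param outdoor_mean Outdoor daily mean temperature, degC.
#' @param cfg A [season_config()] object.
#' @param person A [person_profile()] object.
#' @param activities Named list of activity levels
#'   (default [default_activities()]).
#' @param constants A [model_constants()] object.
#' @return Evaporated water, litres per person per day (1 g water = 1 mL).
#' @export
daily_person_evaporation <- function(schedule, outdoor_mean, cfg,
                                     person = person_profile(),
                                     activities = default_activities(),
                                     constants = model_constants()) {
  stopifnot(inherits(schedule, "evap_schedule"), length(outdoor_mean) == 1L)
  ta <- indoor_temperature(outdoor_mean, cfg)
  sum(activity_day_grams(ta, schedule, cfg, person, activities, constants)) / 1000
}

#' Per-person evaporation over one season
#'
#' @param outdoor_means Vector of outdoor daily mean temperatures, degC, one
#'   per day of the season (must be non-empty).
#' @inheritParams daily_person_evaporation
#' @return Evaporated water, litres per person per season (sum of daily
#'   values; additive over any partition of the day list).
#' @export
seasonal_person_evaporation <- function(outdoor_means, schedule, cfg,
                                        person = person_profile(),
                                        activities = default_activities(),
                                        constants = model_constants()) {
  if (length(outdoor_means) == 0L) stop("season must contain at least one day")
  sum(vapply(outdoor_means, function(t) {
    daily_person_evaporation(schedule, t, cfg, person, activities, constants)
  }, numeric(1)))
}

# litres contributed per scheduled hour of each activity over a whole year;
# the annual total is linear in the schedule hours, so this decomposition is
# exact and lets the sensitivity grid reuse one pass over the weather
annual_activity_litre_hours <- function(weather, cfgs,
                                        person = person_profile(),
                                        activities = default_activities(),
                                        constants = model_constants()) {
  acc <- c(sleep = 0, light = 0, moderate = 0)
  for (season in names(weather)) {
    cfg <- cfgs[[season]]
    for (t_out in weather[[season]]$tmean) {
      ta <- indoor_temperature(t_out, cfg)
      env <- environment_state(ta, cfg$rh, tr = ta, constants = constants)
      rates <- vapply(
        activities[c("sleep", "light_work", "moderate_work")],
        function(a) heat_balance(env, a, cfg$clothing, person, constants)$msw,
        numeric(1)
      )
      acc <- acc + rates * person$AD / 1000
    }
  }
  acc
}

#' Per-person evaporation over a full year
#'
#' @param weather Named list (spring, summer, autumn, winter) of data frames
#'   with a `tmean` column of outdoor daily means, as produced by
#'   [generate_weather()].
#' @inheritParams daily_person_evaporation
#' @return Named numeric: litres per person for each season plus `annual`
#'   (the sum of the four).
#' @export
annual_person_evaporation <- function(weather, schedule = daily_schedule(),
                                      cfgs = default_season_configs(),
                                      person = person_profile(),
                                      activities = default_activities(),
                                      constants = model_constants()) {
  stopifnot(setequal(names(weather), c("spring", "summer", "autumn", "winter")))
  seasonal <- vapply(names(weather), function(s) {
    seasonal_person_evaporation(weather[[s]]$tmean, schedule, cfgs[[s]],
                                person, activities, constants)
  }, numeric(1))
  c(seasonal, annual = sum(seasonal))
}

#' Sensitivity of the annual total to the daily schedule
#'
#' Evaluates the annual per-person total over a uniform grid of
#' (sleep, moderate) hour pairs inside the stated plausible ranges (light
#' work takes the remainder of the 24 h day) and reports the extreme
#' relative changes against the baseline schedule. The grid includes all
#' four corners and the baseline itself, so the returned range always
#' brackets zero.
#'
#' @param weather Year of weather as for [annual_person_evaporation()].
#' @param cfgs Named list of [season_config()] objects.
#' @param baseline Baseline [daily_schedule()]; must lie inside the bounds.
#' @param sleep_range Plausible sleep duration range, h (default 6-10, from
#'   national sleep-survey statistics).
#' @param moderate_range Plausible moderate-activity range, h (default
#'   0.5-2, from national fitness-survey statistics).
#' @param n_sleep,n_moderate Grid resolution per axis (defaults 9 and 7,
#'   giving 0.5 h and 0.25 h steps over the default ranges).
#' @inheritParams daily_person_evaporation
#' @return List with `min_pct`, `max_pct` (extreme percent changes of the
#'   annual total vs. baseline), `baseline_annual` (litres) and `grid`
#'   (data frame of sleep, moderate, annual litres and pct change).
#' @export
schedule_sensitivity <- function(weather, cfgs = default_season_configs(),
                                 baseline = daily_schedule(),
                                 sleep_range = c(6, 10),
                                 moderate_range = c(0.5, 2),
                                 n_sleep = 9, n_moderate = 7,
                                 person = person_profile(),
                                 activities = default_activities(),
                                 constants = model_constants()) {
  if (baseline$sleep < sleep_range[1] || baseline$sleep > sleep_range[2] ||
      baseline$moderate < moderate_range[1] ||
      baseline$moderate > moderate_range[2]) {
    stop("baseline schedule must lie inside the sensitivity bounds")
  }
  lh <- annual_activity_litre_hours(weather, cfgs, person, activities,
                                    constants)
  annual_for <- function(sleep, moderate) {
    light <- 24 - sleep - moderate
    sleep * lh[["sleep"]] + light * lh[["light"]] + moderate * lh[["moderate"]]
  }
  sleep_grid <- seq(sleep_range[1], sleep_range[2], length.out = n_sleep)
  mod_grid <- seq(moderate_range[1], moderate_range[2], length.out = n_moderate)
  grid <- expand.grid(sleep = sleep_grid, moderate = mod_grid)
  grid$annual_l <- mapply(annual_for, grid$sleep, grid$moderate)
  base <- annual_for(baseline$sleep, baseline$moderate)
  grid$pct_change <- 100 * (grid$annual_l - base) / base
  list(min_pct = min(grid$pct_change), max_pct = max(grid$pct_change),
       baseline_annual = base, grid = grid)
}
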