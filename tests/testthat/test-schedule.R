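test_that("daily schedule validates hours and their 24 h sum", {
  s <- daily_schedule()
  expect_equal(s$sleep + s$light + s$moderate, 24)
  expect_error(daily_schedule(8, 14, 3), "sum to 24")
  expect_error(daily_schedule(-1, 23, 2), "non-negative")
})

test_that("season calendar covers the year with meteorological seasons", {
  expect_equal(unname(lengths(season_days(2020))), c(92, 92, 91, 91))
  expect_equal(sum(lengths(season_days(2020))), 366)
  expect_equal(sum(lengths(season_days(2021))), 365)
  # winter holds Jan-Feb plus December of the same calendar year
  w <- season_days(2020)$winter
  expect_true(as.Date("2020-12-25") %in% w)
  expect_true(as.Date("2020-02-29") %in% w)
  expect_false(as.Date("2020-03-01") %in% w)
})

test_that("indoor temperature rules behave per mode", {
  clo <- default_clothing()
  fixed <- season_config("winter", clo$winter, 0.3, "fixed", setpoint = 22)
  expect_equal(indoor_temperature(-10, fixed), 22)
  expect_equal(indoor_temperature(15, fixed), 22)
  follow <- season_config("spring", clo$spring, 0.4, "follow")
  expect_equal(indoor_temperature(18.3, follow), 18.3)
  clipped <- season_config("summer", clo$summer, 0.6, "clipped",
                           clip = c(16, 28))
  expect_equal(indoor_temperature(31, clipped), 28)
  expect_equal(indoor_temperature(10, clipped), 16)
  expect_equal(indoor_temperature(20, clipped), 20)
  expect_error(season_config("winter", clo$winter, 0.3, "fixed"), "setpoint")
})

test_that("daily total is the hour-weighted sum of the three activity blocks", {
  cfg <- season_config("summer", default_clothing()$summer, rh = 0.5,
                       indoor_mode = "fixed", setpoint = 23)
  person <- person_profile(1.8)
  sched <- daily_schedule()
  daily <- daily_person_evaporation(sched, 27, cfg, person)
  # oracle: assemble from individual heat-balance calls
  env <- environment_state(23, 0.5)
  acts <- default_activities()
  rates <- vapply(acts, function(a) {
    heat_balance(env, a, cfg$clothing, person)$msw
  }, numeric(1))
  want <- sum(rates * c(8, 14, 2) * 1.8) / 1000
  expect_equal(daily, want)
  # block order does not matter: permuting hours across same-rate blocks
  daily_swapped <- daily_person_evaporation(daily_schedule(2, 14, 8), 27, cfg,
                                            person)
  expect_equal(daily_swapped,
               sum(rates * c(2, 14, 8) * 1.8) / 1000)
})

test_that("a constant sweat rate integrates to the exact whole-day volume", {
  # all three activity blocks at msw = 100 g/m2/h for AD 1.8 give 4.32 L/day
  expect_equal(sum(person_evaporation_mass(100, 1.8, c(8, 14, 2))) / 1000,
               4.32)
})

test_that("seasonal totals are additive over day partitions", {
  cfg <- season_config("autumn", default_clothing()$autumn, rh = 0.5,
                       indoor_mode = "clipped")
  sched <- daily_schedule()
  temps <- c(12, 15, 18, 21, 24, 17)
  whole <- seasonal_person_evaporation(temps, sched, cfg)
  halves <- seasonal_person_evaporation(temps[1:3], sched, cfg) +
    seasonal_person_evaporation(temps[4:6], sched, cfg)
  expect_equal(whole, halves)
  one <- seasonal_person_evaporation(temps[1], sched, cfg)
  expect_equal(one, daily_person_evaporation(sched, temps[1], cfg))
  const <- seasonal_person_evaporation(rep(18, 5), sched, cfg)
  expect_equal(const, 5 * daily_person_evaporation(sched, 18, cfg))
  expect_error(seasonal_person_evaporation(numeric(0), sched, cfg),
               "at least one day")
})

test_that("annual total equals the sum of the four seasonal totals", {
  w <- generate_weather(weather_spec(seed = 3), 2021)
  pp <- annual_person_evaporation(w)
  expect_equal(pp[["annual"]],
               sum(pp[c("spring", "summer", "autumn", "winter")]))
  expect_true(all(pp > 0))
})

test_that("schedule sensitivity brackets zero with extremes at the corners", {
  w <- generate_weather(weather_spec(seed = 7), 2021)
  sens <- schedule_sensitivity(w)
  expect_lte(sens$min_pct, 0)
  expect_gte(sens$max_pct, 0)
  expect_lte(sens$min_pct, sens$max_pct)
  g <- sens$grid
  # exhaustive-grid oracle: extremes sit at the predicted corners
  expect_equal(unlist(g[which.min(g$pct_change), c("sleep", "moderate")]),
               c(sleep = 10, moderate = 0.5))
  expect_equal(unlist(g[which.max(g$pct_change), c("sleep", "moderate")]),
               c(sleep = 6, moderate = 2))
  # decomposition used by the grid agrees with the direct schedule evaluation
  direct <- annual_person_evaporation(w)[["annual"]]
  expect_equal(sens$baseline_annual, direct, tolerance = 1e-12)
  # degenerate bounds collapse the range onto the baseline
  degen <- schedule_sensitivity(w, baseline = daily_schedule(),
                                sleep_range = c(8, 8),
                                moderate_range = c(2, 2),
                                n_sleep = 1, n_moderate = 1)
  expect_equal(degen$min_pct, 0)
  expect_equal(degen$max_pct, 0)
  expect_error(schedule_sensitivity(w, baseline = daily_schedule(11, 11, 2),
                                    sleep_range = c(6, 10)),
               "inside the sensitivity bounds")
})

test_that("more moderate work at fixed sleep never lowers the annual total", {
  w <- generate_weather(weather_spec(seed = 9), 2021)
  sens <- schedule_sensitivity(w)
  g <- sens$grid
  for (s in unique(g$sleep)) {
    sub <- g[g$sleep == s, ]
    sub <- sub[order(sub$moderate), ]
    expect_true(all(diff(sub$annual_l) >= 0))
  }
})
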