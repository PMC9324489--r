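test_that("skin temperature follows the linear regression exactly", {
  expect_equal(skin_temperature(0), 26.6)
  expect_equal(skin_temperature(23), 31.545)
  expect_equal(skin_temperature(34), 33.91)
})

test_that("saturation vapour pressure matches the direct-evaluation oracle", {
  for (t in c(0, 17, 23, 26.6, 30, 31.545, 35, 100)) {
    expect_equal(saturation_vapor_pressure(t), svp_kpa_oracle(t))
  }
  # unit-convention anchor: ~1 atm at the boiling point
  expect_lt(abs(saturation_vapor_pressure(100) - 101.325) / 101.325, 0.02)
  # strictly increasing
  ts <- seq(-20, 60, by = 0.5)
  expect_true(all(diff(saturation_vapor_pressure(ts)) > 0))
  # native-unit flag returns mmHg
  cst <- model_constants(vp_unit = "mmHg")
  expect_equal(saturation_vapor_pressure(100, cst),
               exp(18.6686 - 4030.183 / 335))
  expect_error(saturation_vapor_pressure(-235), "exceed")
})

test_that("skin vapour pressure is the saturation curve at skin temperature", {
  expect_equal(skin_vapor_pressure(26.6), svp_kpa_oracle(26.6))
  tsk <- skin_temperature(23)
  expect_equal(skin_vapor_pressure(tsk), saturation_vapor_pressure(tsk))
})

test_that("ambient vapour pressure scales linearly with relative humidity", {
  expect_equal(ambient_vapor_pressure(23, 0), 0)
  expect_equal(ambient_vapor_pressure(23, 1), svp_kpa_oracle(23))
  expect_equal(ambient_vapor_pressure(23, 0.5), svp_kpa_oracle(23) / 2)
  expect_error(ambient_vapor_pressure(23, 1.2), "\\[0, 1\\]")
  expect_error(environment_state(23, -0.1), "\\[0, 1\\]")
})

test_that("metabolic rate from gas exchange has the right grouping and units", {
  expect_equal(metabolic_rate_from_gas(RQ = 1, VO2 = 1.8, AD = 1.8), 21)
  expect_equal(metabolic_rate_from_gas(0.85, 5.9, 1.8),
               21 * (0.23 * 0.85 + 0.77) * 5.9 / 1.8)
  expect_equal(metabolic_rate_from_gas(0.85, 2 * 5.9, 1.8),
               2 * metabolic_rate_from_gas(0.85, 5.9, 1.8))
  expect_error(metabolic_rate_from_gas(0.85, -1, 1.8), "positive")
})

test_that("mechanical work is the efficiency share of metabolism", {
  expect_equal(mechanical_work(220, 0), 0)
  expect_equal(mechanical_work(220, 0.05), 11)
  expect_equal(mechanical_work(75, 0.10), 7.5)
  expect_error(mechanical_work(75, 0.2), "\\[0, 0.10\\]")
})

test_that("clothing surface temperature solves the conduction balance", {
  cst <- model_constants()
  clo <- default_clothing()$spring
  act <- default_activities()$light_work
  # zero-gradient fixed point
  env_eq <- environment_state(31.545, 0.5, tr = 31.545)
  tcl_eq <- clothing_surface_temperature(31.545, env_eq, act, clo, cst)
  expect_equal(tcl_eq, 31.545, tolerance = 1e-8)
  # generic state: residual below 1e-6 W/m^2 and bracketed by (ta, Tsk)
  env <- environment_state(23, 0.5)
  tsk <- skin_temperature(23)
  tcl <- clothing_surface_temperature(tsk, env, act, clo, cst)
  icl <- clo$icl_thermal * 0.155
  resid <- (tsk - tcl) / icl - clo$fcl * act$hc * (tcl - 23) -
    act$fr * cst$hr * (tcl - 23)
  expect_lt(abs(resid), 1e-6)
  expect_true(tcl > 23 && tcl < tsk)
})

test_that("surface-temperature solver agrees with the bisection oracle", {
  cst <- model_constants()
  set.seed(42)
  for (i in 1:100) {
    ta <- runif(1, -10, 35)
    tr <- ta + runif(1, -5, 5)
    tsk <- 0.215 * ta + 26.6
    fcl <- runif(1, 1, 1.5); hc <- runif(1, 2, 10)
    fr <- runif(1, 0.2, 1); icl <- runif(1, 0.02, 0.3)
    env <- environment_state(ta, 0.5, tr = tr)
    act <- activity_level("light_work", M = 75, hc = hc, fr = fr)
    clo <- clothing_ensemble("spring", fcl = fcl, icl_thermal = icl,
                             icl_perm = 0.5)
    cst_si <- model_constants(icl_unit = "si")
    got <- clothing_surface_temperature(tsk, env, act, clo, cst_si)
    want <- bisect_tcl_oracle(tsk, ta, tr, icl, fcl, hc, fr, cst$hr)
    expect_lt(abs(got - want), 1e-4)
  }
})

test_that("dry and respiratory loss components match closed-form oracles", {
  expect_equal(convective_loss(1.1, 4.0, 28, 23), 1.1 * 4.0 * 5)
  expect_equal(convective_loss(1.1, 4.0, 23, 23), 0)
  expect_equal(convective_loss(1.1, 4.0, 18, 23),
               -convective_loss(1.1, 4.0, 28, 23))
  expect_equal(radiant_loss(0.7, 4.7, 28, 23), 0.7 * 4.7 * 5)
  expect_equal(radiant_loss(0.7, 4.7, 23, 23), 0)
  expect_equal(radiant_loss(1.4, 4.7, 28, 23), 2 * radiant_loss(0.7, 4.7, 28, 23))
  expect_equal(respiratory_loss(40, 1.4, 23),
               0.0173 * 40 * (5.867 - 1.4) + 0.0014 * 40 * (34 - 23))
  expect_equal(respiratory_loss(40, 5.867, 34), 0)
  expect_equal(respiratory_loss(80, 1.4, 23), 2 * respiratory_loss(40, 1.4, 23))
  expect_equal(required_evaporation(40, 0, 0, 0, 0), 40)
  expect_equal(required_evaporation(75, 0, 30, 15, 7.26), 75 - 30 - 15 - 7.26)
})

test_that("evaporative resistance uses the quotient convention by default", {
  expect_equal(evaporative_resistance(0.36, 0.55, 16.5), 0.36 / (0.55 * 16.5))
  expect_equal(evaporative_resistance(0.36, 1, 1), 0.36)
  expect_equal(evaporative_resistance(0.36, 0.55, 33),
               evaporative_resistance(0.36, 0.55, 16.5) / 2)
  expect_equal(evaporative_resistance(0.36, 0.55, 16.5, "product"),
               0.36 * 0.55 / 16.5)
  expect_error(evaporative_resistance(0.36, 0, 16.5), "positive")
})

test_that("mass transfer coefficient and maximal capacity follow their forms", {
  expect_equal(mass_transfer_coefficient(2.7), 44.55)
  expect_equal(mass_transfer_coefficient(4.0), 66.0)
  expect_equal(mass_transfer_coefficient(8.2), 135.3)
  expect_equal(max_evaporative_capacity(3, 3, 0.02, 1.1, 66), 0)
  expect_equal(max_evaporative_capacity(4.2, 1.0, 0.02, 1.1, 66),
               3.2 / (0.02 + 1 / (1.1 * 66)))
  expect_equal(max_evaporative_capacity(7.4, 1.0, 0.02, 1.1, 66),
               2 * max_evaporative_capacity(4.2, 1.0, 0.02, 1.1, 66))
  expect_error(max_evaporative_capacity(4, 1, -0.1, 1.1, 100), "positive")
})

test_that("sweat-rate regression clamps negative predictions and flags them", {
  s0 <- sweat_rate(0, 0)
  expect_equal(s0$msw, 147)
  expect_false(s0$clamped)
  expect_equal(sweat_rate(100, 100)$msw, 147 + 1.527 * 100 - 0.87 * 100)
  neg <- sweat_rate(-200, 200)
  expect_equal(neg$msw, 0)
  expect_true(neg$clamped)
  expect_equal(neg$raw, 147 + 1.527 * (-200) - 0.87 * 200)
  # strictly increasing in Ereq, decreasing in Emax
  expect_gt(sweat_rate(10, 0)$msw, sweat_rate(9, 0)$msw)
  expect_lt(sweat_rate(0, 10)$msw, sweat_rate(0, 9)$msw)
})

test_that("whole-body mass is a product and additive over time", {
  expect_equal(person_evaporation_mass(100, 1.8, 8), 1440)
  expect_equal(person_evaporation_mass(100, 1.8, 0), 0)
  expect_equal(person_evaporation_mass(100, 1.8, 4) +
                 person_evaporation_mass(100, 1.8, 4),
               person_evaporation_mass(100, 1.8, 8))
  expect_error(person_evaporation_mass(100, 1.8, -1), ">= 0")
})

test_that("heat balance components equal independent single-expression oracles", {
  cst <- model_constants()
  env <- environment_state(23, 0.5)
  act <- default_activities()$light_work
  clo <- default_clothing()$summer
  hb <- heat_balance(env, act, clo, person_profile(1.8), cst)
  icl <- clo$icl_thermal * 0.155
  expect_equal(hb$tsk, 0.215 * 23 + 26.6)
  expect_equal(hb$psk, svp_kpa_oracle(hb$tsk))
  expect_equal(hb$pa, 0.5 * svp_kpa_oracle(23))
  expect_equal(hb$C, clo$fcl * act$hc * (hb$tcl - 23))
  expect_equal(hb$R, act$fr * 4.7 * (hb$tcl - 23))
  expect_equal(hb$Qres, 0.0173 * 75 * (5.867 - hb$pa) + 0.0014 * 75 * (34 - 23))
  expect_equal(hb$ereq, 75 - 0 - hb$C - hb$R - hb$Qres)
  expect_equal(hb$ie_cl, icl / (clo$icl_perm * 16.5))
  expect_equal(hb$he, 16.5 * act$hc)
  expect_equal(hb$emax,
               (hb$psk - hb$pa) / (hb$ie_cl + 1 / (clo$fcl * hb$he)))
  expect_equal(hb$msw, 147 + 1.527 * hb$ereq - 0.87 * hb$emax)
  expect_equal(hb$g_per_h, hb$msw * 1.8)
})

test_that("whole-body evaporation never decreases with ambient temperature", {
  for (clo in default_clothing()) {
    for (act in default_activities()) {
      rates <- vapply(seq(20, 34, by = 1), function(ta) {
        heat_balance(environment_state(ta, 0.5), act, clo)$g_per_h
      }, numeric(1))
      expect_true(all(diff(rates) >= 0))
    }
  }
})

test_that("parameter tables round-trip through their CSV readers", {
  acts <- read_activity_csv(system.file("extdata", "activity_parameters.csv",
                                        package = "bodyevap"))
  expect_equal(acts$sleep$M, 40)
  expect_equal(acts$moderate_work$hc, 8.2)
  expect_equal(lapply(acts, unclass),
               lapply(default_activities(), unclass))
  clo <- read_clothing_csv(system.file("extdata", "clothing_parameters.csv",
                                       package = "bodyevap"))
  expect_equal(lapply(clo, unclass), lapply(default_clothing(), unclass))
})
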