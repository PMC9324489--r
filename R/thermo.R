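#' Mean skin temperature from ambient air temperature
#'
#' Saltin-type linear regression of mean skin temperature on the surrounding
#' air temperature, valid for resting to moderately active people indoors.
#'
#' @param ta Air temperature, degC (vectorised).
#' @param constants A [model_constants()] object.
#' @return Mean skin temperature, degC.
#' @examples
#' skin_temperature(23) # 31.545
#' @export
skin_temperature <- function(ta, constants = model_constants()) {
  stopifnot(is.numeric(ta), all(is.finite(ta)))
  constants$tsk_slope * ta + constants$tsk_intercept
}

#' Saturation vapour pressure over water
#'
#' Antoine-form saturation pressure; the tabulated constants are native in
#' mmHg and the result is converted to kPa unless the `vp_unit` flag selects
#' the native unit. Strictly increasing in temperature; at 100 degC the kPa
#' form returns ~101.8, i.e. one atmosphere to within 2 percent.
#'
#' @param temp Temperature, degC (vectorised); must exceed -`svp_c`.
#' @param constants A [model_constants()] object.
#' @return Saturation vapour pressure in kPa (or mmHg if `vp_unit = "mmHg"`).
#' @export
saturation_vapor_pressure <- function(temp, constants = model_constants()) {
  stopifnot(is.numeric(temp), all(is.finite(temp)))
  if (any(temp <= -constants$svp_c)) {
    stop("temperature must exceed ", -constants$svp_c, " degC")
  }
  p_mmHg <- exp(constants$svp_a - constants$svp_b / (temp + constants$svp_c))
  if (constants$vp_unit == "kPa") p_mmHg * constants$mmHg_to_kPa else p_mmHg
}

#' Vapour pressure of water at the skin surface
#'
#' Saturation pressure evaluated at mean skin temperature (skin assumed
#' fully wetted at saturation).
#'
#' @param tsk Mean skin temperature, degC.
#' @inheritParams saturation_vapor_pressure
#' @return Skin-surface vapour pressure, kPa.
#' @export
skin_vapor_pressure <- function(tsk, constants = model_constants()) {
  saturation_vapor_pressure(tsk, constants)
}

#' Ambient water-vapour pressure from temperature and relative humidity
#'
#' @param ta Air temperature, degC.
#' @param rh Relative humidity, fraction in \[0, 1\].
#' @inheritParams saturation_vapor_pressure
#' @return Ambient vapour pressure, kPa.
#' @export
ambient_vapor_pressure <- function(ta, rh, constants = model_constants()) {
  if (any(!is.finite(rh)) || any(rh < 0) || any(rh > 1)) {
    stop("relative humidity must lie in [0, 1]")
  }
  rh * saturation_vapor_pressure(ta, constants)
}

#' Metabolic rate from respiratory gas exchange
#'
#' Alternative entry point for the metabolic rate when indirect calorimetry
#' data are available; the tabulated per-activity rates are used otherwise.
#'
#' @param RQ Respiratory quotient (exhaled CO2 over inhaled O2, molar),
#'   dimensionless; typical range 0.7-1.1.
#' @param VO2 Oxygen consumption at 0 degC and 101.325 kPa, mL/s.
#' @param AD Body surface area, m^2.
#' @return Metabolic rate, W/m^2: `21 * (0.23 RQ + 0.77) * VO2 / AD`.
#' @export
metabolic_rate_from_gas <- function(RQ, VO2, AD) {
  if (!is.numeric(VO2) || any(VO2 <= 0)) stop("oxygen consumption must be positive")
  if (!is.numeric(AD) || any(AD <= 0)) stop("body surface area must be positive")
  21 * (0.23 * RQ + 0.77) * VO2 / AD
}

#' Rate of accomplished mechanical work
#'
#' @param M Metabolic rate, W/m^2.
#' @param eta Mechanical efficiency, fraction in \[0, 0.10\].
#' @return External work rate, W/m^2.
#' @export
mechanical_work <- function(M, eta) {
  if (any(eta < 0) || any(eta > 0.10)) {
    stop("mechanical efficiency must lie in [0, 0.10]")
  }
  eta * M
}

#' Clothing surface temperature from the steady conduction balance
#'
#' Solves for the clothing surface temperature at which heat conducted from
#' the skin through the ensemble equals the convective plus radiative loss
#' from the clothing surface:
#' `(Tsk - tcl)/Icl = fcl hc (tcl - ta) + fr hr (tcl - tr)`.
#' The residual is driven below 1e-6 W/m^2 (the balance is monotone in
#' `tcl`, so the root is unique).
#'
#' @param tsk Mean skin temperature, degC.
#' @param env A [environment_state()] object.
#' @param act An [activity_level()] object (supplies `hc`, `fr`).
#' @param clothing A [clothing_ensemble()] object.
#' @param constants A [model_constants()] object.
#' @param tol Convergence tolerance on the residual, W/m^2.
#' @param maxiter Maximum solver iterations.
#' @return Clothing surface temperature, degC.
#' @export
clothing_surface_temperature <- function(tsk, env, act, clothing,
                                         constants = model_constants(),
                                         tol = 1e-6, maxiter = 200) {
  icl <- icl_si(clothing, constants)
  if (!is.finite(icl) || icl < 0) stop("effective clothing resistance must be >= 0")
  if (icl < 1e-9) return(tsk)  # bare-skin limit: surface is the skin
  resid <- function(tcl) {
    (tsk - tcl) / icl -
      clothing$fcl * act$hc * (tcl - env$ta) -
      act$fr * constants$hr * (tcl - env$tr)
  }
  lo <- min(tsk, env$ta, env$tr) - 1
  hi <- max(tsk, env$ta, env$tr) + 1
  if (resid(lo) == 0) return(lo)
  sol <- stats::uniroot(resid, lower = lo, upper = hi,
                        tol = .Machine$double.eps^0.75, maxiter = maxiter)
  if (abs(resid(sol$root)) >= tol) {
    stop("clothing surface temperature did not converge (residual ",
         signif(resid(sol$root), 3), " W/m^2); check configuration")
  }
  sol$root
}

#' Convective heat loss from the clothing surface
#'
#' @param fcl Clothing area factor.
#' @param hc Convective heat-transfer coefficient, W/(m^2 K).
#' @param tcl Clothing surface temperature, degC.
#' @param ta Air temperature, degC.
#' @return Convective loss `fcl hc (tcl - ta)`, W/m^2 (negative = gain).
#' @export
convective_loss <- function(fcl, hc, tcl, ta) fcl * hc * (tcl - ta)

#' Radiative heat loss to surrounding surfaces
#'
#' @param fr Effective radiation area factor.
#' @param hr Linearised radiative transfer coefficient, W/(m^2 K).
#' @param tcl Clothing surface temperature, degC.
#' @param tr Mean radiant temperature, degC.
#' @return Radiative loss `fr hr (tcl - tr)`, W/m^2 (negative = gain).
#' @export
radiant_loss <- function(fr, hr, tcl, tr) fr * hr * (tcl - tr)

#' Respiratory heat loss
#'
#' Latent plus dry heat carried away by breathing, both proportional to the
#' metabolic rate.
#'
#' @param M Metabolic rate, W/m^2.
#' @param pa Ambient vapour pressure, kPa (>= 0).
#' @param ta Air temperature, degC.
#' @param constants A [model_constants()] object.
#' @return Respiratory loss, W/m^2:
#'   `0.0173 M (5.867 - pa) + 0.0014 M (34 - ta)`.
#' @export
respiratory_loss <- function(M, pa, ta, constants = model_constants()) {
  if (any(pa < 0)) stop("ambient vapour pressure must be >= 0")
  constants$res_latent_coef * M * (constants$res_ref_pressure - pa) +
    constants$res_dry_coef * M * (constants$res_ref_temp - ta)
}

#' Evaporation required to close the heat balance
#'
#' @param M Metabolic rate, W/m^2.
#' @param W Mechanical work rate, W/m^2.
#' @param C Convective loss, W/m^2.
#' @param R Radiative loss, W/m^2.
#' @param Qres Respiratory loss, W/m^2.
#' @return Required evaporative heat loss `M - W - C - R - Qres`, W/m^2.
#'   May be negative in cold or heavily insulated states.
#' @export
required_evaporation <- function(M, W, C, R, Qres) M - W - C - R - Qres

#' Evaporative resistance of a clothing ensemble
#'
#' Converts the thermal resistance and vapour permeability index of an
#' ensemble into its resistance to latent heat transfer. The default
#' (and standard) grouping is `Icl / (icl * LR)`; the alternative product
#' grouping `Icl * icl / LR` is selectable for sensitivity to the
#' interpretation.
#'
#' @param icl_thermal Thermal resistance of the clothing, m^2 K/W.
#' @param icl_perm Vapour permeability index, dimensionless in (0, 1].
#' @param lewis_ratio Lewis ratio, degC/kPa.
#' @param grouping `"quotient"` (default) or `"product"`.
#' @return Evaporative resistance, m^2 kPa/W.
#' @export
evaporative_resistance <- function(icl_thermal, icl_perm, lewis_ratio = 16.5,
                                   grouping = c("quotient", "product")) {
  grouping <- match.arg(grouping)
  if (any(icl_perm <= 0)) stop("vapour permeability index must be positive")
  if (any(lewis_ratio <= 0)) stop("Lewis ratio must be positive")
  if (grouping == "quotient") icl_thermal / (icl_perm * lewis_ratio)
  else icl_thermal * icl_perm / lewis_ratio
}

#' Convective mass-transfer coefficient at the garment surface
#'
#' @param hc Convective heat-transfer coefficient, W/(m^2 K).
#' @param lewis_ratio Lewis ratio, degC/kPa.
#' @return Mass-transfer (evaporative) coefficient `LR * hc`, W/(m^2 kPa).
#' @export
mass_transfer_coefficient <- function(hc, lewis_ratio = 16.5) {
  stopifnot(all(hc > 0), all(lewis_ratio > 0))
  lewis_ratio * hc
}

#' Maximal evaporative capacity of the environment
#'
#' Skin-to-air vapour-pressure gradient over the series evaporative
#' resistance of clothing and boundary layer.
#'
#' @param psk Skin-surface vapour pressure, kPa.
#' @param pa Ambient vapour pressure, kPa.
#' @param ie_cl Clothing evaporative resistance, m^2 kPa/W.
#' @param fcl Clothing area factor.
#' @param he Surface mass-transfer coefficient, W/(m^2 kPa).
#' @return Maximal evaporative heat flux
#'   `(psk - pa) / (ie_cl + 1/(fcl he))`, W/m^2.
#' @export
max_evaporative_capacity <- function(psk, pa, ie_cl, fcl, he) {
  denom <- ie_cl + 1 / (fcl * he)
  if (any(denom <= 0)) stop("total evaporative resistance must be positive")
  (psk - pa) / denom
}

#' Sweating rate from the piecewise (PW) prediction equation
#'
#' Regression of whole-body sweating rate on the required evaporation and
#' the environment's maximal evaporative capacity. A negative raw prediction
#' is clamped to zero (mass flux cannot be negative) and flagged.
#'
#' @param ereq Required evaporation, W/m^2.
#' @param emax Maximal evaporative capacity, W/m^2.
#' @param constants A [model_constants()] object.
#' @return List with `msw` (clamped rate, g m^-2 h^-1), `raw` (unclamped
#'   regression value) and `clamped` (logical).
#' @examples
#' sweat_rate(0, 0)$msw    # the regression intercept, 147
#' sweat_rate(-200, 200)   # clamped at zero
#' @export
sweat_rate <- function(ereq, emax, constants = model_constants()) {
  stopifnot(all(is.finite(ereq)), all(is.finite(emax)))
  raw <- constants$sweat_intercept + constants$ereq_coef * ereq -
    constants$emax_coef * emax
  list(msw = pmax(raw, 0), raw = raw, clamped = raw < 0)
}

#' Whole-body evaporated mass over a time interval
#'
#' @param msw Sweating rate, g m^-2 h^-1.
#' @param AD Body surface area, m^2.
#' @param hours Duration, h (>= 0).
#' @return Evaporated water mass, g. Additive over disjoint intervals.
#' @export
person_evaporation_mass <- function(msw, AD, hours) {
  if (any(hours < 0)) stop("duration must be >= 0")
  msw * AD * hours
}

#' Full steady-state heat balance and sweat prediction for one state
#'
#' Chains the whole model for a single (environment, activity, clothing,
#' person) state: skin temperature and vapour pressure, clothing surface
#' temperature, dry and respiratory losses, required evaporation, maximal
#' evaporative capacity, and the PW sweating rate.
#'
#' @param env A [environment_state()] object.
#' @param act An [activity_level()] object.
#' @param clothing A [clothing_ensemble()] object.
#' @param person A [person_profile()] object.
#' @param constants A [model_constants()] object.
#' @return Object of class `pw_heat_balance`: a list with `tsk`, `tcl`,
#'   `psk`, `pa`, `M`, `W`, `C`, `R`, `Qres`, `ereq`, `ie_cl`, `he`, `emax`,
#'   `msw` (g m^-2 h^-1), `msw_raw`, `clamped`, and `g_per_h` (whole-body
#'   evaporation rate, g/h).
#' @examples
#' hb <- heat_balance(environment_state(23, 0.5),
#'                    default_activities()$sleep,
#'                    default_clothing()$summer)
#' hb$g_per_h
#' @export
heat_balance <- function(env, act, clothing, person = person_profile(),
                         constants = model_constants()) {
  stopifnot(inherits(env, "pw_environment"), inherits(act, "pw_activity"),
            inherits(clothing, "pw_clothing"), inherits(person, "pw_person"))
  tsk <- skin_temperature(env$ta, constants)
  psk <- skin_vapor_pressure(tsk, constants)
  tcl <- clothing_surface_temperature(tsk, env, act, clothing, constants)
  C <- convective_loss(clothing$fcl, act$hc, tcl, env$ta)
  R <- radiant_loss(act$fr, constants$hr, tcl, env$tr)
  Qres <- respiratory_loss(act$M, env$pa, env$ta, constants)
  W <- mechanical_work(act$M, act$eta)
  ereq <- required_evaporation(act$M, W, C, R, Qres)
  ie_cl <- evaporative_resistance(icl_si(clothing, constants),
                                  clothing$icl_perm, constants$lewis_ratio,
                                  constants$ie_grouping)
  he <- mass_transfer_coefficient(act$hc, constants$lewis_ratio)
  emax <- max_evaporative_capacity(psk, env$pa, ie_cl, clothing$fcl, he)
  sw <- sweat_rate(ereq, emax, constants)
  structure(list(tsk = tsk, tcl = tcl, psk = psk, pa = env$pa,
                 M = act$M, W = W, C = C, R = R, Qres = Qres,
                 ereq = ereq, ie_cl = ie_cl, he = he, emax = emax,
                 msw = sw$msw, msw_raw = sw$raw, clamped = sw$clamped,
                 g_per_h = sw$msw * person$AD),
            class = "pw_heat_balance")
}

#' Whole-body sleep evaporation sweep over ambient temperature and season
#'
#' Evaluates the full model chain for the sleep activity over a grid of
#' ambient temperatures (with radiant temperature equal to air temperature)
#' and the four seasonal clothing ensembles. Used to check the modelled
#' resting ("insensible") evaporation against the physiological range
#' reported for sleeping adults.
#'
#' @param temps Ambient temperatures, degC (default 20:34).
#' @param rh Relative humidity fraction (default 0.5).
#' @param clothing Named list of [clothing_ensemble()] objects
#'   (default [default_clothing()]).
#' @param person A [person_profile()] object.
#' @param constants A [model_constants()] object.
#' @return Data frame with columns `season`, `ta` and `g_per_h` (whole-body
#'   evaporation rate during sleep, g/h).
#' @export
sleep_insensible_sweep <- function(temps = 20:34, rh = 0.5,
                                   clothing = default_clothing(),
                                   person = person_profile(),
                                   constants = model_constants()) {
  act <- default_activities()$sleep
  grid <- expand.grid(season = names(clothing), ta = temps,
                      stringsAsFactors = FALSE)
  grid$g_per_h <- mapply(function(season, ta) {
    env <- environment_state(ta, rh, tr = ta, constants = constants)
    heat_balance(env, act, clothing[[season]], person, constants)$g_per_h
  }, grid$season, grid$ta)
  rownames(grid) <- NULL
  grid
}
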