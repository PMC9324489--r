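#' Physical constants and interpretation flags of the sweat-prediction chain
#'
#' Collects every literal used by the heat-balance/sweat chain together with
#' the interpretation flags that resolve genuinely ambiguous unit conventions.
#' The object is a plain immutable list: build a new one to change anything.
#'
#' @param hr Linearised radiative heat-transfer coefficient, W/(m^2 K).
#'   4.7 is the standard value for indoor surfaces near skin temperature.
#' @param lewis_ratio Lewis ratio relating convective mass and heat transfer,
#'   degC/kPa. 16.5 for typical indoor air.
#' @param sweat_intercept,ereq_coef,emax_coef Coefficients of the piecewise
#'   (PW) sweat-prediction regression, giving the sweating rate in
#'   g m^-2 h^-1 from the required evaporation and the maximal evaporative
#'   capacity (both W/m^2).
#' @param res_latent_coef,res_dry_coef,res_ref_pressure,res_ref_temp
#'   Respiratory heat-loss coefficients: latent term coefficient (1/kPa),
#'   dry term coefficient (1/degC), reference vapour pressure (kPa) and
#'   reference air temperature (degC).
#' @param tsk_slope,tsk_intercept Saltin-type linear regression of mean skin
#'   temperature on ambient air temperature (degC).
#' @param svp_a,svp_b,svp_c Antoine-form constants for saturation vapour
#'   pressure over water; with these values the form is native in mmHg.
#' @param mmHg_to_kPa Unit conversion applied when `vp_unit = "kPa"`.
#' @param clo_to_si m^2 K/W per clo (0.155).
#' @param icl_unit How tabulated clothing thermal resistances are read:
#'   `"clo"` (default; tabulated 0.36-1.20 are plausible ensembles in clo) or
#'   `"si"` (taken as m^2 K/W as printed).
#' @param ie_grouping Grouping of the clothing evaporative-resistance
#'   relation: `"quotient"` (default, Icl/(icl * LR), the standard
#'   clothing-science convention) or `"product"` (Icl * icl / LR).
#' @param vp_unit `"kPa"` (default: Antoine output converted from mmHg) or
#'   `"mmHg"` (native, no conversion).
#'
#' @return An object of class `pw_constants`.
#' @examples
#' cst <- model_constants()
#' cst$lewis_ratio
#' @export
model_constants <- function(hr = 4.7,
                            lewis_ratio = 16.5,
                            sweat_intercept = 147,
                            ereq_coef = 1.527,
                            emax_coef = 0.87,
                            res_latent_coef = 0.0173,
                            res_dry_coef = 0.0014,
                            res_ref_pressure = 5.867,
                            res_ref_temp = 34,
                            tsk_slope = 0.215,
                            tsk_intercept = 26.6,
                            svp_a = 18.6686,
                            svp_b = 4030.183,
                            svp_c = 235,
                            mmHg_to_kPa = 0.133322,
                            clo_to_si = 0.155,
                            icl_unit = c("clo", "si"),
                            ie_grouping = c("quotient", "product"),
                            vp_unit = c("kPa", "mmHg")) {
  icl_unit <- match.arg(icl_unit)
  ie_grouping <- match.arg(ie_grouping)
  vp_unit <- match.arg(vp_unit)
  num <- list(
    hr = hr, lewis_ratio = lewis_ratio,
    sweat_intercept = sweat_intercept, ereq_coef = ereq_coef,
    emax_coef = emax_coef,
    res_latent_coef = res_latent_coef, res_dry_coef = res_dry_coef,
    res_ref_pressure = res_ref_pressure, res_ref_temp = res_ref_temp,
    tsk_slope = tsk_slope, tsk_intercept = tsk_intercept,
    svp_a = svp_a, svp_b = svp_b, svp_c = svp_c,
    mmHg_to_kPa = mmHg_to_kPa, clo_to_si = clo_to_si
  )
  bad <- vapply(num, function(x) !is.numeric(x) || length(x) != 1L ||
                  !is.finite(x) || x <= 0, logical(1))
  if (any(bad)) {
    stop("model constants must all be single positive finite numbers; bad: ",
         paste(names(num)[bad], collapse = ", "))
  }
  structure(c(num, list(icl_unit = icl_unit, ie_grouping = ie_grouping,
                        vp_unit = vp_unit)),
            class = "pw_constants")
}

#' Ambient environment around the body
#'
#' Air temperature, mean radiant temperature and relative humidity; the
#' ambient water-vapour pressure is derived as rh times the saturation
#' pressure at the air temperature.
#'
#' @param ta Air temperature around the body, degC (must lie in (-50, 60)).
#' @param rh Relative humidity as a fraction in \[0, 1\].
#' @param tr Mean radiant temperature, degC. Defaults to `ta` (indoor
#'   assumption: surrounding surfaces at air temperature).
#' @param constants A [model_constants()] object (used to derive `pa`).
#' @return Object of class `pw_environment` with fields `ta`, `tr`, `rh`,
#'   `pa` (ambient vapour pressure, kPa).
#' @examples
#' env <- environment_state(ta = 23, rh = 0.5)
#' env$pa
#' @export
environment_state <- function(ta, rh, tr = ta, constants = model_constants()) {
  stopifnot(is.numeric(ta), length(ta) == 1L, is.finite(ta),
            is.numeric(tr), length(tr) == 1L, is.finite(tr))
  if (ta <= -50 || ta >= 60) {
    stop("air temperature ", ta, " degC is outside the supported (-50, 60)")
  }
  if (!is.numeric(rh) || length(rh) != 1L || is.na(rh) || rh < 0 || rh > 1) {
    stop("relative humidity must be a fraction in [0, 1], got ", rh)
  }
  structure(list(ta = ta, tr = tr, rh = rh,
                 pa = ambient_vapor_pressure(ta, rh, constants)),
            class = "pw_environment")
}

#' Activity level (metabolic and transfer parameters)
#'
#' @param name One of `"sleep"`, `"light_work"`, `"moderate_work"`.
#' @param M Metabolic rate, W/m^2 of body surface.
#' @param hc Convective heat-transfer coefficient at the clothing surface,
#'   W/(m^2 K).
#' @param fr Effective radiation area factor, in \[0, 1\].
#' @param eta Mechanical efficiency, fraction in \[0, 0.10\]. For most
#'   everyday activities it is effectively zero, the default.
#' @return Object of class `pw_activity`.
#' @seealso [default_activities()] for the tabulated defaults.
#' @export
activity_level <- function(name, M, hc, fr, eta = 0) {
  name <- match.arg(name, c("sleep", "light_work", "moderate_work"))
  stopifnot(is.numeric(M), M > 0, is.numeric(hc), hc > 0)
  if (fr < 0 || fr > 1) stop("effective radiation area factor must be in [0, 1]")
  if (eta < 0 || eta > 0.10) stop("mechanical efficiency must be in [0, 0.10]")
  structure(list(name = name, M = M, hc = hc, fr = fr, eta = eta),
            class = "pw_activity")
}

#' Default activity parameters
#'
#' Tabulated metabolic rate, convective coefficient and radiation area factor
#' for the three activity classes used by the daily schedule.
#'
#' @param eta Mechanical efficiency applied to all three activities
#'   (default 0).
#' @return Named list of [activity_level()] objects:
#'   sleep (M = 40, hc = 2.7, fr = 0.35), light_work (75, 4.0, 0.7),
#'   moderate_work (220, 8.2, 0.73).
#' @export
default_activities <- function(eta = 0) {
  list(
    sleep         = activity_level("sleep",         M = 40,  hc = 2.7, fr = 0.35, eta = eta),
    light_work    = activity_level("light_work",    M = 75,  hc = 4.0, fr = 0.70, eta = eta),
    moderate_work = activity_level("moderate_work", M = 220, hc = 8.2, fr = 0.73, eta = eta)
  )
}

#' Seasonal clothing ensemble
#'
#' @param season One of `"spring"`, `"summer"`, `"autumn"`, `"winter"`.
#' @param fcl Clothing area factor (clothed over nude surface area), >= 1.
#' @param icl_thermal Intrinsic thermal resistance of the ensemble, in the
#'   unit selected by the `icl_unit` flag of [model_constants()] (clo by
#'   default).
#' @param icl_perm Water-vapour permeability index of the ensemble,
#'   dimensionless in (0, 1].
#' @return Object of class `pw_clothing`.
#' @seealso [default_clothing()]
#' @export
clothing_ensemble <- function(season, fcl, icl_thermal, icl_perm) {
  season <- match.arg(season, c("spring", "summer", "autumn", "winter"))
  if (!is.numeric(fcl) || fcl < 1) stop("clothing area factor must be >= 1")
  if (!is.numeric(icl_thermal) || icl_thermal <= 0) {
    stop("clothing thermal resistance must be positive")
  }
  if (!is.numeric(icl_perm) || icl_perm <= 0 || icl_perm > 1) {
    stop("vapour permeability index must lie in (0, 1]")
  }
  structure(list(season = season, fcl = fcl, icl_thermal = icl_thermal,
                 icl_perm = icl_perm),
            class = "pw_clothing")
}

#' Default seasonal clothing ensembles
#'
#' Tabulated seasonal clothing: area factor, thermal resistance (read per the
#' `icl_unit` interpretation flag, clo by default) and vapour permeability.
#'
#' @return Named list (spring, summer, autumn, winter) of
#'   [clothing_ensemble()] objects with values 1.22/0.89/0.5, 1.1/0.36/0.55,
#'   1.28/1.01/0.48 and 1.33/1.20/0.43.
#' @export
default_clothing <- function() {
  list(
    spring = clothing_ensemble("spring", fcl = 1.22, icl_thermal = 0.89, icl_perm = 0.50),
    summer = clothing_ensemble("summer", fcl = 1.10, icl_thermal = 0.36, icl_perm = 0.55),
    autumn = clothing_ensemble("autumn", fcl = 1.28, icl_thermal = 1.01, icl_perm = 0.48),
    winter = clothing_ensemble("winter", fcl = 1.33, icl_thermal = 1.20, icl_perm = 0.43)
  )
}

#' Person profile
#'
#' @param AD Nude body surface area, m^2, in (1.0, 2.6). Default 1.8
#'   (standard adult).
#' @return Object of class `pw_person`.
#' @seealso [body_surface_area()] to derive `AD` from mass and height.
#' @export
person_profile <- function(AD = 1.8) {
  if (!is.numeric(AD) || length(AD) != 1L || is.na(AD) || AD <= 1.0 || AD >= 2.6) {
    stop("body surface area must lie in (1.0, 2.6) m^2, got ", AD)
  }
  structure(list(AD = AD), class = "pw_person")
}

#' Body surface area from mass and height (DuBois formula)
#'
#' @param mass_kg Body mass, kg.
#' @param height_m Height, m.
#' @return Surface area in m^2: 0.007184 * mass^0.425 * (100 height)^0.725.
#' @examples
#' body_surface_area(70, 1.75) # about 1.84 m^2
#' @export
body_surface_area <- function(mass_kg, height_m) {
  stopifnot(mass_kg > 0, height_m > 0)
  0.007184 * mass_kg^0.425 * (height_m * 100)^0.725
}

# effective thermal resistance in m^2 K/W under the active unit flag
icl_si <- function(clothing, constants) {
  if (constants$icl_unit == "clo") clothing$icl_thermal * constants$clo_to_si
  else clothing$icl_thermal
}
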