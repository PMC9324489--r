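#' Forest plantation specification
#'
#' Parameters of the reference plantation used to express the city's
#' human-body evaporation as an equivalent forest area. Defaults describe an
#' Acer truncatum timber plantation: 15 cm diameter at breast height, 800
#' plants per hectare, 1667.6 kg of evapotranspiration per plant per year.
#'
#' @param dbh_cm Diameter at breast height, cm.
#' @param density_per_hm2 Afforestation density, plants per hectare.
#' @param et_per_plant_kg Annual evapotranspiration per plant, kg/year.
#' @return Object of class `forest_spec`.
#' @export
forest_spec <- function(dbh_cm = 15, density_per_hm2 = 800,
                        et_per_plant_kg = 1667.6) {
  vals <- c(dbh_cm, density_per_hm2, et_per_plant_kg)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all forest parameters must be positive")
  }
  structure(list(dbh_cm = dbh_cm, density_per_hm2 = density_per_hm2,
                 et_per_plant_kg = et_per_plant_kg),
            class = "forest_spec")
}

#' Annual forest evapotranspiration per unit area
#'
#' @param spec A [forest_spec()].
#' @return Evapotranspiration in m^3/km^2/year:
#'   per-plant kg/year x plants/hm^2 x 100 hm^2/km^2 / 1000 kg/m^3
#'   (water density 1000 kg/m^3). The default plantation gives 133,408.
#' @export
forest_et_per_area <- function(spec = forest_spec()) {
  stopifnot(inherits(spec, "forest_spec"))
  spec$et_per_plant_kg * spec$density_per_hm2 * 100 / 1000
}

#' Forest area with the same annual evapotranspiration
#'
#' @param total_m3 Annual evaporated volume to match, m^3/year.
#' @param per_area Forest evapotranspiration rate, m^3/km^2/year (> 0).
#' @return List with `km2` (raw quotient) and `km2_reported` (rounded to one
#'   decimal, the reporting convention).
#' @export
equivalent_forest_area <- function(total_m3, per_area = forest_et_per_area()) {
  if (any(per_area <= 0)) stop("per-area evapotranspiration must be positive")
  km2 <- total_m3 / per_area
  list(km2 = km2, km2_reported = round(km2, 1))
}

#' Land-use class grid
#'
#' Class-coded grid (WorldCover-style integer codes) with a class table.
#' Default codes: 10 tree cover, 30 grassland, 50 built-up, 80 water.
#'
#' @param codes Integer matrix of class codes.
#' @param cellsize Cell edge length, m (default 10).
#' @param classes Data frame with columns `code` and `name` covering every
#'   code present in the grid.
#' @return Object of class `landuse_grid`.
#' @export
land_use_grid <- function(codes, cellsize = 10, classes = default_landuse_classes()) {
  stopifnot(is.matrix(codes))
  if (cellsize <= 0) stop("cell size must be positive")
  present <- sort(unique(as.vector(codes)))
  if (!all(present %in% classes$code)) {
    stop("codes present in the grid but not in the class table: ",
         paste(setdiff(present, classes$code), collapse = ", "))
  }
  structure(list(codes = codes, cellsize = cellsize, classes = classes),
            class = "landuse_grid")
}

#' Default land-use class table
#'
#' @return Data frame of the WorldCover-style codes the synthetic generator
#'   emits: 10 tree cover, 30 grassland, 50 built-up, 80 water.
#' @export
default_landuse_classes <- function() {
  data.frame(code = c(10L, 30L, 50L, 80L),
             name = c("tree_cover", "grassland", "built_up", "water"),
             stringsAsFactors = FALSE)
}

#' Annual evaporation if the green space were planted as reference forest
#'
#' Green space is a configurable set of class codes (tree cover plus
#' grassland by default); every green cell is assumed planted at the
#' reference plantation's evapotranspiration rate.
#'
#' @param grid A [land_use_grid()].
#' @param per_area Plantation evapotranspiration, m^3/km^2/year.
#' @param green_codes Integer class codes counted as green space.
#' @return List with `green_km2` (green area) and `m3` (annual green-space
#'   evaporation, m^3).
#' @export
green_space_evaporation <- function(grid, per_area = forest_et_per_area(),
                                    green_codes = c(10L, 30L)) {
  stopifnot(inherits(grid, "landuse_grid"))
  if (!all(green_codes %in% grid$classes$code)) {
    stop("unknown green class code(s): ",
         paste(setdiff(green_codes, grid$classes$code), collapse = ", "))
  }
  n_green <- sum(grid$codes %in% green_codes)
  green_km2 <- n_green * grid$cellsize^2 / 1e6
  list(green_km2 = green_km2, m3 = green_km2 * per_area)
}

#' Human-body evaporation as a percentage of green-space evaporation
#'
#' @param human_m3 Annual human-body evaporation, m^3.
#' @param green_m3 Annual green-space evaporation, m^3 (> 0).
#' @return List with `percent` (raw) and `percent_reported` (two decimals).
#' @export
human_vs_green_ratio <- function(human_m3, green_m3) {
  if (any(green_m3 <= 0)) stop("green-space evaporation must be positive")
  pct <- 100 * human_m3 / green_m3
  list(percent = pct, percent_reported = round(pct, 2))
}

#' Population density at which human evaporation matches green space
#'
#' Human-body evaporation scales linearly with population, so the density at
#' which it would equal the green-space evaporation is the current density
#' scaled by the green/human volume ratio.
#'
#' @param current_density Current population density, people/km^2.
#' @param green_m3 Annual green-space evaporation, m^3.
#' @param human_m3 Annual human-body evaporation, m^3 (> 0).
#' @return List with `density` (raw people/km^2) and `density_reported`
#'   (rounded to the nearest hundred, the reporting convention).
#' @export
equivalent_population_density <- function(current_density, green_m3, human_m3) {
  if (any(human_m3 <= 0)) stop("human evaporation must be positive")
  dens <- current_density * green_m3 / human_m3
  list(density = dens, density_reported = round(dens / 100) * 100)
}

#' Human evaporation as a fraction of natural evapotranspiration
#'
#' @param human_mm Human-body evaporation intensity, mm/year.
#' @param natural_mm Natural evapotranspiration, mm/year (> 0).
#' @return List with `percent` (raw) and `percent_reported` (nearest whole
#'   percent, the reporting convention).
#' @export
natural_et_fraction <- function(human_mm, natural_mm) {
  if (any(natural_mm <= 0)) stop("natural evapotranspiration must be positive")
  pct <- 100 * human_mm / natural_mm
  list(percent = pct, percent_reported = round(pct))
}

#' Reference municipal water-use table
#'
#' Annual total water use of four European cities in 2015, used to put the
#' city-scale human evaporation volume in context.
#'
#' @return Data frame with columns `city`, `country`, `use_million_m3`:
#'   Kronoberg (Sweden) 17.42, Esbjerg (Denmark) 14.30, Aust-Agder (Norway)
#'   15.67, Tartu (Estonia) 6.75.
#' @export
water_use_table <- function() {
  data.frame(
    city = c("Kronoberg", "Esbjerg", "Aust-Agder", "Tartu"),
    country = c("Sweden", "Denmark", "Norway", "Estonia"),
    use_million_m3 = c(17.42, 14.30, 15.67, 6.75),
    stringsAsFactors = FALSE
  )
}

#' Ratio of an evaporation total to a city's annual water use
#'
#' @param total_million_m3 Annual evaporation total, million m^3.
#' @param use_million_m3 City annual water use, million m^3 (> 0).
#' @return The ratio total/use.
#' @export
water_use_multiple <- function(total_million_m3, use_million_m3) {
  if (any(use_million_m3 <= 0)) stop("water use must be positive")
  total_million_m3 / use_million_m3
}

#' Equivalence-accounting report for an annual city total
#'
#' Assembles the comparison block: equivalent forest area, fraction of
#' natural evapotranspiration, and water-use multiples, each with raw and
#' reported (rounded) values.
#'
#' @param annual_m3 Annual city human-evaporation total, m^3.
#' @param city_area_km2 Administrative area used for the mm/year conversion.
#' @param natural_et_mm Natural urban evapotranspiration, mm/year.
#' @param forest A [forest_spec()].
#' @param water_use Data frame as from [water_use_table()].
#' @return Data frame with columns `metric`, `value`, `reported`, `units`.
#' @export
comparison_report <- function(annual_m3, city_area_km2, natural_et_mm = 348,
                              forest = forest_spec(),
                              water_use = water_use_table()) {
  per_area <- forest_et_per_area(forest)
  fa <- equivalent_forest_area(annual_m3, per_area)
  ui <- unit_area_intensity(annual_m3, city_area_km2)
  nf <- natural_et_fraction(ui$mm, natural_et_mm)
  rows <- data.frame(
    metric = c("forest_et_per_area", "equivalent_forest_area",
               "intensity_mm", "natural_et_fraction_pct"),
    value = c(per_area, fa$km2, ui$mm, nf$percent),
    reported = c(per_area, fa$km2_reported, round(ui$mm, 2),
                 nf$percent_reported),
    units = c("m3/km2/yr", "km2", "mm/yr", "%"),
    stringsAsFactors = FALSE
  )
  wu <- data.frame(
    metric = paste0("water_use_multiple_", tolower(water_use$city)),
    value = water_use_multiple(annual_m3 / 1e6, water_use$use_million_m3),
    reported = round(water_use_multiple(annual_m3 / 1e6,
                                        water_use$use_million_m3), 2),
    units = "ratio",
    stringsAsFactors = FALSE
  )
  rbind(rows, wu)
}
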