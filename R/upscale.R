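#' Gridded raster container
#'
#' Minimal north-up, row-major raster: a numeric matrix whose first row is
#' the northernmost, plus the square cell size and the lower-left corner of
#' the grid. This is the in-memory twin of the ESRI ASCII grid files the
#' package reads and writes (see [read_esri_ascii()]).
#'
#' @param values Numeric matrix (row 1 = north).
#' @param cellsize Cell edge length, m (> 0).
#' @param xll,yll Coordinates of the lower-left corner, m.
#' @param nodata Value that marks missing cells in files.
#' @return Object of class `evap_raster`.
#' @export
evap_raster <- function(values, cellsize = 100, xll = 0, yll = 0,
                        nodata = -9999) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("raster values must be a numeric matrix")
  }
  if (!is.finite(cellsize) || cellsize <= 0) stop("cell size must be positive")
  structure(list(values = values, cellsize = cellsize, xll = xll, yll = yll,
                 nodata = nodata),
            class = "evap_raster")
}

#' Population raster (persons per cell)
#'
#' Cell values are person counts in the cell, not densities. Cells flagged
#' as nodata are treated as zero population with a warning.
#'
#' @inheritParams evap_raster
#' @return Object of classes `pop_raster`, `evap_raster`.
#' @export
population_raster <- function(values, cellsize = 100, xll = 0, yll = 0,
                              nodata = -9999) {
  nd <- which(values == nodata | is.na(values))
  if (length(nd) > 0) {
    warning(length(nd), " nodata population cells treated as zero population")
    values[nd] <- 0
  }
  if (any(values < 0)) stop("populated cells must be >= 0")
  r <- evap_raster(values, cellsize, xll, yll, nodata)
  class(r) <- c("pop_raster", class(r))
  r
}

#' District label map aligned to a population raster
#'
#' @param labels Integer matrix of district labels, same dimensions as the
#'   population raster it accompanies.
#' @param info Data frame with columns `label`, `name` and `area_km2`
#'   (> 0), one row per district.
#' @param cellsize,xll,yll As in [evap_raster()].
#' @return Object of class `district_map`.
#' @export
district_map <- function(labels, info, cellsize = 100, xll = 0, yll = 0) {
  stopifnot(is.matrix(labels))
  req <- c("label", "name", "area_km2")
  if (!all(req %in% names(info))) {
    stop("district info needs columns: ", paste(req, collapse = ", "))
  }
  if (any(info$area_km2 <= 0)) stop("district areas must be positive")
  present <- sort(unique(as.vector(labels)))
  if (!all(present %in% info$label)) {
    stop("labels present in the grid but missing from the info table: ",
         paste(setdiff(present, info$label), collapse = ", "))
  }
  structure(list(labels = labels, info = info, cellsize = cellsize,
                 xll = xll, yll = yll),
            class = "district_map")
}

check_aligned <- function(pop, districts) {
  if (!identical(dim(pop$values), dim(districts$labels)) ||
      !isTRUE(all.equal(pop$cellsize, districts$cellsize))) {
    stop("population raster and district map are not aligned ",
         "(dimensions or cell size differ)")
  }
}

#' District and city evaporation totals from per-person seasonal rates
#'
#' The model treats the per-person rate as spatially uniform (one
#' representative person), so spatial structure enters only through the
#' population raster: each district's seasonal volume is its population
#' times the per-person litres, converted to cubic metres.
#'
#' @param per_person Named numeric vector of litres/person/season, one entry
#'   per season (names are the season labels).
#' @param districts A [district_map()].
#' @param pop A [population_raster()] aligned with `districts`.
#' @return Object of class `city_result`: a data frame with columns
#'   `district`, `season`, `population`, `volume_m3`, plus attributes
#'   `seasons` and `district_info`.
#' @export
district_totals <- function(per_person, districts, pop) {
  stopifnot(inherits(districts, "district_map"), inherits(pop, "pop_raster"))
  check_aligned(pop, districts)
  if (is.null(names(per_person)) || any(!nzchar(names(per_person)))) {
    stop("per-person rates must be named by season")
  }
  dist_pop <- tapply(as.vector(pop$values), as.vector(districts$labels), sum)
  info <- districts$info[match(as.integer(names(dist_pop)), districts$info$label), ]
  out <- do.call(rbind, lapply(names(per_person), function(season) {
    data.frame(district = info$name, season = season,
               population = as.numeric(dist_pop),
               volume_m3 = as.numeric(dist_pop) * per_person[[season]] / 1000,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  structure(out, seasons = names(per_person), district_info = districts$info,
            class = c("city_result", "data.frame"))
}

#' Per-cell evaporation intensity raster (mm/year)
#'
#' Converts the per-cell annual volume (cell persons times the per-person
#' annual litres) to a water depth over the cell area: 1 mm is 10^-3 m^3
#' per m^2. Cells with zero population map exactly to zero intensity.
#'
#' @param pop A [population_raster()].
#' @param per_person_annual Litres per person per year.
#' @return An `evap_raster` of intensities in mm/year.
#' @export
intensity_raster <- function(pop, per_person_annual) {
  stopifnot(inherits(pop, "pop_raster"))
  if (pop$cellsize <= 0) stop("cell size must be positive")
  vol_m3 <- pop$values * per_person_annual / 1000
  mm <- vol_m3 / (pop$cellsize^2) * 1000
  evap_raster(mm, pop$cellsize, pop$xll, pop$yll, pop$nodata)
}

#' Evaporation intensity per unit area
#'
#' @param volume_m3 Total evaporated volume, m^3.
#' @param area_km2 Reference land area, km^2 (> 0). The area is always an
#'   explicit input: for a city average it is the administrative area of the
#'   region being summarised.
#' @return List with `m3_per_km2` and `mm` (`m3_per_km2 / 1000`; 1 mm over
#'   1 km^2 is 1000 m^3).
#' @export
unit_area_intensity <- function(volume_m3, area_km2) {
  if (any(area_km2 <= 0)) stop("area must be positive")
  m3_per_km2 <- volume_m3 / area_km2
  list(m3_per_km2 = m3_per_km2, mm = m3_per_km2 / 1000)
}

#' Annual city total from a seasonal city result
#'
#' @param result A `city_result` from [district_totals()]; all four seasons
#'   must be present.
#' @param seasons Season labels that must be present (default the four
#'   seasons).
#' @return Annual city total, m^3 (sum over districts and seasons).
#' @export
annual_city_total <- function(result,
                              seasons = c("spring", "summer", "autumn",
                                          "winter")) {
  stopifnot(inherits(result, "city_result"))
  missing <- setdiff(seasons, unique(result$season))
  if (length(missing) > 0) {
    stop("missing seasons: ", paste(missing, collapse = ", "))
  }
  sum(result$volume_m3[result$season %in% seasons])
}

#' @export
print.city_result <- function(x, ...) {
  cat("City evaporation result:", length(unique(x$district)), "districts x",
      length(unique(x$season)), "seasons\n")
  cat("Total population:",
      format(sum(x$population[x$season == x$season[1]]), big.mark = ","), "\n")
  cat("Total volume:", format(round(sum(x$volume_m3)), big.mark = ","), "m^3\n")
  invisible(x)
}
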