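# run code under a fixed seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# integer allocation of `total` over non-negative weights; exact by
# construction (largest-remainder rule, ties broken by cell index)
largest_remainder <- function(weights, total) {
  stopifnot(all(weights >= 0), sum(weights) > 0, total >= 0)
  quota <- total * weights / sum(weights)
  base <- floor(quota)
  rem <- as.integer(round(total - sum(base)))
  if (rem > 0) {
    frac <- quota - base
    take <- order(-frac, seq_along(frac))[seq_len(rem)]
    base[take] <- base[take] + 1
  }
  base
}

#' Synthetic city specification
#'
#' Parameters of the seeded synthetic-city generator. Defaults emulate a
#' megacity of the scale studied: 16 districts, 21.89 million people on a
#' 128 x 128 km extent (about 16,400 km^2), with a core-peaked density
#' profile and a green-space fraction typical of a built-up region.
#'
#' @param n_districts Number of districts.
#' @param population Total population (allocated to cells exactly).
#' @param nrow,ncol Population grid dimensions.
#' @param cellsize Population cell edge length, m.
#' @param density_scale Decay length of the core-peaked density profile,
#'   as a fraction of the grid half-diagonal.
#' @param density_noise Log-scale standard deviation of multiplicative
#'   cell-level density noise.
#' @param green_fraction Fraction of land-use cells assigned a green class.
#' @param landuse_cellsize Land-use cell edge length, m; defaults to one
#'   tenth of the population cell size (finer land-cover grid).
#' @param seed Integer seed fixing all randomness of the generator.
#' @return Object of class `city_spec`.
#' @export
city_spec <- function(n_districts = 16, population = 21890000,
                      nrow = 128, ncol = 128, cellsize = 1000,
                      density_scale = 0.35, density_noise = 0.3,
                      green_fraction = 0.25, landuse_cellsize = NULL,
                      seed = 1L) {
  if (population <= 0) stop("population must be positive")
  if (green_fraction < 0 || green_fraction > 1) {
    stop("green fraction must lie in [0, 1]")
  }
  if (nrow * ncol < n_districts) {
    stop("grid too small for the requested number of districts")
  }
  if (is.null(landuse_cellsize)) landuse_cellsize <- cellsize / 10
  structure(list(n_districts = n_districts, population = population,
                 nrow = nrow, ncol = ncol, cellsize = cellsize,
                 density_scale = density_scale, density_noise = density_noise,
                 green_fraction = green_fraction,
                 landuse_cellsize = landuse_cellsize,
                 seed = as.integer(seed)),
            class = "city_spec")
}

#' Generate a synthetic city
#'
#' Produces a population raster with a core-peaked density gradient (person
#' counts allocated by the largest-remainder rule so cells sum to the total
#' exactly), a district partition (Voronoi cells around seeded points, ties
#' broken by cell index), and a finer land-use class grid whose green-cell
#' count matches the requested green fraction exactly. All randomness flows
#' from the spec's seed; the same spec reproduces identical outputs.
#'
#' @param spec A [city_spec()].
#' @return List with elements `pop` ([population_raster()]), `districts`
#'   ([district_map()]), `landuse` ([land_use_grid()]) and `seed`.
#' @examples
#' city <- generate_city(city_spec(n_districts = 4, population = 10000,
#'                                 nrow = 16, ncol = 16, seed = 7))
#' sum(city$pop$values) # exactly 10000
#' @export
generate_city <- function(spec) {
  stopifnot(inherits(spec, "city_spec"))
  with_local_seed(spec$seed, {
    nr <- spec$nrow; nc <- spec$ncol
    rows <- matrix(seq_len(nr), nr, nc)
    cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
    d <- sqrt((rows - cr)^2 + (cols - cc)^2)
    scale <- spec$density_scale * sqrt(cr^2 + cc^2)
    w <- exp(-d / scale) * exp(stats::rnorm(nr * nc, 0, spec$density_noise))
    people <- matrix(largest_remainder(as.vector(w), spec$population), nr, nc)
    pop <- population_raster(people, cellsize = spec$cellsize)

    # district partition: Voronoi around seeded cells
    seeds <- sample.int(nr * nc, spec$n_districts)
    sr <- (seeds - 1) %% nr + 1
    sc <- (seeds - 1) %/% nr + 1
    dist2 <- sapply(seq_len(spec$n_districts), function(k) {
      as.vector((rows - sr[k])^2 + (cols - sc[k])^2)
    })
    labels <- matrix(max.col(-dist2, ties.method = "first"), nr, nc)
    counts <- tabulate(labels, nbins = spec$n_districts)
    info <- data.frame(
      label = seq_len(spec$n_districts),
      name = sprintf("D%02d", seq_len(spec$n_districts)),
      area_km2 = counts * spec$cellsize^2 / 1e6,
      stringsAsFactors = FALSE
    )
    districts <- district_map(labels, info, cellsize = spec$cellsize)

    # land-use grid over the same extent, finer cells
    lu_nr <- max(1L, as.integer(round(nr * spec$cellsize / spec$landuse_cellsize)))
    lu_nc <- max(1L, as.integer(round(nc * spec$cellsize / spec$landuse_cellsize)))
    n_lu <- lu_nr * lu_nc
    codes <- matrix(50L, lu_nr, lu_nc)
    n_green <- as.integer(round(spec$green_fraction * n_lu))
    if (n_green > 0) {
      green_cells <- sample.int(n_lu, n_green)
      split <- largest_remainder(c(0.6, 0.4), n_green)  # trees vs grassland
      codes[green_cells] <- rep(c(10L, 30L), times = split)
    }
    landuse <- land_use_grid(codes, cellsize = spec$landuse_cellsize)

    list(pop = pop, districts = districts, landuse = landuse,
         seed = spec$seed)
  })
}

#' Synthetic weather specification
#'
#' Seasonal temperature statistics for the synthetic daily weather
#' generator. Defaults emulate a northern temperate monsoon climate (annual
#' mean near 12 degC, hot humid summers, cold dry winters).
#'
#' @param means Named per-season mean outdoor daily temperature, degC.
#' @param amplitudes Named per-season within-season sinusoid amplitude,
#'   degC.
#' @param noise_sd Day-to-day noise standard deviation, degC (>= 0).
#' @param seed Integer seed fixing all randomness.
#' @return Object of class `weather_spec`.
#' @export
weather_spec <- function(means = c(spring = 13.5, summer = 26.0,
                                   autumn = 13.0, winter = -1.5),
                         amplitudes = c(spring = 7, summer = 2,
                                        autumn = 8, winter = 3),
                         noise_sd = 2, seed = 1L) {
  seasons <- c("spring", "summer", "autumn", "winter")
  if (!all(seasons %in% names(means)) || !all(seasons %in% names(amplitudes))) {
    stop("means and amplitudes must be named for all four seasons")
  }
  if (noise_sd < 0) stop("noise standard deviation must be >= 0")
  structure(list(means = means[seasons], amplitudes = amplitudes[seasons],
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "weather_spec")
}

#' Generate synthetic seasonal daily weather
#'
#' For each meteorological season the daily mean temperature is the season
#' mean plus a full-period sinusoid (which averages to zero over the season,
#' so with zero noise the seasonal sample mean equals the specified mean
#' exactly) plus Gaussian day-to-day noise. Deterministic under a fixed
#' seed; day counts follow the season calendar of the requested year.
#'
#' @param spec A [weather_spec()].
#' @param year Calendar year (determines day counts, including leap years).
#' @return Named list (spring, summer, autumn, winter) of data frames with
#'   columns `date` and `tmean` (degC).
#' @export
generate_weather <- function(spec, year = 2020) {
  stopifnot(inherits(spec, "weather_spec"))
  cal <- season_days(year)
  with_local_seed(spec$seed, {
    out <- lapply(names(cal), function(season) {
      dates <- cal[[season]]
      n <- length(dates)
      i <- seq_len(n)
      tmean <- spec$means[[season]] +
        spec$amplitudes[[season]] * sin(2 * pi * (i - 0.5) / n) +
        stats::rnorm(n, 0, spec$noise_sd)
      data.frame(date = dates, tmean = tmean)
    })
    names(out) <- names(cal)
    out
  })
}
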