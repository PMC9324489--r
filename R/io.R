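#' Write a raster to an ESRI ASCII grid file
#'
#' Plain-text raster interchange format: a six-line header (ncols, nrows,
#' xllcorner, yllcorner, cellsize, NODATA_value) followed by rows of cell
#' values, northernmost row first — matching the in-memory convention of
#' [evap_raster()].
#'
#' @param raster An [evap_raster()] (or subclass).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_esri_ascii <- function(raster, path) {
  stopifnot(inherits(raster, "evap_raster"))
  v <- raster$values
  v[is.na(v)] <- raster$nodata
  header <- c(
    paste("ncols", ncol(v)),
    paste("nrows", nrow(v)),
    paste("xllcorner", format(raster$xll, scientific = FALSE)),
    paste("yllcorner", format(raster$yll, scientific = FALSE)),
    paste("cellsize", format(raster$cellsize, scientific = FALSE)),
    paste("NODATA_value", format(raster$nodata, scientific = FALSE))
  )
  body <- apply(v, 1, function(row) {
    paste(format(row, trim = TRUE, scientific = FALSE, digits = 15),
          collapse = " ")
  })
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid file
#'
#' @param path File path.
#' @return An [evap_raster()]; nodata cells are returned as `NA`.
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 7) stop("not an ESRI ASCII grid: ", path)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% names(hdr))) {
    stop("missing ESRI ASCII header fields in ", path)
  }
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    stop("cell count does not match header in ", path)
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA
  evap_raster(m, cellsize = hdr$cellsize, xll = hdr$xllcorner,
              yll = hdr$yllcorner, nodata = hdr$nodata_value)
}

#' Read activity parameters from CSV
#'
#' Expected columns: `name` (sleep/light_work/moderate_work), `M`, `hc`,
#' `fr`, and optionally `eta`.
#'
#' @param path CSV file path.
#' @return Named list of [activity_level()] objects.
#' @export
read_activity_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "M", "hc", "fr")
  if (!all(need %in% names(df))) {
    stop("activity table needs columns: ", paste(need, collapse = ", "))
  }
  if (!"eta" %in% names(df)) df$eta <- 0
  out <- lapply(seq_len(nrow(df)), function(i) {
    activity_level(df$name[i], df$M[i], df$hc[i], df$fr[i], df$eta[i])
  })
  names(out) <- df$name
  out
}

#' Read clothing parameters from CSV
#'
#' Expected columns: `season`, `fcl`, `icl_thermal`, `icl_perm`.
#'
#' @param path CSV file path.
#' @return Named list of [clothing_ensemble()] objects.
#' @export
read_clothing_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("season", "fcl", "icl_thermal", "icl_perm")
  if (!all(need %in% names(df))) {
    stop("clothing table needs columns: ", paste(need, collapse = ", "))
  }
  out <- lapply(seq_len(nrow(df)), function(i) {
    clothing_ensemble(df$season[i], df$fcl[i], df$icl_thermal[i],
                      df$icl_perm[i])
  })
  names(out) <- df$season
  out
}

#' Read a daily weather series from CSV
#'
#' Expected columns: `date` (ISO), `tmean` (degC).
#'
#' @param path CSV file path.
#' @return Data frame with `date` (Date) and `tmean`.
#' @export
read_weather_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("date", "tmean") %in% names(df))) {
    stop("weather table needs columns: date, tmean")
  }
  df$date <- as.Date(df$date)
  if (anyNA(df$date)) stop("unparseable dates in ", path)
  if (anyDuplicated(df$date)) stop("duplicate dates in ", path)
  df[order(df$date), , drop = FALSE]
}
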