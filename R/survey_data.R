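# Data model, file I/O, region assignment and catch standardization for
# tow-level groundfish survey data.

TOW_COLUMNS <- c(
  "tow_id", "station_id", "year", "doy", "lat", "lon",
  "depth_m", "bottom_temp_c", "tow_length_nmi"
)
CATCH_COLUMNS <- c("tow_id", "species_id", "count")

# Region divider constants (degrees). Longitudes are stored signed, west
# negative, so arithmetic near the east/west divider is unambiguous.
REGION_LON_DIVIDER <- -20
REGION_LAT_DIVIDER_WEST <- 65.5
REGION_LAT_DIVIDER_EAST <- 64.5

#' Read a tow table
#'
#' Reads a delimited text file of standardized survey tows, one row per tow,
#' with header columns `tow_id, station_id, year, doy, lat, lon, depth_m,
#' bottom_temp_c, tow_length_nmi`. An empty `bottom_temp_c` cell marks a tow
#' without a temperature measurement; such tows are retained (they still
#' carry location and effort information) and a warning reports how many
#' there are. Malformed numeric cells and non-positive depths or tow lengths
#' are fatal, reported with their file line numbers.
#'
#' @param path path to the delimited file.
#' @param sep field separator (default comma).
#' @return a tibble of tows; `bottom_temp_c` is `NA` where missing.
#' @seealso [write_tows()], [read_catches()]
#' @export
read_tows <- function(path, sep = ",") {
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  colClasses = "character", check.names = TRUE,
                  na.strings = c("", "NA"))
  assert_cols(raw, TOW_COLUMNS, what = sprintf("tow file '%s'", path))
  n <- nrow(raw)
  lines <- seq_len(n) + 1L # header occupies line 1

  num <- function(col, allow_na = FALSE) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- is.na(v) & !is.na(raw[[col]])
    if (any(bad)) {
      stop(sprintf(
        "non-numeric value in column '%s' at line(s) %s of '%s'",
        col, paste(head(lines[bad], 5L), collapse = ", "), path
      ), call. = FALSE)
    }
    if (!allow_na && anyNA(v)) {
      stop(sprintf(
        "missing value in required column '%s' at line(s) %s of '%s'",
        col, paste(head(lines[is.na(v)], 5L), collapse = ", "), path
      ), call. = FALSE)
    }
    v
  }

  tows <- tibble::tibble(
    tow_id = raw$tow_id,
    station_id = raw$station_id,
    year = as.integer(num("year")),
    doy = as.integer(num("doy")),
    lat = num("lat"),
    lon = num("lon"),
    depth_m = num("depth_m"),
    bottom_temp_c = num("bottom_temp_c", allow_na = TRUE),
    tow_length_nmi = num("tow_length_nmi")
  )

  if (any(tows$depth_m <= 0)) {
    stop(sprintf(
      "non-positive tow depth at line(s) %s of '%s'",
      paste(head(lines[tows$depth_m <= 0], 5L), collapse = ", "), path
    ), call. = FALSE)
  }
  if (any(tows$tow_length_nmi <= 0)) {
    stop(sprintf(
      "non-positive tow length at line(s) %s of '%s'",
      paste(head(lines[tows$tow_length_nmi <= 0], 5L), collapse = ", "), path
    ), call. = FALSE)
  }
  n_miss <- sum(is.na(tows$bottom_temp_c))
  if (n_miss > 0L) {
    warning(sprintf(
      "%d of %d tows (%.1f%%) lack a bottom temperature; retained with NA",
      n_miss, n, 100 * n_miss / n
    ), call. = FALSE)
  }
  out_of_range <- !is.na(tows$bottom_temp_c) &
    (tows$bottom_temp_c < -2.5 | tows$bottom_temp_c > 12)
  if (any(out_of_range)) {
    warning(sprintf(
      "%d bottom temperatures outside the plausible range [-2.5, 12] degC",
      sum(out_of_range)
    ), call. = FALSE)
  }
  tows
}

#' Write a tow table
#'
#' Inverse of [read_tows()]; missing temperatures are written as empty cells
#' so that a read/write round trip reproduces all fields.
#'
#' @param tows a tow tibble as returned by [read_tows()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tows <- function(tows, path) {
  assert_cols(tows, TOW_COLUMNS)
  write.csv(tows[TOW_COLUMNS], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a catch table
#'
#' One row per (tow, species) with a non-negative integer count. Duplicate
#' (tow, species) pairs and negative counts are fatal.
#'
#' @param path path to the delimited file with header
#'   `tow_id, species_id, count`.
#' @param sep field separator.
#' @return a tibble of catch records.
#' @export
read_catches <- function(path, sep = ",") {
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  colClasses = c("character", "character", "numeric"),
                  na.strings = c("", "NA"))
  assert_cols(raw, CATCH_COLUMNS, what = sprintf("catch file '%s'", path))
  if (anyNA(raw$count) || any(raw$count < 0) || any(raw$count %% 1 != 0)) {
    bad <- which(is.na(raw$count) | raw$count < 0 | raw$count %% 1 != 0)
    stop(sprintf(
      "invalid count at line(s) %s of '%s' (must be a non-negative integer)",
      paste(head(bad + 1L, 5L), collapse = ", "), path
    ), call. = FALSE)
  }
  key <- paste(raw$tow_id, raw$species_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop(sprintf("duplicate (tow_id, species_id) pair(s) in '%s'", path),
         call. = FALSE)
  }
  tibble::tibble(
    tow_id = raw$tow_id,
    species_id = raw$species_id,
    count = as.integer(raw$count)
  )
}

#' @rdname read_catches
#' @param catches a catch tibble.
#' @export
write_catches <- function(catches, path) {
  assert_cols(catches, CATCH_COLUMNS)
  write.csv(catches[CATCH_COLUMNS], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Assign survey regions from coordinates
#'
#' Partitions coordinates into four regions (`NW`, `NE`, `SW`, `SE`) using a
#' meridian divider at 20 degrees W and latitudinal dividers at 65.5 degrees N
#' west of it and 64.5 degrees N east of it. Boundary convention: a point
#' exactly on the meridian divider is assigned east; a point exactly on a
#' latitudinal divider is assigned south. Every finite coordinate maps to
#' exactly one region.
#'
#' @param lat latitude, decimal degrees north.
#' @param lon longitude, decimal degrees, signed (west negative).
#' @return character vector of region codes.
#' @examples
#' assign_region(66.0, -23.0) # "NW"
#' assign_region(65.0, -15.0) # "NE"
#' @export
assign_region <- function(lat, lon) {
  if (length(lat) != length(lon)) {
    stop("lat and lon must have the same length")
  }
  if (any(!is.finite(lat)) || any(!is.finite(lon))) {
    stop("non-finite coordinate passed to assign_region()")
  }
  west <- lon < REGION_LON_DIVIDER
  north <- ifelse(west, lat > REGION_LAT_DIVIDER_WEST,
                  lat > REGION_LAT_DIVIDER_EAST)
  paste0(ifelse(north, "N", "S"), ifelse(west, "W", "E"))
}

REGIONS <- c("NW", "NE", "SW", "SE")

#' Standardize a catch count to fish per nautical mile
#'
#' Survey catches are standardized to the number of fish caught per nautical
#' mile towed (1 nmi = 1.852 km), the catch-per-unit-effort used by every
#' downstream index and model.
#'
#' @param count non-negative catch count(s).
#' @param tow_length_nmi tow length(s) in nautical miles, strictly positive.
#' @return fish per nautical mile.
#' @examples
#' standardize_catch(57, 2.85) # 20
#' @export
standardize_catch <- function(count, tow_length_nmi) {
  if (any(!is.finite(tow_length_nmi)) || any(tow_length_nmi <= 0)) {
    stop("tow_length_nmi must be positive and finite")
  }
  if (any(count < 0, na.rm = TRUE)) {
    stop("count must be non-negative")
  }
  count / tow_length_nmi
}

#' Standardize a catch table against its tow table
#'
#' Joins catches to tows by `tow_id` and adds the per-nautical-mile
#' standardized catch (`cpue_nmi`). A catch record whose `tow_id` is absent
#' from the tow table is an error.
#'
#' @param catches catch tibble (`tow_id, species_id, count`).
#' @param tows tow tibble (see [read_tows()]).
#' @return the catch tibble with a `cpue_nmi` column.
#' @export
standardize_catches <- function(catches, tows) {
  assert_cols(catches, CATCH_COLUMNS)
  assert_cols(tows, c("tow_id", "tow_length_nmi"))
  orphan <- setdiff(catches$tow_id, tows$tow_id)
  if (length(orphan) > 0L) {
    stop(sprintf(
      "catch records reference %d tow_id(s) absent from the tow table (e.g. %s)",
      length(orphan), paste(head(orphan, 3L), collapse = ", ")
    ), call. = FALSE)
  }
  len <- tows$tow_length_nmi[match(catches$tow_id, tows$tow_id)]
  dplyr::mutate(catches, cpue_nmi = standardize_catch(count, len))
}

#' Select core species by year coverage
#'
#' Returns the species with a positive catch in at least `min_years` distinct
#' survey years, the inclusion rule for all cross-year analyses (19 of 22
#' years by default).
#'
#' @param catches catch tibble.
#' @param tows tow tibble (supplies the year of each tow).
#' @param min_years minimum number of distinct years with a positive catch.
#' @return sorted character vector of species ids.
#' @export
filter_core_species <- function(catches, tows, min_years = 19) {
  assert_cols(catches, CATCH_COLUMNS)
  assert_cols(tows, c("tow_id", "year"))
  yr <- tows$year[match(catches$tow_id, tows$tow_id)]
  if (anyNA(yr)) {
    stop("catch records reference tow_id(s) absent from the tow table")
  }
  pos <- catches$count > 0
  cover <- tapply(yr[pos], catches$species_id[pos],
                  function(y) length(unique(y)))
  sort(names(cover)[!is.na(cover) & cover >= min_years])
}
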