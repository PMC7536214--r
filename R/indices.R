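# Abundance indices, spatial coverage, and thermal affinity indices
# (thermal bias and stenothermy) with their class bins.

#' Annual abundance index
#'
#' The annual abundance of a species, `A_y`, is the within-year sum of its
#' standardized catch (fish per nautical mile) over all tows. The returned
#' grid is complete: every species x survey-year combination appears, with 0
#' where the species was not caught.
#'
#' @param std_catches standardized catch tibble (from
#'   [standardize_catches()]).
#' @param tows tow tibble.
#' @return tibble `species_id, year, A_y`.
#' @export
annual_abundance <- function(std_catches, tows) {
  assert_cols(std_catches, c("tow_id", "species_id", "cpue_nmi"))
  assert_cols(tows, c("tow_id", "year"))
  yr <- tows$year[match(std_catches$tow_id, tows$tow_id)]
  if (anyNA(yr)) {
    stop("standardized catches reference tow_id(s) absent from the tow table")
  }
  d <- tibble::tibble(species_id = std_catches$species_id, year = yr,
                      A_y = std_catches$cpue_nmi)
  d <- dplyr::summarise(dplyr::group_by(d, species_id, year),
                        A_y = sum(A_y), .groups = "drop")
  grid <- tidyr::expand_grid(species_id = sort(unique(d$species_id)),
                             year = sort(unique(tows$year)))
  out <- dplyr::left_join(grid, d, by = c("species_id", "year"))
  out$A_y[is.na(out$A_y)] <- 0
  out
}

#' Standardized annual abundance
#'
#' `SA_y` is the species' annual abundance divided by its across-year mean,
#' the mean being taken over all survey years with data (zero-catch years
#' included), so `SA_y` averages to exactly 1 within each species. A species
#' with no positive year cannot be standardized and is an error.
#'
#' @param a_y output of [annual_abundance()].
#' @return tibble `species_id, year, SA_y`.
#' @export
standardized_abundance <- function(a_y) {
  assert_cols(a_y, c("species_id", "year", "A_y"))
  out <- dplyr::mutate(dplyr::group_by(a_y, species_id),
                       SA_y = A_y / mean(A_y))
  out <- dplyr::ungroup(out)
  if (any(!is.finite(out$SA_y))) {
    bad <- unique(out$species_id[!is.finite(out$SA_y)])
    stop(sprintf(
      "cannot standardize all-zero abundance for species: %s",
      paste(head(bad, 5L), collapse = ", ")
    ), call. = FALSE)
  }
  out[, c("species_id", "year", "SA_y")]
}

#' Abundance summaries across years and regions
#'
#' `A_s` is the mean of the species' *non-zero* annual abundances; `A_r` is
#' the across-year sum of annual abundance within each region.
#'
#' @inheritParams annual_abundance
#' @return list with tibbles `A_s` (`species_id, A_s`) and
#'   `A_r` (`species_id, region, A_r`, complete over regions with 0).
#' @export
abundance_summary <- function(std_catches, tows) {
  a_y <- annual_abundance(std_catches, tows)
  a_s <- dplyr::summarise(dplyr::group_by(a_y, species_id),
                          A_s = mean(A_y[A_y > 0]), .groups = "drop")
  assert_cols(tows, c("tow_id", "lat", "lon"))
  reg <- assign_region(tows$lat, tows$lon)[match(std_catches$tow_id,
                                                 tows$tow_id)]
  d <- tibble::tibble(species_id = std_catches$species_id, region = reg,
                      A_r = std_catches$cpue_nmi)
  d <- dplyr::summarise(dplyr::group_by(d, species_id, region),
                        A_r = sum(A_r), .groups = "drop")
  grid <- tidyr::expand_grid(species_id = sort(unique(std_catches$species_id)),
                             region = REGIONS)
  a_r <- dplyr::left_join(grid, d, by = c("species_id", "region"))
  a_r$A_r[is.na(a_r$A_r)] <- 0
  list(A_s = a_s, A_r = a_r)
}

# Environmental reference temperatures: all sampled station-year records
# with a temperature, unweighted.
env_temp_reference <- function(tows) {
  assert_cols(tows, c("bottom_temp_c"))
  t <- tows$bottom_temp_c[!is.na(tows$bottom_temp_c)]
  if (length(t) == 0L) stop("no tows carry a bottom temperature")
  list(median = median(t), mean = mean(t), n = length(t))
}

#' Thermal affinity indices
#'
#' For each species, the thermal bias index `TB` is the catch-weighted
#' median temperature-at-capture minus the unweighted median temperature of
#' all sampled tows (positive = warmwater species), and the stenothermy
#' index `Steno` is the span between the catch-weighted 5th and 95th
#' temperature percentiles (small = stenothermal). Weights are the
#' standardized catch (cpue); tows without a temperature are excluded from
#' both the species and the environmental term. The catch-weighted mean
#' occupied depth and the class bins of [classify_affinity()] are included.
#'
#' @inheritParams annual_abundance
#' @param species optional subset of species ids.
#' @return tibble `species_id, TB, Steno, mean_depth_m, tb_class, steno_bin,
#'   depth_class` (`TB`/`Steno` are `NA`, with a warning, for species never
#'   caught on a temperatured tow). The environmental reference median and
#'   mean are attached as attributes `env_median` and `env_mean`.
#' @export
thermal_affinity <- function(std_catches, tows, species = NULL) {
  assert_cols(std_catches, c("tow_id", "species_id", "cpue_nmi"))
  assert_cols(tows, c("tow_id", "depth_m", "bottom_temp_c"))
  env <- env_temp_reference(tows)
  idx <- match(std_catches$tow_id, tows$tow_id)
  if (anyNA(idx)) {
    stop("standardized catches reference tow_id(s) absent from the tow table")
  }
  d <- tibble::tibble(
    species_id = std_catches$species_id,
    cpue = std_catches$cpue_nmi,
    temp = tows$bottom_temp_c[idx],
    depth = tows$depth_m[idx]
  )
  d <- d[d$cpue > 0, ]
  if (!is.null(species)) d <- d[d$species_id %in% species, ]
  per_species <- function(g) {
    has_t <- !is.na(g$temp)
    if (!any(has_t)) {
      tb <- NA_real_
      steno <- NA_real_
    } else {
      q <- weighted_quantile(g$temp[has_t], g$cpue[has_t],
                             c(0.05, 0.5, 0.95))
      tb <- q[2] - env$median
      steno <- q[3] - q[1]
    }
    tibble::tibble(TB = tb, Steno = steno,
                   mean_depth_m = weighted.mean(g$depth, g$cpue))
  }
  out <- dplyr::group_modify(dplyr::group_by(d, species_id),
                             function(g, key) per_species(g))
  out <- dplyr::ungroup(out)
  if (anyNA(out$TB)) {
    warning(sprintf(
      "%d species have no temperatured catch; TB/Steno set to NA",
      sum(is.na(out$TB))
    ), call. = FALSE)
  }
  cls <- classify_affinity(out$TB, out$Steno, out$mean_depth_m)
  out <- dplyr::bind_cols(out, cls)
  attr(out, "env_median") <- env$median
  attr(out, "env_mean") <- env$mean
  out
}

#' @rdname thermal_affinity
#' @export
thermal_bias <- function(std_catches, tows, species = NULL) {
  aff <- thermal_affinity(std_catches, tows, species)
  setNames(aff$TB, aff$species_id)
}

#' @rdname thermal_affinity
#' @export
steno_index <- function(std_catches, tows, species = NULL) {
  aff <- thermal_affinity(std_catches, tows, species)
  setNames(aff$Steno, aff$species_id)
}

#' Classify thermal affinity and depth habitat
#'
#' Deterministic binning of the affinity indices: `tb_class` is warmwater
#' (`TB > 0`), coolwater (`-3 < TB <= 0`) or coldwater (`-7 < TB <= -3`)
#' with left-open, right-closed negative bins; TB outside `[-7, 7]` is
#' clamped with a warning. `steno_bin` uses four equal 2.5 degC bins.
#' `depth_class` splits the mean occupied depth at 300 and 800 m, boundaries
#' assigned to the shallower class.
#'
#' @param tb thermal bias index (degC, signed).
#' @param steno stenothermy index (degC, >= 0).
#' @param mean_depth mean occupied depth (m).
#' @return tibble `tb_class, steno_bin, depth_class` (factors).
#' @examples
#' classify_affinity(2.5, 3.2, 150)
#' @export
classify_affinity <- function(tb, steno, mean_depth) {
  if (any(tb < -7 | tb > 7, na.rm = TRUE)) {
    warning("TB outside [-7, 7]; clamped for classification", call. = FALSE)
    tb <- pmin(pmax(tb, -7), 7)
  }
  if (any(steno > 10, na.rm = TRUE)) {
    warning("Steno above 10; clamped for binning", call. = FALSE)
    steno <- pmin(steno, 10)
  }
  tibble::tibble(
    tb_class = cut(tb, breaks = c(-7, -3, 0, 7),
                   labels = c("coldwater", "coolwater", "warmwater"),
                   right = TRUE, include.lowest = TRUE),
    steno_bin = cut(steno, breaks = c(0, 2.5, 5, 7.5, 10),
                    labels = c("0-2.5", "2.5-5", "5-7.5", "7.5-10"),
                    right = TRUE, include.lowest = TRUE),
    depth_class = cut(mean_depth, breaks = c(0, 300, 800, Inf),
                      labels = c("shallow", "mid", "deep"),
                      right = TRUE, include.lowest = TRUE)
  )
}

#' Spatial coverage: unique stations occupied
#'
#' `Area_sr` is a simple count of the unique stations at which a species was
#' ever caught (any year, any positive catch, unweighted), within each
#' region. The grid is complete: species never caught in a region get 0.
#'
#' @inheritParams annual_abundance
#' @return tibble `species_id, region, Area_sr`.
#' @export
spatial_coverage <- function(std_catches, tows) {
  assert_cols(std_catches, c("tow_id", "species_id", "cpue_nmi"))
  assert_cols(tows, c("tow_id", "station_id", "lat", "lon"))
  idx <- match(std_catches$tow_id, tows$tow_id)
  if (anyNA(idx)) {
    stop("standardized catches reference tow_id(s) absent from the tow table")
  }
  d <- tibble::tibble(
    species_id = std_catches$species_id,
    station_id = tows$station_id[idx],
    region = assign_region(tows$lat, tows$lon)[idx],
    cpue = std_catches$cpue_nmi
  )
  d <- d[d$cpue > 0, ]
  d <- dplyr::summarise(dplyr::group_by(d, species_id, region),
                        Area_sr = dplyr::n_distinct(station_id),
                        .groups = "drop")
  grid <- tidyr::expand_grid(species_id = sort(unique(std_catches$species_id)),
                             region = REGIONS)
  out <- dplyr::left_join(grid, d, by = c("species_id", "region"))
  out$Area_sr[is.na(out$Area_sr)] <- 0L
  out
}
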