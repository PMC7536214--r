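# Abundance-weighted annual 3D centroids per species, their linear temporal
# trends, endpoint displacement as geodesic distance and bearing, and
# rose-plot data.

#' Abundance-weighted annual centroids
#'
#' The annual centre of mass of each species: the mean latitude, longitude
#' and depth of the tows in which it was caught, each tow weighted by the
#' species' standardized catch (cpue). Zero-catch tows contribute nothing; a
#' year without positive catch yields no centroid.
#'
#' @param std_catches standardized catch tibble.
#' @param tows tow tibble.
#' @param species optional subset of species ids.
#' @return tibble `species_id, year, lat_c, lon_c, depth_c, w_total`.
#' @export
annual_centroids <- function(std_catches, tows, species = NULL) {
  assert_cols(std_catches, c("tow_id", "species_id", "cpue_nmi"))
  assert_cols(tows, c("tow_id", "year", "lat", "lon", "depth_m"))
  idx <- match(std_catches$tow_id, tows$tow_id)
  if (anyNA(idx)) {
    stop("standardized catches reference tow_id(s) absent from the tow table")
  }
  d <- tibble::tibble(
    species_id = std_catches$species_id,
    year = tows$year[idx],
    lat = tows$lat[idx],
    lon = tows$lon[idx],
    depth_m = tows$depth_m[idx],
    w = std_catches$cpue_nmi
  )
  d <- d[d$w > 0, ]
  if (!is.null(species)) d <- d[d$species_id %in% species, ]
  out <- dplyr::summarise(
    dplyr::group_by(d, species_id, year),
    lat_c = weighted.mean(lat, w),
    lon_c = weighted.mean(lon, w),
    depth_c = weighted.mean(depth_m, w),
    w_total = sum(w),
    .groups = "drop"
  )
  dplyr::arrange(out, species_id, year)
}

#' Linear temporal trend of annual centroids and net displacement
#'
#' Per species: ordinary least-squares regressions of the annual centroid
#' coordinates on calendar year (two-sided p-values), the fitted locations
#' at the first and last survey year (predicted from the regression line,
#' not the raw endpoint centroids), and the geodesic distance and initial
#' bearing between those fitted endpoints. A species is flagged
#' `significant` when its latitude or longitude trend has `p < alpha` (no
#' multiple-testing correction; the number of species tested is returned as
#' an attribute `n_tested`).
#'
#' @param centroids output of [annual_centroids()].
#' @param alpha significance level for the lat/lon trend gate.
#' @param year_range first and last survey year for the fitted endpoints;
#'   defaults to the range of years present in `centroids`.
#' @return tibble with per-coordinate slopes, p-values, fitted endpoints,
#'   `distance_km`, `bearing_deg` and `significant`. Species with fewer than
#'   3 centroid years yield NA trends with a warning.
#' @export
centroid_trend <- function(centroids, alpha = 0.05, year_range = NULL) {
  assert_cols(centroids, c("species_id", "year", "lat_c", "lon_c", "depth_c"))
  year_range <- year_range %||% range(centroids$year)
  grp <- dplyr::group_by(centroids, species_id)
  n_short <- 0L
  fit_one <- function(g, key) {
    if (nrow(g) < 3) {
      n_short <<- n_short + 1L
      return(tibble::tibble(
        n_years = nrow(g),
        slope_lat = NA_real_, p_lat = NA_real_,
        slope_lon = NA_real_, p_lon = NA_real_,
        slope_depth = NA_real_, p_depth = NA_real_,
        lat_start = NA_real_, lon_start = NA_real_,
        lat_end = NA_real_, lon_end = NA_real_,
        depth_start = NA_real_, depth_end = NA_real_,
        distance_km = NA_real_, bearing_deg = NA_real_,
        significant = NA
      ))
    }
    one <- function(y) {
      fit <- lm(y ~ g$year)
      cf <- summary(fit)$coefficients
      pred <- unname(coef(fit)[1] + coef(fit)[2] * year_range)
      slope <- unname(coef(fit)[2])
      p <- if (nrow(cf) >= 2) cf[2, 4] else NA_real_
      list(slope = slope, p = p, start = pred[1], end = pred[2])
    }
    la <- one(g$lat_c)
    lo <- one(g$lon_c)
    de <- one(g$depth_c)
    gs <- geodesic_shift(la$start, lo$start, la$end, lo$end)
    tibble::tibble(
      n_years = nrow(g),
      slope_lat = la$slope, p_lat = la$p,
      slope_lon = lo$slope, p_lon = lo$p,
      slope_depth = de$slope, p_depth = de$p,
      lat_start = la$start, lon_start = lo$start,
      lat_end = la$end, lon_end = lo$end,
      depth_start = de$start, depth_end = de$end,
      distance_km = gs$distance_km, bearing_deg = gs$bearing_deg,
      significant = (!is.na(la$p) & la$p < alpha) |
        (!is.na(lo$p) & lo$p < alpha)
    )
  }
  out <- dplyr::ungroup(dplyr::group_modify(grp, fit_one))
  if (n_short > 0L) {
    warning(sprintf(
      "%d species have < 3 centroid years; trend set to NA", n_short
    ), call. = FALSE)
  }
  attr(out, "n_tested") <- sum(!is.na(out$p_lat)) + sum(!is.na(out$p_lon))
  attr(out, "alpha") <- alpha
  out
}

#' Geodesic distance and initial bearing between two points
#'
#' Distance (km) along the WGS84 ellipsoid and the initial bearing (degrees
#' clockwise from true north, in `[0, 360)`) from the start point to the end
#' point. Coincident points return distance 0 with bearing 0 by convention.
#' A spherical great-circle fallback is available; at regional scales it
#' agrees with the ellipsoidal distance to within ~0.5%.
#'
#' @param lat_start,lon_start,lat_end,lon_end coordinates in decimal
#'   degrees (vectorized).
#' @param method `"ellipsoid"` (default) or `"sphere"`.
#' @return tibble `distance_km, bearing_deg`.
#' @examples
#' geodesic_shift(64, -22, 65, -22) # due north, ~111 km
#' @export
geodesic_shift <- function(lat_start, lon_start, lat_end, lon_end,
                           method = c("ellipsoid", "sphere")) {
  method <- match.arg(method)
  if (any(!is.finite(c(lat_start, lon_start, lat_end, lon_end)))) {
    stop("non-finite coordinate passed to geodesic_shift()")
  }
  p1 <- cbind(lon_start, lat_start)
  p2 <- cbind(lon_end, lat_end)
  dist_m <- if (method == "ellipsoid") {
    geosphere::distGeo(p1, p2)
  } else {
    geosphere::distHaversine(p1, p2)
  }
  brg <- geosphere::bearing(p1, p2) %% 360
  brg[brg >= 360 - 1e-9] <- 0
  same <- dist_m == 0 | (lat_start == lat_end & lon_start == lon_end)
  brg[same] <- 0
  dist_m[same] <- 0
  tibble::tibble(distance_km = dist_m / 1000, bearing_deg = brg)
}

#' Rose-plot table of significant shift vectors
#'
#' One row per species whose latitude or longitude centroid trend is
#' significant: bearing, distance (with a log10 column for display) and,
#' when an affinity table is supplied, the depth/stenothermy/thermal-bias
#' class bins used to colour rose plots.
#'
#' @param trends output of [centroid_trend()].
#' @param affinity optional output of [thermal_affinity()].
#' @return tibble `species_id, bearing_deg, distance_km, log10_km` plus any
#'   class columns.
#' @export
rose_table <- function(trends, affinity = NULL) {
  assert_cols(trends, c("species_id", "bearing_deg", "distance_km",
                        "significant"))
  out <- trends[!is.na(trends$significant) & trends$significant,
                c("species_id", "bearing_deg", "distance_km")]
  out$log10_km <- log10(pmax(out$distance_km, 1e-3))
  if (!is.null(affinity)) {
    out <- dplyr::left_join(
      out,
      affinity[, c("species_id", "tb_class", "steno_bin", "depth_class")],
      by = "species_id"
    )
  }
  out
}
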