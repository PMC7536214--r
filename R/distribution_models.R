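# The linear-model battery: thermal-habitat models of temperature-at-capture,
# pooled 3D location models with year/temperature/abundance covariates and
# species interactions, per-species spatially-structured regional models, and
# shift predictions for +1 degC and for an abundance doubling.
#
# "Multivariate GLM" means per-response least squares on a shared design
# matrix (coefficients identical to a joint multivariate fit); significance
# is per-response. Observation rows are one per (tow x species with positive
# catch), weighted by cpue, so the fits target abundance-weighted location.
# Because cpue weights are not inverse error variances, significance in the
# regional model uses heteroscedasticity-robust (sandwich) covariances;
# classical type-III F-tests remain available in the summaries.

#' Build the observation table for the location models
#'
#' One row per tow x species-with-positive-catch, carrying location, depth,
#' temperature-at-capture, the annual environmental temperature (joined by
#' year), the species' standardized annual abundance (joined by species and
#' year) and the cpue weight. Rows without a bottom temperature are retained
#' but flagged (`has_temp`); temperature-response fits exclude them.
#'
#' @param std_catches standardized catch tibble.
#' @param tows tow tibble.
#' @param temp_e tibble `year, temp_e` from [marginal_means()].
#' @param sa_y tibble `species_id, year, SA_y` from
#'   [standardized_abundance()].
#' @param species optional subset of species ids (e.g. the core set).
#' @return tibble, one row per positive catch.
#' @export
build_observations <- function(std_catches, tows, temp_e, sa_y,
                               species = NULL) {
  assert_cols(std_catches, c("tow_id", "species_id", "cpue_nmi"))
  assert_cols(tows, c("tow_id", "station_id", "year", "lat", "lon",
                      "depth_m", "bottom_temp_c"))
  assert_cols(temp_e, c("year", "temp_e"))
  assert_cols(sa_y, c("species_id", "year", "SA_y"))
  d <- std_catches[std_catches$cpue_nmi > 0, ]
  if (!is.null(species)) d <- d[d$species_id %in% species, ]
  idx <- match(d$tow_id, tows$tow_id)
  if (anyNA(idx)) {
    stop("standardized catches reference tow_id(s) absent from the tow table")
  }
  obs <- tibble::tibble(
    species_id = d$species_id,
    tow_id = d$tow_id,
    station_id = tows$station_id[idx],
    region = assign_region(tows$lat, tows$lon)[idx],
    year = tows$year[idx],
    lat = tows$lat[idx],
    lon = tows$lon[idx],
    depth_m = tows$depth_m[idx],
    bottom_temp_c = tows$bottom_temp_c[idx],
    weight = d$cpue_nmi
  )
  obs$temp_e <- temp_e$temp_e[match(obs$year, temp_e$year)]
  if (anyNA(obs$temp_e)) {
    stop("observation years missing from the Temp_e series")
  }
  key_obs <- paste(obs$species_id, obs$year, sep = "\r")
  key_sa <- paste(sa_y$species_id, sa_y$year, sep = "\r")
  obs$sa_y <- sa_y$SA_y[match(key_obs, key_sa)]
  if (anyNA(obs$sa_y)) {
    bad <- unique(obs$species_id[is.na(obs$sa_y)])
    stop(sprintf("species missing SA_y: %s",
                 paste(head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  obs$has_temp <- !is.na(obs$bottom_temp_c)
  obs
}

# Shared tidy summary of a weighted lm.
fit_summary <- function(fit) {
  sm <- summary(fit)
  tibble::tibble(
    term = rownames(sm$coefficients),
    estimate = sm$coefficients[, 1],
    se = sm$coefficients[, 2],
    p_value = sm$coefficients[, 4]
  )
}

#' Thermal-habitat models of temperature-at-capture
#'
#' Weighted least-squares models of the bottom temperature at which each
#' catch was taken. Variants build hierarchically:
#' \describe{
#'   \item{`species`}{`temp ~ species` - thermal affinities alone.}
#'   \item{`year`}{adds calendar year as a covariate.}
#'   \item{`tempe_depth`}{replaces year with the annual environmental
#'     temperature and depth.}
#'   \item{`abundance`}{adds standardized annual abundance as a main effect
#'     and with slopes nested within species.}
#' }
#'
#' @param obs observation table from [build_observations()]; rows without a
#'   temperature are dropped.
#' @param variant which model to fit.
#' @return list of class `habitat_fit`: the `lm`, variant name, `r_squared`,
#'   `aic`, `n`, coefficient table, and the year/Temp_e/depth slopes where
#'   present.
#' @export
fit_thermal_habitat <- function(obs,
                                variant = c("species", "year", "tempe_depth",
                                            "abundance")) {
  variant <- match.arg(variant)
  d <- obs[obs$has_temp, , drop = FALSE]
  if (length(unique(d$species_id)) < 1) stop("no species to fit")
  d$species <- factor(d$species_id)
  multi <- nlevels(d$species) > 1
  sp_term <- if (multi) "species" else NULL
  terms_rhs <- switch(variant,
    species = sp_term %||% "1",
    year = c(sp_term, "year"),
    tempe_depth = c(sp_term, "temp_e", "depth_m"),
    abundance = c(sp_term, "temp_e", "depth_m", "sa_y",
                  if (multi) "species:sa_y")
  )
  form <- stats::reformulate(terms_rhs, response = "bottom_temp_c")
  fit <- lm(form, data = d, weights = d$weight)
  sm <- summary(fit)
  slopes <- coef(fit)[intersect(c("year", "temp_e", "depth_m", "sa_y"),
                                names(coef(fit)))]
  structure(
    list(
      fit = fit, variant = variant,
      r_squared = if (is.null(sm$r.squared)) 0 else sm$r.squared,
      aic = AIC(fit), n = nrow(d),
      coefficients = fit_summary(fit),
      slopes = slopes
    ),
    class = "habitat_fit"
  )
}

#' Compare thermal-habitat model variants by AIC
#'
#' @param obs observation table.
#' @param variants variants to fit (see [fit_thermal_habitat()]).
#' @return tibble `variant, aic, r_squared, n` sorted by AIC, with the fits
#'   as attribute `fits`.
#' @export
compare_thermal_habitat <- function(obs,
                                    variants = c("species", "year",
                                                 "tempe_depth")) {
  fits <- lapply(variants, function(v) fit_thermal_habitat(obs, v))
  names(fits) <- variants
  out <- tibble::tibble(
    variant = variants,
    aic = vapply(fits, `[[`, 0, "aic"),
    r_squared = vapply(fits, `[[`, 0, "r_squared"),
    n = vapply(fits, `[[`, 0L, "n")
  )
  out <- dplyr::arrange(out, aic)
  attr(out, "fits") <- fits
  out
}

#' Residual-vs-abundance screen for thermal habitat
#'
#' Regresses the standardized residuals of a thermal-habitat model *without*
#' an abundance term on each species' standardized annual abundance. A
#' significant slope means the species' thermal habitat shifts with its own
#' abundance (negative = cooler water when abundant).
#'
#' @param obs observation table.
#' @param alpha significance level.
#' @param base_variant habitat-model variant providing the residuals (must
#'   exclude abundance).
#' @return tibble `species_id, slope, p_value, significant, sign`; species
#'   with < 3 distinct SA_y values are skipped. Counts are attached as
#'   attributes `n_significant` and `n_negative`.
#' @export
residual_abundance_screen <- function(obs, alpha = 0.05,
                                      base_variant = "tempe_depth") {
  hab <- fit_thermal_habitat(obs, base_variant)
  d <- obs[obs$has_temp, , drop = FALSE]
  d$resid <- stats::rstandard(hab$fit)
  grp <- dplyr::group_by(d, species_id)
  out <- dplyr::ungroup(dplyr::group_modify(grp, function(g, key) {
    if (length(unique(g$sa_y)) < 3) {
      return(tibble::tibble(slope = NA_real_, p_value = NA_real_,
                            skipped = TRUE))
    }
    fit <- lm(resid ~ sa_y, data = g)
    cf <- summary(fit)$coefficients
    tibble::tibble(slope = unname(coef(fit)["sa_y"]),
                   p_value = cf["sa_y", 4], skipped = FALSE)
  }))
  if (any(out$skipped)) {
    warning(sprintf("%d species skipped (< 3 distinct SA_y values)",
                    sum(out$skipped)), call. = FALSE)
  }
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  out$sign <- sign(out$slope)
  attr(out, "n_significant") <- sum(out$significant)
  attr(out, "n_negative") <- sum(out$significant & out$sign < 0)
  out
}

#' Pooled location model across all species
#'
#' Weighted least-squares fits of latitude, longitude and depth at capture
#' on a shared design: species as a factor, a temporal covariate (calendar
#' year or the annual environmental temperature) and standardized annual
#' abundance, optionally with species-specific slopes for both covariates.
#'
#' @param obs observation table.
#' @param covariate `"temp_e"` or `"year"`.
#' @param interactions add `species:covariate` and `species:SA_y` slopes.
#' @return list of class `location_fit`: per-response `lm`s, `r_squared`,
#'   `aic` (per response and total), the main-effect covariate and SA_y
#'   slopes with SEs, and - with interactions - per-species combined slopes
#'   for each response.
#' @export
fit_location_model <- function(obs, covariate = c("temp_e", "year"),
                               interactions = TRUE) {
  covariate <- match.arg(covariate)
  d <- obs
  d$species <- factor(d$species_id)
  d$x <- d[[covariate]]
  rhs <- if (interactions) {
    ~ species + x + sa_y + species:x + species:sa_y
  } else {
    ~ species + x + sa_y
  }
  responses <- c(lat = "lat", lon = "lon", depth = "depth_m")
  fits <- lapply(responses, function(r) {
    lm(stats::reformulate(attr(terms(rhs), "term.labels"), response = r),
       data = d, weights = d$weight)
  })
  main_slopes <- lapply(fits, function(f) {
    cf <- summary(f)$coefficients
    grab <- function(term) {
      if (term %in% rownames(cf)) unname(cf[term, 1:2]) else c(NA_real_,
                                                               NA_real_)
    }
    list(x = grab("x"), sa_y = grab("sa_y"))
  })
  per_species <- NULL
  if (interactions) {
    sp_levels <- levels(d$species)
    per_species <- lapply(fits, function(f) {
      b <- coef(f)
      b[is.na(b)] <- 0
      xs <- b["x"] + ifelse(
        paste0("species", sp_levels, ":x") %in% names(b),
        b[paste0("species", sp_levels, ":x")], 0
      )
      as_ <- b["sa_y"] + ifelse(
        paste0("species", sp_levels, ":sa_y") %in% names(b),
        b[paste0("species", sp_levels, ":sa_y")], 0
      )
      tibble::tibble(species_id = sp_levels, slope_x = unname(xs),
                     slope_sa_y = unname(as_))
    })
  }
  structure(
    list(
      fits = fits, covariate = covariate, interactions = interactions,
      r_squared = vapply(fits, function(f) summary(f)$r.squared, 0),
      aic = vapply(fits, AIC, 0),
      aic_total = sum(vapply(fits, AIC, 0)),
      main_slopes = main_slopes,
      per_species_slopes = per_species,
      n = nrow(d)
    ),
    class = "location_fit"
  )
}

#' @export
print.location_fit <- function(x, ...) {
  cat(sprintf("Pooled 3D location model (covariate: %s, interactions: %s)\n",
              x$covariate, x$interactions))
  cat(sprintf("  n rows: %d\n", x$n))
  for (r in names(x$fits)) {
    cat(sprintf("  %-5s r^2 = %.3f  AIC = %.1f\n",
                r, x$r_squared[[r]], x$aic[[r]]))
  }
  invisible(x)
}

# ---- spatially-structured per-species model ---------------------------------

# Robust covariance used for inference in the regional model.
robust_vcov <- function(fit) {
  sandwich::vcovHC(fit, type = "HC1")
}

# Per-region covariate slopes of one response fit, via design-matrix
# differencing (coding-independent): slope = E[y | x0 + 1] - E[y | x0].
region_slopes <- function(fit, vc, regions, var, baseline) {
  tt <- delete.response(terms(fit))
  make_grid <- function(xval) {
    g <- data.frame(region = factor(regions,
                                    levels = fit$xlevels$region %||% regions),
                    temp_e = baseline$temp_e, sa_y = baseline$sa_y)
    g[[var]] <- xval
    g
  }
  X0 <- model.matrix(tt, make_grid(baseline[[var]]),
                     contrasts.arg = fit$contrasts, xlev = fit$xlevels)
  X1 <- model.matrix(tt, make_grid(baseline[[var]] + 1),
                     contrasts.arg = fit$contrasts, xlev = fit$xlevels)
  L <- X1 - X0
  beta <- coef(fit)
  ok <- !is.na(beta)
  b <- beta
  b[!ok] <- 0
  est <- drop(L %*% b)
  Lok <- L[, ok, drop = FALSE]
  se <- sqrt(pmax(rowSums((Lok %*% vc) * Lok), 0))
  df <- df.residual(fit)
  est <- unname(est)
  se <- unname(se)
  p <- 2 * pt(abs(est / se), df, lower.tail = FALSE)
  tibble::tibble(region = regions, slope = est, se = se, p_value = p)
}

#' Spatially-structured regional model for one species
#'
#' Weighted least-squares fits of latitude, longitude and depth at capture
#' for a single species, with region as a factor (sum-to-zero contrasts),
#' the annual environmental temperature and standardized annual abundance as
#' covariates, and region x covariate interactions so each region gets its
#' own slopes. Regions contributing fewer than `min_region_n` rows are
#' dropped with a warning; a species confined to one region reduces to a
#' covariates-only model. A main-effects-only variant is fitted alongside
#' for the AIC comparison; inference and predictions use the full model.
#'
#' Significance is assessed per response with heteroscedasticity-robust
#' (HC1) covariances: a joint Wald test of all Temp_e terms (main effect and
#' region interactions) and likewise for SA_y; per-region slopes carry
#' robust SEs and two-sided p-values.
#'
#' @param obs observation table rows for one species (rows without a
#'   temperature are excluded - Temp_e is a year covariate but weights and
#'   responses come from temperature-measured tows only when `use_temp_rows`
#'   is `TRUE`; default keeps all rows since the covariates are year-level).
#' @param alpha significance level.
#' @param min_region_n minimum rows for a region to enter the model.
#' @param use_temp_rows restrict to rows with a measured tow temperature.
#' @return list of class `regional_fit` (or `NULL` with a warning if no
#'   region has enough rows).
#' @export
fit_regional_model <- function(obs, alpha = 0.05, min_region_n = 10,
                               use_temp_rows = FALSE) {
  sp <- unique(obs$species_id)
  if (length(sp) != 1) stop("fit_regional_model() expects a single species")
  d <- obs
  if (use_temp_rows) d <- d[d$has_temp, , drop = FALSE]
  counts <- table(d$region)
  keep <- names(counts)[counts >= min_region_n]
  if (length(keep) == 0L) {
    warning(sprintf("species %s: no region with >= %d rows; not fitted",
                    sp, min_region_n), call. = FALSE)
    return(NULL)
  }
  if (length(keep) < length(counts)) {
    warning(sprintf(
      "species %s: dropping region(s) %s with < %d rows", sp,
      paste(setdiff(names(counts), keep), collapse = ", "), min_region_n
    ), call. = FALSE)
    d <- d[d$region %in% keep, , drop = FALSE]
  }
  d$region <- factor(d$region, levels = sort(keep))
  multi_region <- nlevels(d$region) > 1
  rhs_full <- if (multi_region) {
    ~ region + temp_e + sa_y + region:temp_e + region:sa_y
  } else {
    ~ temp_e + sa_y
  }
  rhs_main <- if (multi_region) ~ region + temp_e + sa_y else ~ temp_e + sa_y
  contrasts_arg <- if (multi_region) list(region = "contr.sum") else NULL

  fit_resp <- function(rhs, resp) {
    lm(stats::reformulate(attr(terms(rhs), "term.labels"), response = resp),
       data = d, weights = d$weight, contrasts = contrasts_arg)
  }
  responses <- c(lat = "lat", lon = "lon", depth = "depth_m")
  fits <- lapply(responses, function(r) fit_resp(rhs_full, r))
  fits_main <- lapply(responses, function(r) fit_resp(rhs_main, r))

  baseline <- list(temp_e = mean(d$temp_e), sa_y = 1)
  regions <- levels(d$region) %||% sort(keep)

  per_resp <- lapply(names(fits), function(r) {
    f <- fits[[r]]
    vc <- robust_vcov(f)
    list(
      response = r,
      p_temp = term_wald(f, "temp_e", vc)$p_value,
      p_sa = term_wald(f, "sa_y", vc)$p_value,
      temp_slopes = region_slopes(f, vc, regions, "temp_e", baseline),
      sa_slopes = region_slopes(f, vc, regions, "sa_y", baseline),
      r_squared = summary(f)$r.squared,
      aic_full = AIC(f)
    )
  })
  names(per_resp) <- names(fits)

  structure(
    list(
      species_id = sp,
      fits = fits,
      regions = regions,
      n_by_region = as.integer(table(d$region)),
      baseline = baseline,
      temp_e_range = range(d$temp_e),
      alpha = alpha,
      per_response = per_resp,
      aic = tibble::tibble(
        response = names(fits),
        aic_main = vapply(fits_main, AIC, 0),
        aic_full = vapply(fits, AIC, 0)
      ),
      centroids = dplyr::summarise(
        dplyr::group_by(d, region),
        lat = weighted.mean(lat, weight),
        lon = weighted.mean(lon, weight),
        n_obs = dplyr::n(),
        w_total = sum(weight),
        .groups = "drop"
      )
    ),
    class = "regional_fit"
  )
}

#' Predicted distribution shift for warming and abundance perturbations
#'
#' From a fitted regional model, the predicted change in latitude, longitude
#' and depth per region for (a) a +1 degC increase in the environmental
#' temperature about its mean, and (b) a doubling of standardized annual
#' abundance (SA_y moved from its mean of 1 to 2). Because the model is
#' linear, each shift is the corresponding region-specific slope. Distance
#' and bearing are evaluated geodesically at the species' regional centroid.
#' Species-level significance flags come from the joint robust Wald tests of
#' all Temp_e (resp. SA_y) terms in any response; region-level flags from
#' the region-specific slope tests.
#'
#' A warning (not an error) is issued when the +1 degC perturbation
#' extrapolates more than 1 degC beyond the observed Temp_e range.
#'
#' @param rfit a `regional_fit` from [fit_regional_model()].
#' @param perturbation which perturbations to report.
#' @return tibble, one row per region, with `dlat_per_c, dlon_per_c,
#'   ddepth_per_c, dlat_per_doubling, dlon_per_doubling, ddepth_per_doubling`,
#'   per-perturbation `distance_km`/`bearing_deg`, and significance flags.
#' @export
predict_shift <- function(rfit,
                          perturbation = c("both", "temperature",
                                           "abundance")) {
  perturbation <- match.arg(perturbation)
  stopifnot(inherits(rfit, "regional_fit"))
  if (rfit$baseline$temp_e + 1 > rfit$temp_e_range[2] + 1 + 1e-9) {
    warning("Temp_e perturbation extrapolates beyond the observed range + 1",
            call. = FALSE)
  }
  pr <- rfit$per_response
  alpha <- rfit$alpha
  grab <- function(what, which_slope) {
    s <- pr[[what]][[which_slope]]
    s[match(rfit$regions, s$region), ]
  }
  t_lat <- grab("lat", "temp_slopes")
  t_lon <- grab("lon", "temp_slopes")
  t_dep <- grab("depth", "temp_slopes")
  a_lat <- grab("lat", "sa_slopes")
  a_lon <- grab("lon", "sa_slopes")
  a_dep <- grab("depth", "sa_slopes")

  cen <- rfit$centroids[match(rfit$regions, rfit$centroids$region), ]
  gs_t <- geodesic_shift(cen$lat, cen$lon,
                         cen$lat + t_lat$slope, cen$lon + t_lon$slope)
  gs_a <- geodesic_shift(cen$lat, cen$lon,
                         cen$lat + a_lat$slope, cen$lon + a_lon$slope)

  p_temp_any <- vapply(pr, `[[`, 0, "p_temp")
  p_sa_any <- vapply(pr, `[[`, 0, "p_sa")

  out <- tibble::tibble(
    species_id = rfit$species_id,
    region = rfit$regions,
    n_obs = cen$n_obs,
    centroid_lat = cen$lat,
    centroid_lon = cen$lon,
    dlat_per_c = t_lat$slope,
    dlon_per_c = t_lon$slope,
    ddepth_per_c = t_dep$slope,
    p_dlat_per_c = t_lat$p_value,
    p_dlon_per_c = t_lon$p_value,
    p_ddepth_per_c = t_dep$p_value,
    distance_km_temp = gs_t$distance_km,
    bearing_deg_temp = gs_t$bearing_deg,
    dlat_per_doubling = a_lat$slope,
    dlon_per_doubling = a_lon$slope,
    ddepth_per_doubling = a_dep$slope,
    p_dlat_per_doubling = a_lat$p_value,
    p_dlon_per_doubling = a_lon$p_value,
    p_ddepth_per_doubling = a_dep$p_value,
    distance_km_abund = gs_a$distance_km,
    bearing_deg_abund = gs_a$bearing_deg,
    temp_significant = (t_lat$p_value < alpha) | (t_lon$p_value < alpha) |
      (t_dep$p_value < alpha),
    abundance_significant = (a_lat$p_value < alpha) |
      (a_lon$p_value < alpha) | (a_dep$p_value < alpha),
    temp_significant_species = any(p_temp_any < alpha, na.rm = TRUE),
    abundance_significant_species = any(p_sa_any < alpha, na.rm = TRUE),
    p_temp_lat_species = unname(p_temp_any["lat"]),
    p_temp_lon_species = unname(p_temp_any["lon"]),
    p_temp_depth_species = unname(p_temp_any["depth"])
  )
  if (perturbation == "temperature") {
    out <- out[, !grepl("doubling|abund", names(out))]
  } else if (perturbation == "abundance") {
    out <- out[, !grepl("per_c$|_temp$|temp_significant", names(out))]
  }
  out
}

#' Whole-range temperature response per species
#'
#' Estimates each species' total centroid displacement per +1 degC from the
#' year-level series: the abundance-weighted annual centroid latitude (and
#' longitude) regressed on the annual environmental temperature with the
#' standardized annual abundance as a covariate, by ordinary least squares
#' over the survey years. The region-structured model of
#' [fit_regional_model()] estimates within-region redistribution; when a
#' species' whole range translates (as with warming-driven drift), most of
#' the displacement shows up as mass transfer between regions, so the
#' whole-range slope - not the within-region slopes - is the estimate
#' comparable to an injected drift. Year-level OLS is used because the
#' dominant sampling noise in a centroid is the year-to-year catch
#' realization, which the 22 annual replicates estimate directly.
#'
#' @param obs observation table (one or many species).
#' @param alpha significance level for the detection flag.
#' @param min_years minimum centroid years required.
#' @param adjust_abundance include the standardized annual abundance as a
#'   covariate. Off by default: SA_y is estimated from the same catches as
#'   the centroid, so for species whose abundance barely varies it absorbs
#'   correlated sampling noise and mildly inflates the temperature test;
#'   the abundance-adjusted effects live in [fit_regional_model()].
#' @return tibble `species_id, n_obs, n_years, dlat_per_c, se, p_value,
#'   km_per_c, dlon_per_c, p_lon, detected` (detection = latitude Temp_e
#'   effect with `p < alpha`).
#' @export
drift_recovery <- function(obs, alpha = 0.05, min_years = 8,
                           adjust_abundance = FALSE) {
  grp <- dplyr::group_by(obs, species_id)
  out <- dplyr::group_modify(grp, function(d, key) {
    ann <- dplyr::summarise(
      dplyr::group_by(d, year),
      lat_c = weighted.mean(lat, weight),
      lon_c = weighted.mean(lon, weight),
      temp_e = temp_e[1],
      sa_y = sa_y[1],
      .groups = "drop"
    )
    if (nrow(ann) < min_years) {
      return(tibble::tibble(n_obs = nrow(d), n_years = nrow(ann),
                            dlat_per_c = NA_real_, se = NA_real_,
                            p_value = NA_real_, km_per_c = NA_real_,
                            dlon_per_c = NA_real_, p_lon = NA_real_,
                            detected = NA))
    }
    rhs <- if (adjust_abundance) c("temp_e", "sa_y") else "temp_e"
    one <- function(resp) {
      f <- lm(stats::reformulate(rhs, response = resp), data = ann)
      cf <- summary(f)$coefficients
      list(b = unname(cf["temp_e", 1]), se = unname(cf["temp_e", 2]),
           p = unname(cf["temp_e", 4]))
    }
    la <- one("lat_c")
    lo <- one("lon_c")
    tibble::tibble(
      n_obs = nrow(d), n_years = nrow(ann),
      dlat_per_c = la$b, se = la$se, p_value = la$p,
      km_per_c = lat_deg_to_km(la$b), dlon_per_c = lo$b, p_lon = lo$p,
      detected = la$p < alpha
    )
  })
  dplyr::ungroup(out)
}

#' Fit regional models and collect shift predictions for many species
#'
#' Convenience driver: fits [fit_regional_model()] per species and binds the
#' [predict_shift()] rows. Species that cannot be fitted (no region with
#' enough rows) are skipped with the underlying warning.
#'
#' @param obs observation table (possibly many species).
#' @param species species to fit; default all in `obs`.
#' @inheritParams fit_regional_model
#' @return list with `predictions` (tibble) and `fits` (named list).
#' @export
fit_regional_models <- function(obs, species = NULL, alpha = 0.05,
                                min_region_n = 10) {
  species <- species %||% sort(unique(obs$species_id))
  fits <- list()
  preds <- list()
  for (sp in species) {
    rf <- fit_regional_model(obs[obs$species_id == sp, , drop = FALSE],
                             alpha = alpha, min_region_n = min_region_n)
    if (is.null(rf)) next
    fits[[sp]] <- rf
    preds[[sp]] <- suppressWarnings(predict_shift(rf))
  }
  list(predictions = dplyr::bind_rows(preds), fits = fits)
}
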