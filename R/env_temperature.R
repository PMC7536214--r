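# Survey-standardized annual environmental temperature (Temp_e) from a
# station + year + day-of-year linear model, regional depth-temperature
# profiles, and hydrographic series summaries.

#' Fit the environmental temperature model
#'
#' A raw annual mean of tow temperatures confounds real warming with changes
#' in which stations were fished and when. The model
#' `bottom_temp_c ~ station + year + doy` (both factors under sum-to-zero
#' contrasts, day-of-year as a covariate) removes station composition and
#' survey-timing effects; its per-year marginal means are the annual
#' environmental temperature index `Temp_e`. Stations observed in a single
#' year only are dropped with a warning (their station effect would be
#' confounded with that year).
#'
#' @param tows tow tibble; rows without a temperature are ignored.
#' @return an object of class `temp_model`: the `lm` fit plus the DOY slope
#'   and its SE, `r_squared`, and the data used.
#' @seealso [marginal_means()], [doy_effect()], [warming_rate()]
#' @export
fit_temp_model <- function(tows) {
  assert_cols(tows, c("station_id", "year", "doy", "bottom_temp_c"))
  d <- tows[!is.na(tows$bottom_temp_c), , drop = FALSE]
  yrs_per_station <- tapply(d$year, d$station_id,
                            function(y) length(unique(y)))
  single <- names(yrs_per_station)[yrs_per_station < 2]
  if (length(single) > 0L && length(yrs_per_station) > length(single)) {
    warning(sprintf(
      "dropping %d station(s) observed in a single year (confounded with year)",
      length(single)
    ), call. = FALSE)
    d <- d[!(d$station_id %in% single), , drop = FALSE]
  }
  n_st <- length(unique(d$station_id))
  n_yr <- length(unique(d$year))
  if (n_st < 2 || n_yr < 2) {
    stop("temperature model needs >= 2 stations and >= 2 years with data")
  }
  if (nrow(d) < n_st + n_yr + 2) {
    stop("too few temperatured tows to identify station and year effects")
  }
  d$station <- factor(d$station_id)
  d$yearf <- factor(d$year)
  fit <- lm(bottom_temp_c ~ station + yearf + doy, data = d,
            contrasts = list(station = "contr.sum", yearf = "contr.sum"))
  if (anyNA(coef(fit))) {
    warning("rank-deficient temperature model; aliased effects treated as 0",
            call. = FALSE)
  }
  sm <- summary(fit)
  has_doy <- "doy" %in% rownames(sm$coefficients)
  structure(
    list(
      fit = fit,
      data = d,
      doy_mean = mean(d$doy),
      stations = levels(d$station),
      years = sort(unique(d$year)),
      doy_slope = if (has_doy) unname(coef(fit)["doy"]) else NA_real_,
      doy_se = if (has_doy) {
        unname(sm$coefficients["doy", "Std. Error"])
      } else {
        NA_real_
      },
      r_squared = sm$r.squared
    ),
    class = "temp_model"
  )
}

#' @export
print.temp_model <- function(x, ...) {
  cat("Environmental temperature model (temp ~ station + year + doy)\n")
  cat(sprintf("  stations: %d   years: %d   n: %d\n",
              length(x$stations), length(x$years), nrow(x$data)))
  cat(sprintf("  DOY slope: %.4f degC/day (SE %.4f)   r^2: %.3f\n",
              x$doy_slope, x$doy_se, x$r_squared))
  invisible(x)
}

# Prediction that tolerates aliased (NA) coefficients by treating them as 0.
predict_temp <- function(object, newdata, se = FALSE) {
  tt <- delete.response(terms(object$fit))
  X <- model.matrix(tt, newdata, contrasts.arg = object$fit$contrasts,
                    xlev = object$fit$xlevels)
  beta <- coef(object$fit)
  beta[is.na(beta)] <- 0
  drop(X %*% beta)
}

#' Estimated marginal mean temperature per year (Temp_e)
#'
#' For each year, the model prediction averaged over *all* station levels
#' with day-of-year fixed at its grand mean. In a balanced design with
#' constant DOY this reduces to the raw annual mean; in an unbalanced design
#' it corrects the raw mean toward the balanced value.
#'
#' @param object a `temp_model` from [fit_temp_model()].
#' @return tibble `year, temp_e, se`.
#' @export
marginal_means <- function(object) {
  stopifnot(inherits(object, "temp_model"))
  fit <- object$fit
  tt <- delete.response(terms(fit))
  beta <- coef(fit)
  ok <- !is.na(beta)
  vc <- vcov(fit)[ok, ok, drop = FALSE]
  out <- lapply(object$years, function(y) {
    grid <- data.frame(
      station = factor(object$stations, levels = object$stations),
      yearf = factor(y, levels = fit$xlevels$yearf),
      doy = object$doy_mean
    )
    X <- model.matrix(tt, grid, contrasts.arg = fit$contrasts,
                      xlev = fit$xlevels)
    xbar <- colMeans(X)
    b <- beta
    b[!ok] <- 0
    est <- drop(xbar %*% b)
    se <- sqrt(drop(t(xbar[ok]) %*% vc %*% xbar[ok]))
    tibble::tibble(year = y, temp_e = est, se = se)
  })
  dplyr::bind_rows(out)
}

#' Temperature effect of a survey-timing difference
#'
#' The inter-annual mean temperature difference implied by a shift in survey
#' timing: `|DOY slope| * delta_days`.
#'
#' @param object a `temp_model`, or a numeric DOY slope (degC per day).
#' @param delta_days timing difference in days.
#' @return degrees Celsius (non-negative).
#' @examples
#' doy_effect(-0.003, 10) # 0.03
#' @export
doy_effect <- function(object, delta_days) {
  slope <- if (inherits(object, "temp_model")) object$doy_slope else object
  abs(slope) * delta_days
}

#' Warming rate of the environmental temperature series
#'
#' Ordinary least-squares trend of `Temp_e` on calendar year, and the net
#' change implied over the span of the series (`slope * (last - first
#' year)`).
#'
#' @param temp_e tibble `year, temp_e` (as from [marginal_means()]).
#' @return list with `slope_c_per_year`, `slope_se`, `net_change_c`,
#'   `first_year`, `last_year`.
#' @export
warming_rate <- function(temp_e) {
  assert_cols(temp_e, c("year", "temp_e"))
  if (nrow(temp_e) < 3) stop("warming_rate needs >= 3 years of Temp_e")
  fit <- lm(temp_e ~ year, data = temp_e)
  slope <- unname(coef(fit)["year"])
  span <- max(temp_e$year) - min(temp_e$year)
  list(
    slope_c_per_year = slope,
    slope_se = unname(summary(fit)$coefficients["year", "Std. Error"]),
    net_change_c = slope * span,
    first_year = min(temp_e$year),
    last_year = max(temp_e$year)
  )
}

#' Regional depth-temperature profiles from survey tows
#'
#' Unweighted mean bottom temperature in depth bins per region; an optional
#' local-linear smooth of the bin means is appended (the bin means, not the
#' smooth, are the primary summary).
#'
#' @param tows tow tibble.
#' @param bin_width depth bin width in metres.
#' @param smooth add a local-linear (loess, degree 1) smooth of bin means.
#' @return tibble `region, depth_bin, mean_temp, n` (+ `smooth_temp`).
#' @export
depth_profile <- function(tows, bin_width = 50, smooth = FALSE) {
  assert_cols(tows, c("lat", "lon", "depth_m", "bottom_temp_c"))
  d <- tows[!is.na(tows$bottom_temp_c), , drop = FALSE]
  d <- dplyr::mutate(d,
                     region = assign_region(lat, lon),
                     depth_bin = floor(depth_m / bin_width) * bin_width +
                       bin_width / 2)
  out <- dplyr::summarise(dplyr::group_by(d, region, depth_bin),
                          mean_temp = mean(bottom_temp_c),
                          n = dplyr::n(), .groups = "drop")
  out <- dplyr::arrange(out, region, depth_bin)
  if (smooth) {
    out <- dplyr::group_modify(dplyr::group_by(out, region), function(g, key) {
      if (nrow(g) >= 5) {
        lo <- stats::loess(mean_temp ~ depth_bin, data = g, degree = 1,
                           span = 0.75)
        g$smooth_temp <- predict(lo, g$depth_bin)
      } else {
        g$smooth_temp <- g$mean_temp
      }
      g
    })
    out <- dplyr::ungroup(out)
  }
  out
}

#' Interpolated profile temperature at a reference depth
#'
#' Linear interpolation of the binned profile means at an arbitrary depth;
#' convenience for comparing regions at, e.g., 500 m.
#'
#' @param profile output of [depth_profile()].
#' @param region region code.
#' @param depth_m depth at which to interpolate.
#' @return degrees Celsius (NA if the region has < 2 bins).
#' @export
profile_at_depth <- function(profile, region, depth_m) {
  g <- profile[profile$region == region, ]
  if (nrow(g) < 2) return(NA_real_)
  approx(g$depth_bin, g$mean_temp, xout = depth_m, rule = 2)$y
}

#' Summaries of hydrographic station series
#'
#' Per station x season: annual mean temperatures and the OLS linear trend
#' across years. Optional input; an empty table yields an empty result.
#'
#' @param hydro tibble `station, season, year, temp` (one or more records
#'   per station-season-year).
#' @return tibble `station, season, n_years, mean_temp, slope_c_per_year,
#'   slope_se`.
#' @export
hydro_summary <- function(hydro) {
  assert_cols(hydro, c("station", "season", "year", "temp"))
  ann <- dplyr::summarise(
    dplyr::group_by(hydro, station, season, year),
    temp = mean(temp), .groups = "drop"
  )
  grp <- dplyr::group_by(ann, station, season)
  dplyr::ungroup(dplyr::group_modify(grp, function(g, key) {
    if (nrow(g) >= 2 && var(g$year) > 0) {
      fit <- lm(temp ~ year, data = g)
      slope <- unname(coef(fit)["year"])
      se <- if (nrow(g) >= 3) {
        unname(summary(fit)$coefficients["year", "Std. Error"])
      } else {
        NA_real_
      }
    } else {
      slope <- NA_real_
      se <- NA_real_
    }
    tibble::tibble(n_years = nrow(g), mean_temp = mean(g$temp),
                   slope_c_per_year = slope, slope_se = se)
  }))
}
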