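# Observation table, thermal-habitat models, pooled and regional location
# models, shift predictions, drift recovery.

# Hand-built observation tables with exact structure.
make_obs <- function(n_years = 12, species = c("A", "B"), regions = "NW",
                     lat_fun = function(sp, temp_e, sa_y, year) 65,
                     temp_e = NULL, seed = 1) {
  years <- seq(2000, length.out = n_years)
  temp_e <- temp_e %||% (4 + 0.8 * sin(seq(0, 3, length.out = n_years)))
  set.seed(seed)
  rows <- expand.grid(species_id = species, year = years, rep = 1:8,
                      region = regions, stringsAsFactors = FALSE)
  te <- temp_e[match(rows$year, years)]
  sa <- rep(1, nrow(rows))
  lat <- mapply(lat_fun, rows$species_id, te, sa, rows$year)
  tibble::tibble(
    species_id = rows$species_id,
    tow_id = paste0("T", seq_len(nrow(rows))),
    station_id = paste0("S", rows$rep),
    region = rows$region,
    year = rows$year,
    lat = lat,
    lon = -22 - 0.3 * (rows$rep - 4) / 4,
    depth_m = 200 + 40 * rows$rep,
    bottom_temp_c = 4 + 0.2 * rows$rep,
    weight = 1,
    temp_e = te,
    sa_y = sa,
    has_temp = TRUE
  )
}

test_that("the observation table keeps one row per positive catch", {
  tows <- toy_tows(tibble::tibble(
    tow_id = c("T1", "T2"), year = c(2000L, 2000L),
    bottom_temp_c = c(5, NA)
  ))
  std <- tibble::tibble(
    tow_id = c("T1", "T1", "T2"),
    species_id = c("A", "B", "A"),
    count = c(3L, 0L, 5L),
    cpue_nmi = c(1, 0, 5 / 3)
  )
  temp_e <- tibble::tibble(year = 2000L, temp_e = 4.2)
  sa_y <- tibble::tibble(species_id = c("A", "A", "B"),
                         year = 2000L, SA_y = 1)
  obs <- build_observations(std, tows, temp_e, sa_y[-2, ])
  expect_equal(nrow(obs), 2) # zero catch dropped
  expect_equal(obs$has_temp, c(TRUE, FALSE))
  expect_equal(obs$temp_e, c(4.2, 4.2))
  # a species without SA_y is an error
  expect_error(
    build_observations(std, tows, temp_e,
                       sa_y[sa_y$species_id == "B", ]),
    "missing SA_y"
  )
})

test_that("observation row count equals positive catches on a fixture", {
  fx <- tiny_fixture()
  ch <- shift_chain(fx, min_years = 4)
  idx <- match(ch$std$tow_id, fx$tows$tow_id)
  want <- sum(ch$std$cpue_nmi > 0 & ch$std$species_id %in% ch$core &
                fx$tows$year[idx] %in% ch$temp_e$year)
  expect_equal(nrow(ch$obs), want)
})

test_that("degenerate thermal-habitat fits are handled", {
  obs <- make_obs(species = "A")
  obs$bottom_temp_c <- 6.5 # constant temperature
  fit <- fit_thermal_habitat(obs, "species")
  expect_equal(unname(coef(fit$fit)[1]), 6.5)
  expect_equal(fit$r_squared, 0)
})

test_that("species effects equal their thermal offsets in a noiseless fit", {
  obs <- make_obs(species = c("A", "B", "C"))
  off <- c(A = 0, B = 1.5, C = -2)
  obs$bottom_temp_c <- 5 + off[obs$species_id]
  fit <- fit_thermal_habitat(obs, "species")
  b <- coef(fit$fit)
  expect_equal(unname(b["speciesB"]), 1.5, tolerance = 1e-9)
  expect_equal(unname(b["speciesC"]), -2, tolerance = 1e-9)
  expect_gt(fit$r_squared, 0.999)
})

test_that("temperature-at-capture tracks Temp_e better than year when the anomaly is non-monotonic", {
  # capture temperature follows the (non-monotonic) environmental anomaly
  obs <- make_obs(species = c("A", "B"), n_years = 16)
  set.seed(8)
  obs$bottom_temp_c <- obs$temp_e + c(A = 0, B = -1)[obs$species_id] +
    rnorm(nrow(obs), 0, 0.2)
  cmp <- compare_thermal_habitat(obs, c("species", "year", "tempe_depth"))
  aic <- setNames(cmp$aic, cmp$variant)
  expect_lt(aic[["tempe_depth"]], aic[["year"]])
})

test_that("the residual-abundance screen is calibrated and detects coupling", {
  # null: residuals independent of SA_y
  set.seed(9)
  n_sim <- 150
  hits <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    obs <- make_obs(species = "A", seed = i)
    obs$sa_y <- rep(exp(rnorm(12, 0, 0.4)), each = 8)
    obs$bottom_temp_c <- 5 + rnorm(nrow(obs), 0, 0.5)
    scr <- residual_abundance_screen(obs)
    hits[i] <- scr$significant[1]
  }
  expect_gt(mean(hits), 0.005)
  expect_lt(mean(hits), 0.12)

  # injected negative coupling is found with a negative slope
  obs <- make_obs(species = "A", n_years = 18)
  set.seed(10)
  obs$sa_y <- rep(exp(rnorm(18, 0, 0.5)), each = 8)
  obs$bottom_temp_c <- 5 - 0.8 * obs$sa_y + rnorm(nrow(obs), 0, 0.1)
  scr <- residual_abundance_screen(obs)
  expect_true(scr$significant[1])
  expect_lt(scr$slope[1], 0)

  # single-year species are skipped
  obs1 <- make_obs(species = "A", n_years = 1)
  expect_warning(scr1 <- residual_abundance_screen(obs1), "skipped")
  expect_true(is.na(scr1$slope[1]))
})

test_that("the pooled location model recovers exact per-species trends", {
  obs <- make_obs(species = c("A", "B"), n_years = 10)
  obs$lat <- ifelse(obs$species_id == "A",
                    65 + 0.01 * (obs$year - 2000), 64)
  fit <- fit_location_model(obs, covariate = "year", interactions = TRUE)
  sl <- fit$per_species_slopes$lat
  expect_equal(sl$slope_x[sl$species_id == "A"], 0.01, tolerance = 1e-9)
  expect_equal(sl$slope_x[sl$species_id == "B"], 0, tolerance = 1e-9)
  # stationary input: main-effect slopes are zero without interactions
  obs$lat <- 65
  fit0 <- fit_location_model(obs, covariate = "temp_e",
                             interactions = FALSE)
  expect_equal(fit0$main_slopes$lat$x[1], 0, tolerance = 1e-9)
})

test_that("a temperature-tracking species is caught by the regional model", {
  obs <- make_obs(species = "A", n_years = 16)
  set.seed(11)
  obs$lat <- 66 + 0.1 * obs$temp_e + rnorm(nrow(obs), 0, 0.05)
  rf <- fit_regional_model(obs)
  expect_lt(rf$per_response$lat$p_temp, 0.01)
  sl <- rf$per_response$lat$temp_slopes
  expect_equal(sl$slope[1], 0.1, tolerance = 0.05)
})

test_that("opposite regional drifts produce opposite regional slopes", {
  obs <- dplyr::bind_rows(
    make_obs(species = "A", regions = "NW", n_years = 16, seed = 2),
    make_obs(species = "A", regions = "SE", n_years = 16, seed = 3)
  )
  set.seed(12)
  drift <- ifelse(obs$region == "NW", 0.12, -0.12)
  obs$lat <- ifelse(obs$region == "NW", 66, 63.8) +
    drift * obs$temp_e + rnorm(nrow(obs), 0, 0.05)
  rf <- fit_regional_model(obs)
  sl <- rf$per_response$lat$temp_slopes
  expect_lt(abs(sl$slope[sl$region == "NW"] - 0.12), 0.05)
  expect_lt(abs(sl$slope[sl$region == "SE"] + 0.12), 0.05)
  expect_lt(rf$per_response$lat$p_temp, 0.01)
  # the interaction variant fits better than main effects only
  aic <- rf$aic
  expect_lt(aic$aic_full[aic$response == "lat"],
            aic$aic_main[aic$response == "lat"])
})

test_that("sparse regions are dropped and single-region species reduce", {
  obs <- make_obs(species = "A", regions = "NW", n_years = 12)
  stray <- obs[1:3, ]
  stray$region <- "SE"
  expect_warning(rf <- fit_regional_model(dplyr::bind_rows(obs, stray)),
                 "dropping region")
  expect_equal(rf$regions, "NW")
  expect_null(rf$fits$lat$xlevels$region)
})

test_that("predicted shifts are the regional slopes, linear in the perturbation", {
  obs <- make_obs(species = "A", n_years = 16)
  obs$lat <- 66 + 0.074 * obs$temp_e # exact, noise-free
  rf <- fit_regional_model(obs)
  pred <- suppressWarnings(predict_shift(rf))
  expect_equal(pred$dlat_per_c, 0.074, tolerance = 1e-8)
  expect_equal(pred$distance_km_temp, 8.2, tolerance = 0.1)
  expect_equal(pred$bearing_deg_temp, 0, tolerance = 0.5)
  # linearity: a +2 degC shift is twice the +1 degC shift by construction
  expect_equal(2 * pred$dlat_per_c, 0.148, tolerance = 1e-8)

  # all-zero temperature structure gives zero predicted shift
  obs0 <- make_obs(species = "A", n_years = 16)
  obs0$lat <- 65
  pred0 <- suppressWarnings(predict_shift(fit_regional_model(obs0)))
  expect_equal(pred0$dlat_per_c, 0, tolerance = 1e-9)
  expect_equal(pred0$distance_km_temp, 0, tolerance = 1e-6)
})

test_that("the three responses share the design but fit independently", {
  obs <- make_obs(species = "A", n_years = 14)
  set.seed(13)
  obs$lat <- 66 + rnorm(nrow(obs), 0, 0.1)
  obs$lon <- -22 + rnorm(nrow(obs), 0, 0.2)
  obs$depth_m <- 300 + rnorm(nrow(obs), 0, 30)
  rf <- fit_regional_model(obs)
  for (r in c("lat", "lon", "depth")) {
    resp <- c(lat = "lat", lon = "lon", depth = "depth_m")[[r]]
    solo <- lm(stats::reformulate(c("temp_e", "sa_y"), response = resp),
               data = obs, weights = obs$weight)
    expect_equal(unname(coef(rf$fits[[r]])), unname(coef(solo)),
                 tolerance = 1e-9)
  }
})

test_that("injected whole-range drift is recovered by the year-level estimator", {
  run <- drift_run(301, 20)
  rec <- run$recovery
  expect_gt(mean(rec$detected), 0.7)
  expect_equal(median(rec$km_per_c), 20, tolerance = 0.25)
  # zero-drift null triggers rarely
  run0 <- drift_run(302, 0)
  expect_lt(mean(run0$recovery$detected), 0.2)
})
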