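# Synthetic survey generator: determinism, geometry, temperature field,
# catch simulation, fixtures.

test_that("station grids are deterministic, bounded and quota-aware", {
  a <- generate_stations(245, seed = 1)
  b <- generate_stations(245, seed = 1)
  expect_identical(a, b)
  expect_true(all(a$depth_m >= 26 & a$depth_m <= 1203))
  expect_setequal(unique(a$region), c("NW", "NE", "SW", "SE"))

  q <- generate_stations(8, seed = 2,
                         quota = c(NW = 2, NE = 2, SW = 2, SE = 2))
  expect_equal(as.vector(table(q$region)[c("NW", "NE", "SW", "SE")]),
               rep(2L, 4))
  expect_error(generate_stations(8, seed = 2, quota = c(NW = 4)),
               "sum to n_stations")
  expect_error(generate_stations(8, seed = 2,
                                 quota = c(XX = 4, NW = 4)),
               "quota names")
})

test_that("station depth increases with distance from the coastline proxy", {
  st <- generate_stations(245, seed = 3)
  cfg <- station_config()
  dy <- (st$lat - cfg$center_lat) * 111.2
  dx <- (st$lon - cfg$center_lon) * 111.2 * cos(cfg$center_lat * pi / 180)
  r <- sqrt(dx^2 + dy^2)
  expect_gt(cor(r, st$depth_m, method = "spearman"), 0.99)
})

test_that("temperature field is exact in the noiseless limit and additive in the anomaly", {
  st <- generate_stations(30, seed = 4)
  years <- 1996:1998
  cl0 <- climate_spec(years, anomaly = c(0, 0.5, 1), noise_sd = 0,
                      missing_frac = 0)
  tows <- generate_tows(st, cl0, seed = 5)
  tows$doy <- cl0$mean_doy # doy at its reference: no DOY term
  temps <- generate_temperatures(tows, st, cl0, seed = 6)
  clim <- temps[tows$year == 1996]
  expect_equal(temps[tows$year == 1997], clim + 0.5, tolerance = 1e-12)
  expect_equal(temps[tows$year == 1998], clim + 1.0, tolerance = 1e-12)
  # and the 1996 values are exactly the regional profile at station depth
  idx <- match(tows$station_id[tows$year == 1996], st$station_id)
  prof <- sapply(seq_along(idx), function(i) {
    p <- cl0$profiles[[st$region[idx[i]]]]
    approx(p$depth, p$temp, xout = st$depth_m[idx[i]], rule = 2)$y
  })
  expect_equal(clim, prof, tolerance = 1e-12)
})

test_that("southern water is warmer than northern water at 500 m", {
  prof <- default_depth_profiles()
  at500 <- sapply(prof, function(p) approx(p$depth, p$temp, 500)$y)
  expect_gt(at500[["SW"]] - at500[["NE"]], 4)
  expect_gt(at500[["SE"]] - at500[["NW"]], 1)
})

test_that("a dominant species in the Poisson limit peaks at its best station", {
  st <- generate_stations(40, seed = 8)
  cl <- climate_spec(1996:1997, anomaly = c(0, 0), noise_sd = 0,
                     missing_frac = 0)
  clim <- profile_temp(st$region, st$depth_m, cl$profiles)
  target <- 12 # index of the station the niche is centred on
  sp <- tibble::tibble(
    species_id = "ONE", thermal_optimum_c = clim[target], niche_sd_c = 0.4,
    depth_pref_m = st$depth_m[target], depth_sd_m = 80,
    lat_center = st$lat[target], lon_center = st$lon[target],
    lat_sd = 0.4, lon_sd = 0.6, base_abundance = 1e5, abundance_trend = 1,
    abundance_year_sd = 0, drift_km_per_c = 0, drift_bearing_deg = 0,
    overdispersion = Inf, arrival_year = NA_integer_
  )
  tows <- generate_tows(st, cl, seed = 9)
  catches <- simulate_catches(tows, st, sp, cl, seed = 10)
  std <- standardize_catches(catches, tows)
  idx <- match(std$tow_id, tows$tow_id)
  by_station <- tapply(std$count, tows$station_id[idx], sum)
  expect_equal(names(which.max(by_station)), st$station_id[target])
})

test_that("zero-drift species have no temporal trend in their true centroid", {
  sc <- drift_scenario(seed = 11, drift_km_per_c = 0, n_species = 6,
                       n_stations = 150)
  std <- standardize_catches(sc$catches, sc$tows)
  cen <- annual_centroids(std, sc$tows)
  slopes <- sapply(split(cen, cen$species_id), function(g) {
    f <- lm(lat_c ~ year, data = g)
    summary(f)$coefficients["year", 3] # t statistic
  })
  # stationary construction: no systematic trend (|t| mostly < 3)
  expect_lt(mean(abs(slopes) > 3), 0.5)
})

test_that("a thermal offset of +2 degC is recovered as TB of about +2", {
  st <- generate_stations(245, seed = 12)
  cl <- climate_spec(noise_sd = 0.3)
  clim <- profile_temp(st$region, st$depth_m, cl$profiles)
  env_med <- median(clim)
  sp <- tibble::tibble(
    species_id = "OFF2", thermal_optimum_c = env_med + 2, niche_sd_c = 1,
    depth_pref_m = 250, depth_sd_m = 400,
    lat_center = 65, lon_center = -18.8, lat_sd = 3, lon_sd = 6,
    base_abundance = 2e4, abundance_trend = 1, abundance_year_sd = 0,
    drift_km_per_c = 0, drift_bearing_deg = 0, overdispersion = 5,
    arrival_year = NA_integer_
  )
  tows <- generate_tows(st, cl, seed = 13)
  catches <- simulate_catches(tows, st, sp, cl, seed = 14)
  std <- standardize_catches(catches, tows)
  aff <- thermal_affinity(std, tows)
  expect_equal(aff$TB[aff$species_id == "OFF2"], 2, tolerance = 0.3)
})

test_that("narrow thermal niches realize smaller Steno than wide ones", {
  st <- generate_stations(245, seed = 15)
  cl <- climate_spec(noise_sd = 0.3)
  clim <- profile_temp(st$region, st$depth_m, cl$profiles)
  env_med <- median(clim)
  mk <- function(id, sd) {
    tibble::tibble(
      species_id = id, thermal_optimum_c = env_med + 0.5, niche_sd_c = sd,
      depth_pref_m = 250, depth_sd_m = 400, lat_center = 65,
      lon_center = -18.8, lat_sd = 3, lon_sd = 6, base_abundance = 2e4,
      abundance_trend = 1, abundance_year_sd = 0, drift_km_per_c = 0,
      drift_bearing_deg = 0, overdispersion = 5, arrival_year = NA_integer_
    )
  }
  sp <- dplyr::bind_rows(mk("NARROW", 0.5), mk("WIDE", 3))
  tows <- generate_tows(st, cl, seed = 16)
  catches <- simulate_catches(tows, st, sp, cl, seed = 17)
  std <- standardize_catches(catches, tows)
  aff <- thermal_affinity(std, tows)
  expect_lt(aff$Steno[aff$species_id == "NARROW"],
            aff$Steno[aff$species_id == "WIDE"])
})

test_that("fixtures are byte-identical across regenerations", {
  d1 <- file.path(tempdir(), "fx1")
  d2 <- file.path(tempdir(), "fx2")
  make_fixture("tiny", seed = 7, dir = d1)
  make_fixture("tiny", seed = 7, dir = d2)
  for (f in c("tows.csv", "catches.csv", "stations.csv",
              "ground_truth.yaml")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  expect_error(make_fixture("bogus", seed = 1), "arg")
})

test_that("the paper-scale fixture has the survey's structure", {
  fx <- paper_fixture()
  expect_equal(nrow(fx$stations), 245)
  yrs <- sort(unique(fx$tows$year))
  expect_equal(length(yrs), 22) # 1996-2018 with 2011 missing
  expect_false(2011 %in% yrs)
  expect_equal(nrow(fx$tows), 245 * 22)
  expect_equal(nrow(fx$species), 80)
  # a few percent of tows lack temperature
  miss <- mean(is.na(fx$tows$bottom_temp_c))
  expect_gt(miss, 0.02)
  expect_lt(miss, 0.06)
  # realized thermal-bias estimates span the configured niche range
  std <- standardize_catches(fx$catches, fx$tows)
  aff <- suppressWarnings(thermal_affinity(std, fx$tows))
  expect_lt(min(aff$TB, na.rm = TRUE), -5)
  expect_gt(max(aff$TB, na.rm = TRUE), 2.5)
})

test_that("doubling base abundance doubles expected annual abundance", {
  st <- generate_stations(100, seed = 18)
  cl <- climate_spec(1996:1999, anomaly = rep(0, 4), noise_sd = 0.3)
  sp1 <- species_pool(st, 1, seed = 19, climate = cl,
                      base_log10_mean = 3.5, base_log10_sd = 0,
                      abundance_year_sd = 0, trend_log_sd = 0)
  sp2 <- sp1
  sp2$base_abundance <- 2 * sp1$base_abundance
  tows <- generate_tows(st, cl, seed = 20)
  a_of <- function(sp, s) {
    catches <- simulate_catches(tows, st, sp, cl, seed = s)
    std <- standardize_catches(catches, tows)
    mean(annual_abundance(std, tows)$A_y)
  }
  # average over a few seeds to tame sampling noise
  r1 <- mean(sapply(21:24, function(s) a_of(sp1, s)))
  r2 <- mean(sapply(21:24, function(s) a_of(sp2, s)))
  expect_equal(r2 / r1, 2, tolerance = 0.15)
})
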