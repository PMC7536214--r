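# Cross-species synthesis, orientation tests, matched pairs, functional
# predictors, new-arrival screen and the pipeline driver.

fake_predictions <- function(dlat_temp, dlat_ab = NULL, temp_sig = TRUE,
                             ab_sig = FALSE) {
  n <- length(dlat_temp)
  dlat_ab <- dlat_ab %||% rep(0, n)
  tibble::tibble(
    species_id = sprintf("SP%02d", seq_len(n)),
    region = "NW",
    n_obs = 100L,
    centroid_lat = 66, centroid_lon = -23,
    dlat_per_c = dlat_temp,
    dlon_per_c = 0,
    ddepth_per_c = 0,
    p_dlat_per_c = ifelse(rep(temp_sig, n), 0.01, 0.5),
    p_dlon_per_c = 0.5, p_ddepth_per_c = 0.5,
    distance_km_temp = abs(dlat_temp) * 111.2,
    bearing_deg_temp = ifelse(dlat_temp >= 0, 0, 180),
    dlat_per_doubling = dlat_ab,
    dlon_per_doubling = 0,
    ddepth_per_doubling = 0,
    p_dlat_per_doubling = ifelse(rep(ab_sig, n), 0.01, 0.5),
    p_dlon_per_doubling = 0.5, p_ddepth_per_doubling = 0.5,
    distance_km_abund = abs(dlat_ab) * 111.2,
    bearing_deg_abund = ifelse(dlat_ab >= 0, 0, 180),
    temp_significant = temp_sig,
    abundance_significant = ab_sig,
    temp_significant_species = temp_sig,
    abundance_significant_species = ab_sig,
    p_temp_lat_species = ifelse(rep(temp_sig, n), 0.01, 0.5),
    p_temp_lon_species = 0.5,
    p_temp_depth_species = 0.5
  )
}

test_that("the orientation test matches its exact null and extremes", {
  expect_equal(orientation_test(50, 100), 1)
  expect_lt(orientation_test(100, 100), 1e-10)
  p <- orientation_test(28, 51)
  pb <- binom.test(28, 51, 0.5)$p.value
  expect_lt(abs(p - pb), 0.15) # chi-squared vs exact binomial
  expect_gt(p, 0.1)
})

test_that("matched pairs compare temperature and abundance shifts", {
  pr <- fake_predictions(dlat_temp = c(0.34, 0.34), dlat_ab = c(0.1, 0.1),
                         temp_sig = TRUE, ab_sig = TRUE)
  mp <- matched_pair_comparison(pr)
  expect_equal(mp$ratio, 3.4, tolerance = 1e-9)
  expect_equal(mp$n_pairs, 2L)
  expect_equal(mp$prop_temp_greater, 1)
  # identical columns: ratio 1, ties excluded
  pr2 <- fake_predictions(c(0.2, 0.2), c(0.2, 0.2), TRUE, TRUE)
  mp2 <- matched_pair_comparison(pr2)
  expect_equal(mp2$ratio, 1)
  expect_true(is.na(mp2$prop_temp_greater))
  # no qualifying pairs
  pr3 <- fake_predictions(c(0.2, 0.2), ab_sig = FALSE)
  expect_warning(mp3 <- matched_pair_comparison(pr3), "no species/region")
  expect_equal(mp3$n_pairs, 0L)
})

test_that("the synthesis report aggregates proportions and tests", {
  pr <- fake_predictions(dlat_temp = seq(0.08, 0.12, length.out = 10))
  rep1 <- summarize_shifts(pr)
  expect_equal(rep1$prop_north_temp, 1)
  expect_equal(rep1$prop_temp_significant, 1)
  expect_lt(rep1$dlat_t_test_p, 0.01)
  # symmetric shifts: mean zero, orientation and t-test non-significant
  pr2 <- fake_predictions(dlat_temp = rep(c(0.12, -0.12), 10))
  rep2 <- summarize_shifts(pr2)
  expect_equal(rep2$mean_dlat_per_c, 0, tolerance = 1e-12)
  expect_gt(rep2$dlat_t_test_p, 0.9)
  expect_equal(rep2$orientation_p_temp, 1)
  expect_error(summarize_shifts(pr[0, ]), "empty")
  expect_output(print(rep1), "Cross-species")
})

test_that("the functional model isolates the driving trait", {
  set.seed(21)
  n_seeds <- 20
  steno_hit <- logical(n_seeds)
  others_hit <- numeric(n_seeds)
  for (i in seq_len(n_seeds)) {
    n <- 80
    d <- tibble::tibble(
      depth_class = factor(sample(c("shallow", "mid", "deep"), n, TRUE)),
      steno = runif(n, 1, 9),
      tb = runif(n, -5, 3),
      area_sr = sample(5:60, n, TRUE),
      a_r = 10^runif(n, 0, 3),
      region = sample(c("NW", "NE", "SW", "SE"), n, TRUE)
    )
    d$distance_km <- 5 + 9 * d$steno + rnorm(n, 0, 6)
    ff <- functional_predictor_model(d)
    ps <- setNames(ff$terms$p_value, ff$terms$term)
    steno_hit[i] <- ps[["steno"]] < 0.05
    others_hit[i] <- mean(ps[setdiff(names(ps), "steno")] < 0.05,
                          na.rm = TRUE)
  }
  expect_gte(mean(steno_hit), 0.9)
  expect_lt(mean(others_hit), 0.2)
})

test_that("constant distances produce no significant trait terms", {
  set.seed(22)
  n <- 60
  d <- tibble::tibble(
    depth_class = factor(sample(c("shallow", "mid", "deep"), n, TRUE)),
    steno = runif(n, 1, 9), tb = runif(n, -5, 3),
    area_sr = sample(5:60, n, TRUE), a_r = 10^runif(n, 0, 3),
    region = sample(c("NW", "NE", "SW", "SE"), n, TRUE),
    distance_km = 40 + rnorm(n, 0, 1e-6)
  )
  ff <- functional_predictor_model(d)
  expect_lt(sum(ff$terms$p_value < 0.05, na.rm = TRUE), 3)
})

test_that("non-drifting deep species depress the deep marginal effect", {
  set.seed(23)
  n <- 90
  d <- tibble::tibble(
    depth_class = factor(sample(c("shallow", "mid", "deep"), n, TRUE),
                         levels = c("shallow", "mid", "deep")),
    steno = runif(n, 1, 9), tb = runif(n, -5, 3),
    area_sr = sample(5:60, n, TRUE), a_r = 10^runif(n, 0, 3),
    region = sample(c("NW", "NE", "SW", "SE"), n, TRUE)
  )
  d$distance_km <- ifelse(d$depth_class == "deep", 8, 55) + rnorm(n, 0, 5)
  ff <- functional_predictor_model(d)
  me <- ff$marginal_effects$depth_class
  deep <- me$predicted_km[me$value == "deep"]
  shallow <- me$predicted_km[me$value == "shallow"]
  expect_lt(deep, shallow - 20)
})

test_that("the new-arrival screen finds late, increasing species", {
  years <- 1996:2017
  tows <- toy_tows(tibble::tibble(
    tow_id = paste0("T", years), year = years,
    bottom_temp_c = 6, depth_m = 350
  ))
  arrival <- lapply(2005:2017, function(y) {
    tibble::tibble(tow_id = paste0("T", y), species_id = "NEWCOMER",
                   count = (y - 2004) * 3L)
  })
  sporadic <- tibble::tibble(tow_id = paste0("T", c(2001, 2009, 2015)),
                             species_id = "SPORADIC", count = 1L)
  old <- tibble::tibble(tow_id = paste0("T", years), species_id = "OLD",
                        count = 5L)
  catches <- dplyr::bind_rows(c(arrival, list(sporadic, old)))
  std <- standardize_catches(catches, tows)
  hits <- new_arrival_screen(std, tows, first_year_cutoff = 1997,
                             min_years = 8)
  expect_equal(hits$species_id, "NEWCOMER")
  expect_equal(hits$first_year, 2005L)
  expect_equal(hits$n_years_present, 13L)
  expect_equal(hits$mean_temp_c, 6)
})

test_that("the generator's arrival_year seeds detectable newcomers", {
  fx <- tiny_fixture()
  st <- fx$stations
  cl <- climate_spec(years = 1996:2013,
                     anomaly = default_anomaly(1996:2013), noise_sd = 0.3)
  sp <- species_pool(st, 2, seed = 41, climate = cl,
                     base_log10_mean = 3, base_log10_sd = 0)
  sp$arrival_year[2] <- 2004L
  sp$abundance_trend[2] <- 1.25
  tows <- generate_tows(st, cl, seed = 42)
  catches <- simulate_catches(tows, st, sp, cl, seed = 43)
  std <- standardize_catches(catches, tows)
  expect_equal(min(tows$year[match(
    std$tow_id[std$species_id == sp$species_id[2]], tows$tow_id
  )]), 2004)
  hits <- new_arrival_screen(std, tows, first_year_cutoff = 1997,
                             min_years = 8)
  expect_true(sp$species_id[2] %in% hits$species_id)
  expect_false(sp$species_id[1] %in% hits$species_id)
})

test_that("the pipeline runs end-to-end and is deterministic", {
  d1 <- file.path(tempdir(), "pipe1")
  d2 <- file.path(tempdir(), "pipe2")
  res <- run_pipeline(list(preset = "tiny", seed = 7, outdir = d1))
  expect_true(all(file.exists(unlist(res$files))))
  sizes <- file.size(unlist(res$files))
  expect_true(all(sizes > 0))
  expect_s3_class(res$report, "shift_report")
  run_pipeline(list(preset = "tiny", seed = 7, outdir = d2))
  for (f in basename(unlist(res$files))) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # a bad stage aborts with the stage name
  expect_error(run_pipeline(list(outdir = tempfile())), "preset")
})
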