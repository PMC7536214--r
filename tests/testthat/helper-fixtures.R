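# Shared, lazily-built fixtures. Heavy simulations are cached in this
# environment so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

tiny_fixture <- function() {
  memo("tiny", make_fixture("tiny", seed = 7))
}

paper_fixture <- function() {
  memo("paper", make_fixture("paper_scale", seed = 1))
}

# Full analysis chain: standardized catches, core species, indices, Temp_e
# and the observation table, for any generated fixture.
shift_chain <- function(fx, min_years = 19) {
  std <- standardize_catches(fx$catches, fx$tows)
  core <- filter_core_species(fx$catches, fx$tows, min_years = min_years)
  a_y <- annual_abundance(std[std$species_id %in% core, ], fx$tows)
  sa <- standardized_abundance(a_y)
  te <- marginal_means(fit_temp_model(fx$tows))
  obs <- build_observations(std, fx$tows, te, sa, species = core)
  list(std = std, core = core, a_y = a_y, sa_y = sa, temp_e = te, obs = obs)
}

drift_run <- function(seed, drift, bearing = 0) {
  memo(sprintf("drift_%d_%s_%s", seed, drift, bearing), {
    sc <- drift_scenario(seed = seed, drift_km_per_c = drift,
                         bearing_deg = bearing)
    ch <- shift_chain(sc)
    list(scenario = sc, chain = ch, recovery = drift_recovery(ch$obs))
  })
}

# A small hand-built survey: n_tows tows over a few stations/years with
# direct control over every field, for unit tests that need exact numbers.
toy_tows <- function(df) {
  tibble::tibble(
    tow_id = df[["tow_id"]],
    station_id = df[["station_id"]] %||% df[["tow_id"]],
    year = df[["year"]] %||% 2000L,
    doy = df[["doy"]] %||% 280L,
    lat = df[["lat"]] %||% 64.5,
    lon = df[["lon"]] %||% -22,
    depth_m = df[["depth_m"]] %||% 200,
    bottom_temp_c = df[["bottom_temp_c"]] %||% 5,
    tow_length_nmi = df[["tow_length_nmi"]] %||% 3
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
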