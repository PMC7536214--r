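# End-to-end driver: data (or synthetic preset) -> indices -> Temp_e ->
# centroids -> models -> synthesis, with all outputs written as tidy CSVs
# plus a plain-text report.

#' Read a pipeline configuration file
#'
#' YAML key/value file naming input paths, thresholds and options; any key
#' accepted by [run_pipeline()] can appear.
#'
#' @param path YAML file path.
#' @return named list.
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

#' Run the full distribution-shift pipeline
#'
#' Executes every stage in order and writes tidy CSV outputs plus a
#' plain-text report to `outdir`. Inputs are either tow/catch CSV paths or a
#' synthetic preset. The run is deterministic given `seed`.
#'
#' @param config named list (or YAML path) with elements:
#'   \describe{
#'     \item{tows, catches}{input CSV paths (omit when using a preset)}
#'     \item{preset}{`"tiny"` or `"paper_scale"` synthetic preset}
#'     \item{seed}{RNG seed for synthetic data (default 1)}
#'     \item{outdir}{output directory (required)}
#'     \item{alpha}{significance level (default 0.05)}
#'     \item{min_years}{core-species year threshold; defaults to 19/22 of
#'       the observed span}
#'     \item{min_region_n}{regional-model row threshold (default 10)}
#'     \item{arrival_cutoff, arrival_min_years}{new-arrival screen options}
#'   }
#' @return invisibly, a list with every intermediate object and the output
#'   file paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_config(config)
  }
  outdir <- config$outdir
  if (is.null(outdir)) stop("config$outdir is required")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  alpha <- config$alpha %||% 0.05
  seed <- config$seed %||% 1L

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  truth <- NULL
  if (!is.null(config$preset)) {
    fx <- stage("synthetic data", make_fixture(config$preset, seed = seed))
    tows <- fx$tows
    catches <- fx$catches
    truth <- fx$species
    write_tows(tows, file.path(outdir, "tows.csv"))
    write_catches(catches, file.path(outdir, "catches.csv"))
  } else {
    if (is.null(config$tows) || is.null(config$catches)) {
      stop("config must name either a preset or tows+catches input files")
    }
    tows <- stage("read tows", suppressWarnings(read_tows(config$tows)))
    catches <- stage("read catches", read_catches(config$catches))
  }

  n_years <- length(unique(tows$year))
  min_years <- config$min_years %||% max(2L, round(n_years * 19 / 22))

  std <- stage("standardize", standardize_catches(catches, tows))
  core <- stage("core species",
                filter_core_species(catches, tows, min_years = min_years))
  if (length(core) == 0L) stop("no core species at min_years threshold")
  std_core <- std[std$species_id %in% core, ]

  a_y <- stage("indices", annual_abundance(std_core, tows))
  sa_y <- standardized_abundance(a_y)
  abund <- abundance_summary(std_core, tows)
  aff <- suppressWarnings(thermal_affinity(std_core, tows))
  cov <- spatial_coverage(std_core, tows)

  tm <- stage("environmental temperature", fit_temp_model(tows))
  temp_e <- marginal_means(tm)
  warming <- warming_rate(temp_e)
  profiles <- depth_profile(tows)

  cent <- stage("centroids", annual_centroids(std_core, tows))
  trends <- suppressWarnings(centroid_trend(cent, alpha = alpha))
  rose <- rose_table(trends, aff)

  obs <- stage("observations",
               build_observations(std_core, tows, temp_e, sa_y))
  regional <- stage("regional models", suppressWarnings(
    fit_regional_models(obs, alpha = alpha,
                        min_region_n = config$min_region_n %||% 10)
  ))
  report <- stage("synthesis",
                  summarize_shifts(regional$predictions, aff, cov,
                                   alpha = alpha))
  arrivals <- stage("new arrivals", suppressWarnings(new_arrival_screen(
    std, tows,
    first_year_cutoff = config$arrival_cutoff %||%
      (min(tows$year) + 1L),
    min_years = config$arrival_min_years %||% 8
  )))

  files <- list(
    a_y = file.path(outdir, "annual_abundance.csv"),
    sa_y = file.path(outdir, "standardized_abundance.csv"),
    affinity = file.path(outdir, "thermal_affinity.csv"),
    coverage = file.path(outdir, "spatial_coverage.csv"),
    temp_e = file.path(outdir, "temp_e.csv"),
    profiles = file.path(outdir, "depth_profiles.csv"),
    centroids = file.path(outdir, "centroids.csv"),
    trends = file.path(outdir, "shift_vectors.csv"),
    rose = file.path(outdir, "rose_table.csv"),
    predictions = file.path(outdir, "shift_predictions.csv"),
    arrivals = file.path(outdir, "new_arrivals.csv"),
    report = file.path(outdir, "report.txt")
  )
  write.csv(a_y, files$a_y, row.names = FALSE)
  write.csv(sa_y, files$sa_y, row.names = FALSE)
  write.csv(aff, files$affinity, row.names = FALSE)
  write.csv(cov, files$coverage, row.names = FALSE)
  write.csv(temp_e, files$temp_e, row.names = FALSE)
  write.csv(profiles, files$profiles, row.names = FALSE)
  write.csv(cent, files$centroids, row.names = FALSE)
  write.csv(trends, files$trends, row.names = FALSE)
  write.csv(rose, files$rose, row.names = FALSE)
  write.csv(regional$predictions, files$predictions, row.names = FALSE)
  write.csv(arrivals, files$arrivals, row.names = FALSE)

  con <- file(files$report, open = "wt")
  on.exit(close(con), add = TRUE)
  wl <- function(...) writeLines(sprintf(...), con)
  wl("Distribution-shift pipeline report")
  wl("seed: %s   alpha: %.3f   min_years: %d", as.character(seed), alpha,
     min_years)
  wl("tows: %d   years: %d   species (core/total): %d/%d", nrow(tows),
     n_years, length(core), length(unique(catches$species_id)))
  wl("")
  wl("Environmental temperature: net change %.3f degC over %d-%d (slope %.4f degC/yr, SE %.4f)",
     warming$net_change_c, warming$first_year, warming$last_year,
     warming$slope_c_per_year, warming$slope_se)
  wl("DOY slope: %.4f degC/day => 10-day timing difference ~ %.3f degC",
     tm$doy_slope, doy_effect(tm, 10))
  wl("")
  wl("Thermal affinity: mean TB %.2f (range %.2f to %.2f); mean Steno %.2f (range %.2f to %.2f)",
     mean(aff$TB, na.rm = TRUE), min(aff$TB, na.rm = TRUE),
     max(aff$TB, na.rm = TRUE), mean(aff$Steno, na.rm = TRUE),
     min(aff$Steno, na.rm = TRUE), max(aff$Steno, na.rm = TRUE))
  wl("Centroid trends: %d of %d species significant in lat or lon (no multiplicity correction; %d tests)",
     sum(trends$significant, na.rm = TRUE), nrow(trends),
     attr(trends, "n_tested"))
  wl("")
  txt <- utils::capture.output(print(report))
  writeLines(txt, con)
  if (nrow(arrivals) > 0) {
    wl("")
    wl("New arrivals (first year > cutoff, increasing): %d species",
       nrow(arrivals))
  }
  if (!is.null(truth)) {
    est <- aff[match(truth$species_id, aff$species_id), ]
    ok <- !is.na(est$TB)
    if (sum(ok) >= 3) {
      rho <- suppressWarnings(
        cor(truth$tb_true[ok], est$TB[ok], method = "spearman")
      )
      wl("")
      wl("Ground-truth recovery: Spearman rho(TB_est, TB_true) = %.3f over %d species",
         rho, sum(ok))
    }
  }

  invisible(list(
    tows = tows, catches = catches, std = std, core = core, a_y = a_y,
    sa_y = sa_y, abundance = abund, affinity = aff, coverage = cov,
    temp_model = tm, temp_e = temp_e, warming = warming,
    centroids = cent, trends = trends, rose = rose, observations = obs,
    regional = regional, report = report, arrivals = arrivals,
    files = files, truth = truth
  ))
}
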