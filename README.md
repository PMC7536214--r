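# trawlshift

Quantifies three-dimensional (latitude, longitude, depth) distribution
shifts of fish species sampled by a standardized groundfish trawl survey,
and separates warming-driven shifts from abundance-driven ones. It is aimed
at quantitative marine ecologists working with fixed-station survey time
series: the kind of data where ~245 stations are trawled every autumn for
two decades and each tow yields a location, a depth, a bottom temperature
and a count of every species caught.

## What it computes

* **Catch standardization and abundance indices.** Counts become fish per
  nautical mile towed (CPUE). Per species: annual abundance
  `A_y = Σ_tows CPUE`, its non-zero-year mean `A_s`, regional totals `A_r`,
  and the unit-mean standardized series `SA_y = A_y / mean_y(A_y)` used as
  the within-species abundance covariate.
* **Thermal affinity indices.** Thermal bias
  `TB = median_w(T_catch) − median(T_env)` (catch-weighted median
  temperature-at-capture minus the environment's median; positive =
  warmwater species) and the stenothermy index
  `Steno = P95_w(T_catch) − P5_w(T_catch)` (small = narrow thermal
  tolerance), with the standard class bins (warm/cool/coldwater, four
  2.5 °C stenothermy bins, depth classes at 300/800 m).
* **Environmental temperature index.** `Temp_e`: per-year estimated
  marginal means of `temp ~ station + year + doy` (sum-to-zero contrasts),
  which removes station-coverage and survey-timing artefacts from the
  warming signal.
* **Centroid kinematics.** Abundance-weighted annual centres of mass,
  OLS trends on year, fitted first/last-year endpoints, geodesic distance
  and initial bearing between them (WGS84), and rose-plot tables for the
  species with significant latitude/longitude trends.
* **Location-model battery.** Pooled per-response least squares of
  (lat, lon, depth) on species × (year | `Temp_e`) × `SA_y`, and a
  spatially-structured per-species model with region × covariate
  interactions. From the latter: predicted shifts per +1 °C and per
  doubling of `SA_y`, with heteroscedasticity-robust significance.
* **Synthesis.** Proportions of temperature- and abundance-responsive
  species, mean latitudinal shift per +1 °C with a t-test against zero,
  chi-squared orientation tests (north vs south against 50:50), a
  matched-pair temperature/abundance shift ratio, a functional-trait model
  of shift distance, and a screen for newly arrived species.
* **Synthetic survey generator.** Fixed station grid around a central land
  mass, regional depth–temperature profiles with annual anomalies, species
  with Gaussian thermal niches and negative-binomial catches, and
  configurable warming-driven centroid drift — so every estimator above is
  verified by parameter recovery against known ground truth.

## Worked example

```r
library(trawlshift)
run_pipeline(list(preset = "paper_scale", seed = 1, outdir = "out"))
```

generates a full synthetic survey (245 stations × 22 survey years × 80
species), runs every stage, writes tidy CSVs plus `out/report.txt`, and
prints:

```
Distribution-shift pipeline report
seed: 1   alpha: 0.050   min_years: 19
tows: 5390   years: 22   species (core/total): 74/79

Environmental temperature: net change 0.465 degC over 1996-2018 (slope 0.0211 degC/yr, SE 0.0067)
DOY slope: -0.0021 degC/day => 10-day timing difference ~ 0.021 degC

Thermal affinity: mean TB -1.33 (range -5.64 to 3.18); mean Steno 2.79 (range 1.81 to 5.18)
Centroid trends: 5 of 74 species significant in lat or lon (no multiplicity correction; 148 tests)

Cross-species distribution shift synthesis
  species analysed: 74 (190 species x region combinations)
  temperature-responsive species: 4%; abundance: 4%
  mean shift per +1 degC: 0.284 deg lat (SE 0.087; ~31.5 km; t-test p = 0.00834)
  northward under warming: 91% of 11 combos (orientation p = 0.00666)
  ...
Ground-truth recovery: Spearman rho(TB_est, TB_true) = 0.991 over 74 species
```

Reading it: 74 of 80 simulated species clear the 19-of-22-years inclusion
rule; the recovered environmental warming is the generator's injected
anomaly trend; the default pool injects *no* drift, so few species show
temperature responses (the ~4–8% that do are the calibrated false-trigger
rate of the significance gate), and the estimated thermal-bias indices
rank-match the true thermal optima at ρ = 0.99. Inject drift — e.g.
`drift_scenario(seed = 1, drift_km_per_c = 20)` — and the same chain
detects ~92% of species with a recovered magnitude close to 20 km/°C and
northward bearings.

A shell wrapper for the same pipeline is in
`inst/scripts/run_survey_shift.R`.

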