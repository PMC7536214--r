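# Cross-species synthesis: significant-species proportions, mean latitudinal
# shifts and orientation tests, matched-pair temperature-vs-abundance
# comparison, functional-trait model of shift distance, and a new-arrival
# screen for late-appearing species.

#' Chi-squared orientation test against a 50:50 split
#'
#' One-degree-of-freedom chi-squared test (no continuity correction) of
#' whether the number of northward-moving species differs from half: small
#' p = oriented movement, large p = consistent with random orientation.
#'
#' @param n_north number moving north.
#' @param n_total total number.
#' @return two-sided p-value.
#' @examples
#' orientation_test(50, 100) # 1
#' @export
orientation_test <- function(n_north, n_total) {
  stopifnot(n_total >= 1, n_north >= 0, n_north <= n_total)
  suppressWarnings(
    chisq.test(c(n_north, n_total - n_north), p = c(0.5, 0.5),
               correct = FALSE)$p.value
  )
}

#' Matched-pair comparison of temperature and abundance shifts
#'
#' Restricted to species x region combinations where both the Temp_e and the
#' SA_y effects are significant, compares the predicted latitudinal shift
#' for +1 degC against that for an abundance doubling: the ratio of mean
#' shifts (ratio of means, robust to near-zero single pairs) and the
#' proportion of pairs where the temperature shift exceeds the abundance
#' shift (ties excluded).
#'
#' @param predictions prediction tibble from [fit_regional_models()].
#' @return list `ratio, prop_temp_greater, n_pairs, mean_dlat_temp,
#'   mean_dlat_abund`; empty input yields `n_pairs = 0` with a warning.
#' @export
matched_pair_comparison <- function(predictions) {
  pairs <- predictions[predictions$temp_significant &
                         predictions$abundance_significant, , drop = FALSE]
  if (nrow(pairs) == 0L) {
    warning("no species/region pairs with both effects significant",
            call. = FALSE)
    return(list(ratio = NA_real_, prop_temp_greater = NA_real_, n_pairs = 0L,
                mean_dlat_temp = NA_real_, mean_dlat_abund = NA_real_))
  }
  m_t <- mean(pairs$dlat_per_c)
  m_a <- mean(pairs$dlat_per_doubling)
  ratio <- if (m_a == 0) {
    warning("zero mean abundance shift; ratio is infinite", call. = FALSE)
    Inf
  } else {
    m_t / m_a
  }
  not_tie <- pairs$dlat_per_c != pairs$dlat_per_doubling
  prop <- if (any(not_tie)) {
    mean(pairs$dlat_per_c[not_tie] > pairs$dlat_per_doubling[not_tie])
  } else {
    NA_real_
  }
  list(ratio = ratio, prop_temp_greater = prop, n_pairs = nrow(pairs),
       mean_dlat_temp = m_t, mean_dlat_abund = m_a)
}

#' Cross-species synthesis of predicted shifts
#'
#' Aggregates the per species x region shift predictions into the headline
#' summary: proportions of species with significant temperature and
#' abundance effects, the mean predicted latitudinal shift per +1 degC with
#' its SE and a one-sample t-test against zero, proportions moving
#' northward under each perturbation with chi-squared orientation tests,
#' the matched-pair comparison, and (optionally) breakdowns by thermal and
#' depth class.
#'
#' @param predictions prediction tibble from [fit_regional_models()].
#' @param affinity optional [thermal_affinity()] table for class breakdowns.
#' @param coverage optional [spatial_coverage()] table.
#' @param alpha significance level used in the flags (reported only).
#' @return list of class `shift_report`.
#' @export
summarize_shifts <- function(predictions, affinity = NULL, coverage = NULL,
                             alpha = 0.05) {
  if (is.null(predictions) || nrow(predictions) == 0L) {
    stop("empty prediction table")
  }
  by_sp <- dplyr::distinct(predictions, species_id, temp_significant_species,
                           abundance_significant_species)
  sig_t <- predictions[predictions$temp_significant, , drop = FALSE]
  sig_a <- predictions[predictions$abundance_significant, , drop = FALSE]

  mean_dlat <- if (nrow(sig_t)) mean(sig_t$dlat_per_c) else NA_real_
  se_dlat <- if (nrow(sig_t) > 1) {
    sd(sig_t$dlat_per_c) / sqrt(nrow(sig_t))
  } else {
    NA_real_
  }
  safe_t <- function(x) {
    if (length(x) > 1 && sd(x) > 0) t.test(x)$p.value else NA_real_
  }
  t_p <- safe_t(sig_t$dlat_per_c)
  mean_ddepth <- if (nrow(sig_t)) mean(sig_t$ddepth_per_c) else NA_real_
  depth_t_p <- safe_t(sig_t$ddepth_per_c)

  n_north_t <- sum(sig_t$dlat_per_c > 0)
  n_north_a <- sum(sig_a$dlat_per_doubling > 0)

  mean_dlat_a <- if (nrow(sig_a)) mean(sig_a$dlat_per_doubling) else NA_real_
  t_p_a <- safe_t(sig_a$dlat_per_doubling)

  breakdown <- NULL
  if (!is.null(affinity)) {
    d <- dplyr::left_join(
      sig_t,
      affinity[, c("species_id", "tb_class", "steno_bin", "depth_class")],
      by = "species_id"
    )
    breakdown <- lapply(c("tb_class", "steno_bin", "depth_class"),
                        function(cl) {
      dplyr::summarise(
        dplyr::group_by(d, !!rlang_sym(cl)),
        n = dplyr::n(),
        mean_distance_km = mean(distance_km_temp),
        prop_north = mean(dlat_per_c > 0),
        .groups = "drop"
      )
    })
    names(breakdown) <- c("tb_class", "steno_bin", "depth_class")
  }

  structure(
    list(
      n_species = nrow(by_sp),
      n_combinations = nrow(predictions),
      alpha = alpha,
      prop_temp_significant = mean(by_sp$temp_significant_species),
      prop_abundance_significant = mean(by_sp$abundance_significant_species),
      n_sig_temp_combos = nrow(sig_t),
      n_sig_abund_combos = nrow(sig_a),
      mean_dlat_per_c = mean_dlat,
      se_dlat_per_c = se_dlat,
      dlat_t_test_p = t_p,
      mean_dlat_km = lat_deg_to_km(mean_dlat),
      mean_ddepth_per_c = mean_ddepth,
      ddepth_t_test_p = depth_t_p,
      prop_north_temp = if (nrow(sig_t)) n_north_t / nrow(sig_t) else NA_real_,
      orientation_p_temp = if (nrow(sig_t)) {
        orientation_test(n_north_t, nrow(sig_t))
      } else {
        NA_real_
      },
      mean_dlat_per_doubling = mean_dlat_a,
      dlat_doubling_t_test_p = t_p_a,
      prop_north_abundance = if (nrow(sig_a)) {
        n_north_a / nrow(sig_a)
      } else {
        NA_real_
      },
      orientation_p_abundance = if (nrow(sig_a)) {
        orientation_test(n_north_a, nrow(sig_a))
      } else {
        NA_real_
      },
      mean_distance_km_temp = if (nrow(sig_t)) {
        mean(sig_t$distance_km_temp)
      } else {
        NA_real_
      },
      distance_range_km_temp = if (nrow(sig_t)) {
        range(sig_t$distance_km_temp)
      } else {
        c(NA_real_, NA_real_)
      },
      prop_over_100km = if (nrow(sig_t)) {
        mean(sig_t$distance_km_temp > 100)
      } else {
        NA_real_
      },
      matched_pairs = matched_pair_comparison(predictions),
      breakdown = breakdown
    ),
    class = "shift_report"
  )
}

# rlang-free tidy-eval shim for group_by on a column name string.
rlang_sym <- function(x) as.name(x)

#' @export
print.shift_report <- function(x, ...) {
  pct <- function(p) sprintf("%.0f%%", 100 * p)
  cat("Cross-species distribution shift synthesis\n")
  cat(sprintf("  species analysed: %d (%d species x region combinations)\n",
              x$n_species, x$n_combinations))
  cat(sprintf("  temperature-responsive species: %s; abundance: %s\n",
              pct(x$prop_temp_significant),
              pct(x$prop_abundance_significant)))
  cat(sprintf(
    "  mean shift per +1 degC: %.3f deg lat (SE %.3f; ~%.1f km; t-test p = %.3g)\n",
    x$mean_dlat_per_c, x$se_dlat_per_c, x$mean_dlat_km, x$dlat_t_test_p))
  cat(sprintf(
    "  northward under warming: %s of %d combos (orientation p = %.3g)\n",
    pct(x$prop_north_temp), x$n_sig_temp_combos, x$orientation_p_temp))
  cat(sprintf(
    "  northward under doubling: %s of %d combos (orientation p = %.3g)\n",
    pct(x$prop_north_abundance), x$n_sig_abund_combos,
    x$orientation_p_abundance))
  mp <- x$matched_pairs
  if (mp$n_pairs > 0) {
    cat(sprintf(
      "  matched pairs (n = %d): temperature / abundance shift ratio %.1f\n",
      mp$n_pairs, mp$ratio))
  }
  cat(sprintf("  mean predicted distance per +1 degC: %.1f km (%.1f-%.1f); >100 km: %s\n",
              x$mean_distance_km_temp, x$distance_range_km_temp[1],
              x$distance_range_km_temp[2], pct(x$prop_over_100km)))
  invisible(x)
}

#' Functional-trait model of predicted shift distance
#'
#' Which ecological characteristics make a species shift far per +1 degC?
#' Weighted-free OLS of the predicted distance on depth class, the
#' stenothermy and thermal-bias indices, regional station coverage and
#' regional abundance, all in interaction with region (sum-to-zero
#' contrasts). Type-III Wald F-tests per term and marginal-effect tables
#' (each predictor varied over its observed range with the others held at
#' their mean / averaged over levels) are returned.
#'
#' @param traits tibble with columns `distance_km, depth_class, steno, tb,
#'   area_sr, a_r, region` (one row per species x region).
#' @param alpha significance level (annotation only).
#' @return list of class `functional_fit`: `fit`, `terms` (term-level F and
#'   p), `marginal_effects` (named list of tibbles).
#' @export
functional_predictor_model <- function(traits, alpha = 0.05) {
  assert_cols(traits, c("distance_km", "depth_class", "steno", "tb",
                        "area_sr", "a_r", "region"))
  d <- traits
  d <- d[complete.cases(d[, c("distance_km", "depth_class", "steno", "tb",
                              "area_sr", "a_r", "region")]), ]
  if (nrow(d) < 20) stop("functional model needs >= 20 species x region rows")
  d$region <- factor(d$region)
  d$depth_class <- factor(d$depth_class)
  multi_region <- nlevels(d$region) > 1
  preds <- c("depth_class", "steno", "tb", "area_sr", "a_r")
  keep <- preds[vapply(preds, function(p) {
    length(unique(d[[p]])) > 1
  }, logical(1))]
  rhs <- if (multi_region) {
    paste0("region * (", paste(keep, collapse = " + "), ")")
  } else {
    paste(keep, collapse = " + ")
  }
  contr <- list()
  if (multi_region) contr$region <- "contr.sum"
  if ("depth_class" %in% keep) contr$depth_class <- "contr.sum"
  fit <- lm(stats::as.formula(paste("distance_km ~", rhs)), data = d,
            contrasts = if (length(contr)) contr else NULL)
  vc <- vcov(fit)
  asg <- attr(model.matrix(fit), "assign")
  labels <- attr(terms(fit), "term.labels")
  term_tests <- lapply(seq_along(labels), function(i) {
    idx <- which(asg == i & !is.na(coef(fit)))
    if (length(idx) == 0) {
      return(tibble::tibble(term = labels[i], F = NA_real_,
                            df = 0L, p_value = NA_real_))
    }
    L <- matrix(0, length(idx), length(coef(fit)))
    L[cbind(seq_along(idx), idx)] <- 1
    w <- wald_f(fit, L, vc)
    tibble::tibble(term = labels[i], F = w$statistic, df = w$df1,
                   p_value = w$p_value)
  })
  term_tests <- dplyr::bind_rows(term_tests)

  marginal <- lapply(keep, function(p) {
    if (is.factor(d[[p]])) {
      vals <- levels(d[[p]])
    } else {
      vals <- seq(min(d[[p]]), max(d[[p]]), length.out = 25)
    }
    grid <- expand.grid(val = vals, region = levels(d$region),
                        stringsAsFactors = FALSE)
    nd <- d[rep(1, nrow(grid)), , drop = FALSE]
    for (q in keep) {
      nd[[q]] <- if (is.factor(d[[q]])) {
        factor(levels(d[[q]])[1], levels = levels(d[[q]]))
      } else {
        mean(d[[q]])
      }
    }
    nd[[p]] <- if (is.factor(d[[p]])) {
      factor(grid$val, levels = levels(d[[p]]))
    } else {
      grid$val
    }
    nd$region <- factor(grid$region, levels = levels(d$region))
    pr <- predict(fit, newdata = nd)
    out <- tibble::tibble(value = grid$val, region = grid$region,
                          predicted_km = as.numeric(pr))
    dplyr::summarise(dplyr::group_by(out, value),
                     predicted_km = mean(predicted_km), .groups = "drop")
  })
  names(marginal) <- keep

  structure(
    list(fit = fit, terms = term_tests, marginal_effects = marginal,
         n = nrow(d), alpha = alpha),
    class = "functional_fit"
  )
}

#' Screen for newly arrived species
#'
#' Species absent from every survey year up to the cutoff, present in at
#' least `min_years` subsequent years, and increasing after arrival
#' (positive one-sided Spearman rank correlation of annual abundance with
#' year over the post-arrival years, `p < trend_alpha`). Uses the full
#' species set, not the core-filtered one. Reported locations and
#' temperatures are catch-weighted means; TB and Steno come from
#' [thermal_affinity()].
#'
#' @param std_catches standardized catch tibble (all species).
#' @param tows tow tibble.
#' @param first_year_cutoff last year of the "absent" window.
#' @param min_years minimum number of post-cutoff years present.
#' @param trend_alpha one-sided significance level for the increasing-
#'   abundance rule.
#' @return tibble `species_id, first_year, n_years_present, mean_lat,
#'   mean_lon, mean_depth_m, mean_temp_c, TB, Steno`.
#' @export
new_arrival_screen <- function(std_catches, tows, first_year_cutoff = 1997,
                               min_years = 8, trend_alpha = 0.05) {
  a_y <- annual_abundance(std_catches, tows)
  candidates <- dplyr::group_modify(
    dplyr::group_by(a_y, species_id),
    function(g, key) {
      present <- g$year[g$A_y > 0]
      if (length(present) == 0L) {
        return(tibble::tibble(first_year = NA_integer_, n_years_present = 0L,
                              increasing = FALSE))
      }
      fy <- min(present)
      post <- g[g$year >= fy, ]
      inc <- if (nrow(post) >= 3 && length(unique(post$A_y)) > 1) {
        ct <- suppressWarnings(
          cor.test(post$A_y, post$year, method = "spearman",
                   alternative = "greater", exact = FALSE)
        )
        ct$p.value < trend_alpha
      } else {
        FALSE
      }
      tibble::tibble(first_year = as.integer(fy),
                     n_years_present = length(present), increasing = inc)
    }
  )
  candidates <- dplyr::ungroup(candidates)
  hits <- candidates[!is.na(candidates$first_year) &
                       candidates$first_year > first_year_cutoff &
                       candidates$n_years_present >= min_years &
                       candidates$increasing, , drop = FALSE]
  if (nrow(hits) == 0L) {
    return(tibble::tibble(
      species_id = character(0), first_year = integer(0),
      n_years_present = integer(0), mean_lat = numeric(0),
      mean_lon = numeric(0), mean_depth_m = numeric(0),
      mean_temp_c = numeric(0), TB = numeric(0), Steno = numeric(0)
    ))
  }
  idx <- match(std_catches$tow_id, tows$tow_id)
  d <- tibble::tibble(
    species_id = std_catches$species_id,
    cpue = std_catches$cpue_nmi,
    lat = tows$lat[idx], lon = tows$lon[idx],
    depth = tows$depth_m[idx], temp = tows$bottom_temp_c[idx]
  )
  d <- d[d$cpue > 0 & d$species_id %in% hits$species_id, ]
  means <- dplyr::summarise(
    dplyr::group_by(d, species_id),
    mean_lat = weighted.mean(lat, cpue),
    mean_lon = weighted.mean(lon, cpue),
    mean_depth_m = weighted.mean(depth, cpue),
    mean_temp_c = weighted.mean(temp[!is.na(temp)], cpue[!is.na(temp)]),
    .groups = "drop"
  )
  aff <- suppressWarnings(
    thermal_affinity(std_catches, tows, species = hits$species_id)
  )
  out <- dplyr::left_join(hits[, c("species_id", "first_year",
                                   "n_years_present")],
                          means, by = "species_id")
  out <- dplyr::left_join(out, aff[, c("species_id", "TB", "Steno")],
                          by = "species_id")
  dplyr::arrange(out, first_year, species_id)
}
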