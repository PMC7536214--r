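# Shared numerical helpers and unit constants.

# Meridian arc length used for quick degree <-> km conversion of latitude
# shifts. A single documented constant (km per degree of latitude).
KM_PER_DEG_LAT <- 111.2

# International nautical mile in kilometres.
KM_PER_NMI <- 1.852

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert a latitude difference in degrees to kilometres
#'
#' Multiplies by a fixed meridian arc length of 111.2 km per degree, the
#' convention used throughout the package when a quick scalar conversion of a
#' north-south shift is needed (full geodesic computations use
#' [geodesic_shift()]).
#'
#' @param delta_lat_deg latitude difference in decimal degrees.
#' @return kilometres (signed as the input).
#' @examples
#' lat_deg_to_km(0.074) # ~ 8.2 km
#' @export
lat_deg_to_km <- function(delta_lat_deg) {
  delta_lat_deg * KM_PER_DEG_LAT
}

#' @rdname lat_deg_to_km
#' @param km kilometres to convert back to degrees of latitude.
#' @export
km_to_lat_deg <- function(km) {
  km / KM_PER_DEG_LAT
}

#' Convert nautical miles to kilometres
#'
#' @param nmi distance in international nautical miles (1 nmi = 1.852 km).
#' @return kilometres.
#' @examples
#' nmi_to_km(3.0) # 5.556, the standard tow length
#' @export
nmi_to_km <- function(nmi) {
  nmi * KM_PER_NMI
}

#' Weighted quantiles via the weighted empirical CDF
#'
#' Computes quantiles of `x` with non-negative weights `w` using a weighted
#' empirical CDF: distinct sorted values receive cumulative plotting
#' positions `(cumsum(w) - w/2) / sum(w)` and quantiles are linearly
#' interpolated between adjacent distinct values; probabilities beyond the
#' outermost positions return the extreme values. With uniform weights the
#' median reproduces `stats::median()`. This single rule is used for all
#' catch-weighted percentiles (thermal bias median, 5th/95th stenothermy
#' percentiles).
#'
#' @param x numeric values.
#' @param w non-negative weights, same length as `x`.
#' @param probs probabilities in `[0, 1]`.
#' @return numeric vector of quantiles, one per element of `probs`.
#' @examples
#' weighted_quantile(1:10, rep(1, 10), c(0.05, 0.5, 0.95))
#' @export
weighted_quantile <- function(x, w, probs) {
  stopifnot(length(x) == length(w), all(probs >= 0 & probs <= 1))
  keep <- !is.na(x) & !is.na(w) & w > 0
  x <- x[keep]
  w <- w[keep]
  if (length(x) == 0L) {
    return(rep(NA_real_, length(probs)))
  }
  if (any(w < 0)) {
    stop("weights must be non-negative")
  }
  o <- order(x)
  x <- x[o]
  w <- w[o]
  grp <- cumsum(!duplicated(x))
  if (grp[length(grp)] < length(x)) {
    w <- as.numeric(tapply(w, grp, sum))
    x <- x[!duplicated(x)]
  }
  cw <- cumsum(w)
  pos <- (cw - w / 2) / cw[length(cw)]
  vapply(probs, function(p) {
    if (length(x) == 1L || p <= pos[1L]) {
      x[1L]
    } else if (p >= pos[length(pos)]) {
      x[length(x)]
    } else {
      approx(pos, x, xout = p, ties = "ordered")$y
    }
  }, numeric(1))
}

#' @rdname weighted_quantile
#' @export
weighted_median <- function(x, w) {
  weighted_quantile(x, w, 0.5)
}

#' Circular mean of bearings
#'
#' Mean direction of a set of bearings in degrees clockwise from north,
#' optionally weighted. Returns a value in `[0, 360)`; `NA` if the resultant
#' vector has (numerically) zero length.
#'
#' @param bearing_deg bearings in degrees, 0 = north, clockwise.
#' @param w optional non-negative weights.
#' @return mean bearing in degrees, or `NA`.
#' @export
circular_mean_bearing <- function(bearing_deg, w = NULL) {
  bearing_deg <- bearing_deg[!is.na(bearing_deg)]
  if (length(bearing_deg) == 0L) {
    return(NA_real_)
  }
  w <- w %||% rep(1, length(bearing_deg))
  rad <- bearing_deg * pi / 180
  s <- weighted.mean(sin(rad), w)
  c <- weighted.mean(cos(rad), w)
  if (sqrt(s^2 + c^2) < 1e-12) {
    return(NA_real_)
  }
  out <- (atan2(s, c) * 180 / pi) %% 360
  if (out >= 360 - 1e-9) out <- 0
  out
}

# Evaluate a deterministic expression under a temporary RNG seed.
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

# Column presence check with a readable error.
assert_cols <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(df)
}

# Wald F-test of L %*% beta = 0 given a fitted lm and a covariance matrix.
# Rows of L are linear combinations over the *estimable* (non-NA)
# coefficients. Returns list(statistic, df1, df2, p_value, estimate).
wald_f <- function(fit, L, vc) {
  beta <- coef(fit)
  keep <- !is.na(beta)
  beta <- beta[keep]
  L <- L[, keep, drop = FALSE]
  est <- drop(L %*% beta)
  V <- L %*% vc %*% t(L)
  q <- nrow(L)
  stat <- drop(crossprod(est, solve(V, est))) / q
  df2 <- df.residual(fit)
  list(
    statistic = stat, df1 = q, df2 = df2,
    p_value = pf(stat, q, df2, lower.tail = FALSE),
    estimate = est
  )
}

# Wald test of all coefficients whose name matches `pattern` (fixed string).
term_wald <- function(fit, pattern, vc) {
  beta <- coef(fit)
  idx <- grepl(pattern, names(beta), fixed = TRUE) & !is.na(beta)
  if (!any(idx)) {
    return(list(statistic = NA_real_, df1 = 0L, df2 = df.residual(fit),
                p_value = NA_real_, estimate = numeric(0)))
  }
  L <- matrix(0, nrow = sum(idx), ncol = length(beta),
              dimnames = list(NULL, names(beta)))
  L[cbind(seq_len(sum(idx)), which(idx))] <- 1
  wald_f(fit, L, vc)
}
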