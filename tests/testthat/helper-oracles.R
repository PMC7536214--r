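# Independent brute-force oracles, implemented without reference to the
# package internals they check.

# Weighted quantile by explicit ECDF construction and manual interpolation.
oracle_weighted_quantile <- function(x, w, p) {
  keep <- w > 0 & !is.na(x)
  x <- x[keep]
  w <- w[keep]
  o <- order(x)
  x <- x[o]
  w <- w[o]
  ux <- sort(unique(x))
  uw <- vapply(ux, function(v) sum(w[x == v]), numeric(1))
  cw <- cumsum(uw)
  pos <- (cw - uw / 2) / sum(uw)
  sapply(p, function(pp) {
    if (length(ux) == 1 || pp <= pos[1]) return(ux[1])
    if (pp >= pos[length(pos)]) return(ux[length(ux)])
    i <- max(which(pos <= pp))
    ux[i] + (ux[i + 1] - ux[i]) * (pp - pos[i]) / (pos[i + 1] - pos[i])
  })
}

# Weighted mean by an explicit accumulation loop.
oracle_weighted_mean <- function(x, w) {
  s <- 0
  sw <- 0
  for (i in seq_along(x)) {
    s <- s + x[i] * w[i]
    sw <- sw + w[i]
  }
  s / sw
}

# Haversine distance (km) and spherical initial bearing (deg), from the
# closed-form formulas.
oracle_haversine_km <- function(lat1, lon1, lat2, lon2, r = 6378.137) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(sqrt(pmin(a, 1)))
}

oracle_initial_bearing <- function(lat1, lon1, lat2, lon2) {
  to_rad <- pi / 180
  phi1 <- lat1 * to_rad
  phi2 <- lat2 * to_rad
  dl <- (lon2 - lon1) * to_rad
  y <- sin(dl) * cos(phi2)
  x <- cos(phi1) * sin(phi2) - sin(phi1) * cos(phi2) * cos(dl)
  (atan2(y, x) / to_rad) %% 360
}
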