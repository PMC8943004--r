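# Independent oracles used across the suite. Each deliberately re-derives
# the quantity by a different route than the implementation.

# Solar elevation by the Astronomical Almanac low-precision algorithm
# (Michalsky 1988) -- independent of the NOAA-style formulation in the
# package (different mean elements, sidereal-time-based hour angle).
oracle_solar_elevation <- function(time, lon, lat) {
  d <- as.numeric(time, units = "secs") / 86400 + 2440587.5 - 2451545
  g <- (357.529 + 0.98560028 * d) %% 360
  q <- (280.459 + 0.98564736 * d) %% 360
  L <- q + 1.915 * sin(g * pi / 180) + 0.020 * sin(2 * g * pi / 180)
  e <- 23.439 - 0.00000036 * d
  dec <- asin(sin(e * pi / 180) * sin(L * pi / 180)) * 180 / pi
  RA <- atan2(cos(e * pi / 180) * sin(L * pi / 180), cos(L * pi / 180)) * 180 / pi
  gmst <- (18.697374558 + 24.06570982441908 * d) %% 24
  ha <- (gmst * 15 + lon - RA) %% 360
  asin(sin(lat * pi / 180) * sin(dec * pi / 180) +
         cos(lat * pi / 180) * cos(dec * pi / 180) * cos(ha * pi / 180)) * 180 / pi
}

# Time at which the oracle elevation crosses `elev_deg`, found by bisection
# between two bracketing times.
oracle_crossing_time <- function(t_lo, t_hi, lon, lat, elev_deg) {
  f <- function(t) oracle_solar_elevation(t, lon, lat) - elev_deg
  lo <- as.numeric(t_lo); hi <- as.numeric(t_hi)
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    tm <- as.POSIXct(mid, origin = "1970-01-01", tz = "UTC")
    if (sign(f(tm)) == sign(f(as.POSIXct(lo, origin = "1970-01-01", tz = "UTC")))) {
      lo <- mid
    } else hi <- mid
  }
  as.POSIXct((lo + hi) / 2, origin = "1970-01-01", tz = "UTC")
}

# Exact 1-D k-means by dynamic programming over sorted values (optimal
# partition into k contiguous blocks minimising within-cluster SSE).
oracle_kmeans_1d <- function(x, k) {
  xs <- sort(x)
  n <- length(xs)
  cs <- cumsum(xs); cs2 <- cumsum(xs^2)
  sse <- function(i, j) { # block i..j (1-based, inclusive)
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  D <- matrix(Inf, k, n)
  B <- matrix(NA_integer_, k, n)
  for (j in 1:n) D[1, j] <- sse(1, j)
  if (k > 1) for (m in 2:k) for (j in m:n) {
    for (i in m:j) {
      v <- D[m - 1, i - 1] + sse(i, j)
      if (v < D[m, j]) { D[m, j] <- v; B[m, j] <- i }
    }
  }
  # recover boundaries
  bounds <- integer(k + 1); bounds[k + 1] <- n
  j <- n
  for (m in k:2) { bounds[m] <- B[m, j] - 1; j <- B[m, j] - 1 }
  bounds[1] <- 0
  lab <- integer(n)
  for (m in 1:k) lab[(bounds[m] + 1):bounds[m + 1]] <- m
  list(sorted = xs, labels = lab,
       centroids = tapply(xs, lab, mean))
}

# Brute-force maximal-run scan for bout detection.
oracle_bout_runs <- function(high, min_len) {
  runs <- list()
  i <- 1; n <- length(high)
  while (i <= n) {
    if (high[i]) {
      j <- i
      while (j < n && high[j + 1]) j <- j + 1
      if (j - i + 1 >= min_len) runs[[length(runs) + 1]] <- c(i, j)
      i <- j + 1
    } else i <- i + 1
  }
  runs
}

# Brute-force zonal majority: enumerate every cell, test centre-in-box,
# accumulate cos-latitude weights per code.
oracle_zonal <- function(grid, box, area_weighted = TRUE) {
  acc <- list()
  for (r in seq_len(grid$nrows)) {
    lat <- grid$yllcorner + (grid$nrows - r + 0.5) * grid$cellsize
    if (lat < box[3] || lat > box[4]) next
    w <- if (area_weighted) cos(lat * pi / 180) else 1
    for (cc in seq_len(grid$ncols)) {
      lon <- grid$xllcorner + (cc - 0.5) * grid$cellsize
      if (lon < box[1] || lon > box[2]) next
      v <- grid$values[r, cc]
      if (is.na(v)) next
      key <- as.character(v)
      acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + w
    }
  }
  if (!length(acc)) return(NULL)
  tot <- unlist(acc)
  fr <- tot / sum(tot)
  best <- max(fr)
  winners <- as.numeric(names(fr)[fr >= best - 1e-12])
  list(majority = min(winners), fraction = fr[[as.character(min(winners))]],
       fractions = fr[order(as.numeric(names(fr)))])
}

# 5-min sensor timeline helper
make_times <- function(n, start = "2018-10-01 00:00:00") {
  as.POSIXct(start, tz = "UTC") + (seq_len(n) - 1) * 300
}
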