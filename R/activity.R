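#' Accelerometer activity classification and flight-bout detection
#'
#' The activity index of a multi-sensor logger (sum of absolute z-axis
#' acceleration differences per 5-min interval) separates into three regimes:
#' inactivity, low activity (wing flaps while perched, short movements) and
#' high activity (sustained flapping flight). Migratory flight bouts are
#' maximal runs of uninterrupted high activity lasting at least 60 min;
#' stopovers are days whose night contains no bout.
#'
#' @name activity
NULL

#' Construct a sensor series
#'
#' Validates and orders a multi-sensor logger stream recorded at a nominal
#' 5-min cadence. Gaps are allowed and flagged downstream; duplicated or
#' non-increasing timestamps are errors.
#'
#' @param time POSIXct UTC timestamps.
#' @param activity nonnegative activity index (z-axis jerk sum); NA allowed.
#' @param pressure_hpa air pressure, hPa; NA allowed.
#' @param light light intensity, logger units; NA allowed.
#' @param temperature_C air temperature; NA allowed.
#' @param individual_id identifier of the logger/bird.
#' @return data.frame of class `sensor_series`.
#' @export
sensor_series <- function(time, activity = NA_real_, pressure_hpa = NA_real_,
                          light = NA_real_, temperature_C = NA_real_,
                          individual_id = "ind1") {
  stopifnot(inherits(time, "POSIXct"))
  if (is.unsorted(time, strictly = TRUE)) {
    stop("timestamps must be strictly increasing")
  }
  out <- data.frame(
    individual_id = individual_id, time = time,
    activity = as.numeric(activity), pressure_hpa = as.numeric(pressure_hpa),
    light = as.numeric(light), temperature_C = as.numeric(temperature_C)
  )
  class(out) <- c("sensor_series", "data.frame")
  out
}

#' Classify activity values into inactive / low / high
#'
#' One-dimensional k-means (Lloyd) on the activity index with deterministic
#' quantile initialisation: initial centroids at the 1/(2k), 3/(2k), ...
#' quantiles of the data. Clusters are relabelled by ascending centroid so
#' that inactive < low < high regardless of input order. Classification is
#' per individual: each logger's own value distribution sets its boundaries.
#'
#' @param activity numeric activity values (NAs tolerated, labelled NA).
#' @param k number of states, default 3.
#' @return factor with levels inactive < low < high (for k = 3; otherwise
#'   state1..statek), with the fitted centroids in `attr(, "centroids")`.
#' @export
classify_activity <- function(activity, k = 3) {
  x <- activity[is.finite(activity)]
  if (length(unique(x)) < k) stop("degenerate activity distribution: fewer than ", k, " distinct values")
  centers <- stats::quantile(x, probs = (2 * seq_len(k) - 1) / (2 * k),
                             names = FALSE, type = 7)
  # quantile starts can coincide on heavily-tied data; spread to distinct values
  if (anyDuplicated(centers)) {
    centers <- sort(unique(x))[round(seq(1, length(unique(x)), length.out = k))]
  }
  km <- stats::kmeans(x, centers = matrix(sort(centers), ncol = 1),
                      iter.max = 500, algorithm = "Lloyd")
  ord <- order(km$centers[, 1])
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  lev <- if (k == 3) c("inactive", "low", "high") else paste0("state", seq_len(k))
  lab <- factor(lev[relabel[km$cluster]], levels = lev)
  out <- factor(rep(NA_character_, length(activity)), levels = lev)
  out[is.finite(activity)] <- lab
  attr(out, "centroids") <- sort(as.numeric(km$centers))
  out
}

#' Detect migratory flight bouts
#'
#' Maximal runs of consecutive high-activity intervals whose total duration
#' reaches `min_duration_min`. "Uninterrupted" is strict: any non-high
#' interval, or a recording gap longer than 1.5 nominal intervals, breaks the
#' run (a `gap_tolerance` of n intervals can relax the former).
#'
#' @param time POSIXct timestamps aligned with `state`.
#' @param state factor from [classify_activity()].
#' @param min_duration_min minimum bout duration, minutes (default 60).
#' @param interval_s nominal sampling interval, seconds (default 300).
#' @param gap_tolerance number of interrupting non-high intervals tolerated
#'   inside a run (default 0, strict).
#' @return data.frame with columns start, end, duration_min, n_intervals;
#'   zero rows if no bout qualifies.
#' @export
detect_flight_bouts <- function(time, state, min_duration_min = 60,
                                interval_s = 300, gap_tolerance = 0) {
  stopifnot(length(time) == length(state))
  high <- !is.na(state) & state == "high"
  broken <- c(FALSE, diff(as.numeric(time)) > 1.5 * interval_s)
  if (gap_tolerance > 0) {
    # close runs of <= gap_tolerance non-high intervals flanked by high
    r <- rle(high)
    idx <- which(!r$values & r$lengths <= gap_tolerance)
    idx <- idx[idx > 1 & idx < length(r$values)]
    if (length(idx)) {
      ends <- cumsum(r$lengths)
      for (i in idx) {
        fill <- (ends[i] - r$lengths[i] + 1):ends[i]
        if (!any(broken[fill])) high[fill] <- TRUE
      }
    }
  }
  run_id <- cumsum(c(TRUE, diff(high) != 0) | broken)
  bouts <- list()
  for (id in unique(run_id[high])) {
    sel <- which(run_id == id & high)
    if (length(sel) * interval_s / 60 >= min_duration_min) {
      bouts[[length(bouts) + 1]] <- data.frame(
        start = time[sel[1]], end = time[sel[length(sel)]] + interval_s,
        duration_min = length(sel) * interval_s / 60,
        n_intervals = length(sel)
      )
    }
  }
  if (!length(bouts)) {
    return(data.frame(start = as.POSIXct(character(), tz = "UTC"),
                      end = as.POSIXct(character(), tz = "UTC"),
                      duration_min = numeric(), n_intervals = integer()))
  }
  do.call(rbind, bouts)
}

#' Delineate stopovers
#'
#' A stopover is a run of one or more consecutive days within the migration
#' span whose nights contain no migratory flight bout. A night is attributed
#' to the date of its sunset (noon-to-noon local solar window, see
#' [night_date()]), the actogram convention for a nocturnal migrant.
#'
#' @param bouts data.frame from [detect_flight_bouts()].
#' @param span_start,span_end Dates bounding the migration period.
#' @param lon representative longitude for the local-solar day attribution.
#' @return data.frame with columns start_date, end_date, n_days.
#' @export
delineate_stopovers <- function(bouts, span_start, span_end, lon = 0) {
  span_start <- as.Date(span_start); span_end <- as.Date(span_end)
  stopifnot(span_end >= span_start)
  days <- seq(span_start, span_end, by = "day")
  bout_nights <- if (nrow(bouts)) unique(night_date(bouts$start, lon)) else as.Date(character())
  quiet <- !(days %in% bout_nights)
  r <- rle(quiet)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  data.frame(
    start_date = days[starts[keep]],
    end_date = days[ends[keep]],
    n_days = r$lengths[keep]
  )
}

#' Derive the migrating / foraging binary variables
#'
#' Migrating: interval inside a detected flight bout. Foraging: low or high
#' activity outside any bout (high and low activity levels outside sustained
#' flight are associated with foraging behaviour). The two are exclusive by
#' construction; inactive intervals are neither.
#'
#' @inheritParams detect_flight_bouts
#' @param bouts data.frame from [detect_flight_bouts()].
#' @param foraging_states states counted as foraging outside bouts
#'   (default low and high).
#' @return data.frame with columns time, state, migrating, foraging.
#' @export
derive_binary_variables <- function(time, state, bouts,
                                    foraging_states = c("low", "high")) {
  migrating <- rep(FALSE, length(time))
  if (nrow(bouts)) {
    for (i in seq_len(nrow(bouts))) {
      migrating <- migrating | (time >= bouts$start[i] & time < bouts$end[i])
    }
  }
  migrating <- migrating & !is.na(state) & state == "high"
  foraging <- !is.na(state) & state %in% foraging_states & !migrating
  data.frame(time = time, state = state, migrating = migrating,
             foraging = foraging)
}
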