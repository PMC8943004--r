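#' MCMC refinement of threshold positions (Estelle-style model)
#'
#' Refines the twilight-pair position sequence by Metropolis-within-Gibbs
#' sampling of the joint posterior combining (i) the twilight-time
#' likelihood under the calibrated lognormal delay model, (ii) a gamma prior
#' on great-circle speed between consecutive locations (shape 2.2, rate
#' 0.08, km/h) and (iii) a land mask forbidding stationary positions over
#' water. Stopover twilights are grouped and share one location parameter;
#' the first (and optionally last) location is anchored at a known site.
#'
#' @name estelle
NULL

#' Movement and mask priors for the Estelle model
#'
#' @param deployment_lon,deployment_lat known deployment site (anchors the
#'   first location).
#' @param arrival_lon,arrival_lat optional known terminal site (anchors the
#'   last location); NA leaves it free.
#' @param speed_shape,speed_rate gamma prior on speed in km/h
#'   (defaults 2.2 and 0.08; prior mean 27.5 km/h).
#' @param land_mask optional `ascii_grid` with 1 = land, 0 = water;
#'   stationary (grouped) positions over water get zero prior mass.
#' @return list of class `estelle_priors`.
#' @export
estelle_priors <- function(deployment_lon, deployment_lat,
                           arrival_lon = NA, arrival_lat = NA,
                           speed_shape = 2.2, speed_rate = 0.08,
                           land_mask = NULL) {
  stopifnot(speed_shape > 0, speed_rate > 0)
  if (!is.null(land_mask)) {
    v <- sample_point(land_mask, deployment_lon, deployment_lat)
    if (!is.na(v) && v == 0) stop("deployment site falls on water in the land mask")
  }
  structure(list(
    deployment = c(deployment_lon, deployment_lat),
    arrival = c(arrival_lon, arrival_lat),
    speed_shape = speed_shape, speed_rate = speed_rate,
    land_mask = land_mask
  ), class = "estelle_priors")
}

#' MCMC schedule
#'
#' Defaults follow the conventional Estelle run protocol: 250 iterations to
#' initiate, three tuning runs of 300 iterations each (proposal scales
#' adapted toward 23% acceptance), then 2000 final iterations kept as the
#' posterior sample.
#'
#' @param init,tune_runs,tune_iter,final iteration counts.
#' @param target_accept adaptation target acceptance rate.
#' @param init_scale initial proposal sd, degrees.
#' @return list.
#' @export
mcmc_schedule <- function(init = 250, tune_runs = 3, tune_iter = 300,
                          final = 2000, target_accept = 0.23,
                          init_scale = 1) {
  list(init = init, tune_runs = tune_runs, tune_iter = tune_iter,
       final = final, target_accept = target_accept, init_scale = init_scale)
}

# Solar elevation (deg) at precomputed basis (mins/eqtime/dec) for the
# event's timestamp, as a function of position only. Cheap: no ephemeris
# re-evaluation inside the sampler.
.elev_at_basis <- function(lon, lat, mins, eqtime, dec) {
  tst <- (mins + eqtime + 4 * lon) %% 1440
  ha <- tst / 4 - 180
  cosz <- sin(.deg2rad(lat)) * sin(.deg2rad(dec)) +
    cos(.deg2rad(lat)) * cos(.deg2rad(dec)) * cos(.deg2rad(ha))
  90 - .rad2deg(acos(pmin(1, pmax(-1, cosz))))
}

# Twilight log-likelihood at positions theta[g, ], summed by group.
#
# The error variable is the sun-zenith offset at the observed crossing time:
# err = z0 - zenith(position, t_obs), nonnegative under shading (shading
# raises the crossing elevation by an amount independent of latitude and
# season, which is why the model is formulated in degrees, not minutes).
# Density of the observed *time* includes the |d elevation / d t| Jacobian.
# Below eps degrees the log-density falls off linearly (soft shoulder)
# rather than dropping to -Inf.
.twilight_group_loglik <- function(theta, tw, calib) {
  lon <- theta[tw$group, 1]; lat <- theta[tw$group, 2]
  e0 <- .elev_at_basis(lon, lat, tw$min0, tw$eq0, tw$dec0)
  em <- .elev_at_basis(lon, lat, tw$minm, tw$eqm, tw$decm)
  ep <- .elev_at_basis(lon, lat, tw$minp, tw$eqp, tw$decp)
  rate <- pmax(abs(ep - em) / 10, 1e-4)        # deg per minute at t_obs
  err <- calib$zenith0_deg - (90 - e0)
  eps <- 0.02
  ll_ev <- ifelse(err > eps,
                  stats::dlnorm(err, calib$meanlog_deg, calib$sdlog_deg,
                                log = TRUE),
                  stats::dlnorm(eps, calib$meanlog_deg, calib$sdlog_deg,
                                log = TRUE) + 8 * (err - eps)) + log(rate)
  as.numeric(rowsum(ll_ev, tw$group, reorder = TRUE))
}

# Speed-prior log-density for each between-group segment j = 1..K-1.
.segment_loglik <- function(theta, seg_dt_h, priors) {
  K <- nrow(theta)
  if (K < 2) return(numeric(0))
  d <- great_circle_km(theta[-K, 1], theta[-K, 2], theta[-1, 1], theta[-1, 2])
  speed <- pmax(d / seg_dt_h, 1e-6)
  stats::dgamma(speed, priors$speed_shape, rate = priors$speed_rate, log = TRUE)
}

# Mask log-indicator per group (0 or -Inf); only stationary groups checked.
.mask_loglik <- function(theta, stationary, priors) {
  out <- rep(0, nrow(theta))
  if (is.null(priors$land_mask) || !any(stationary)) return(out)
  v <- suppressWarnings(
    sample_point(priors$land_mask, theta[stationary, 1], theta[stationary, 2]))
  out[stationary][!is.na(v) & v == 0] <- -Inf
  out
}

#' Refine positions by MCMC
#'
#' @param initial data.frame from [threshold_positions()] (one row per
#'   twilight pair is also accepted; what matters are the twilight events in
#'   `twilights`). Used only for starting values.
#' @param twilights data.frame from [detect_twilights()] with an optional
#'   integer `group` column (equal values share one location; defaults to
#'   one group per event). Groups must be contiguous in time.
#' @param calib `calibration_model` from [hill_ekstrom_calibrate()].
#' @param priors `estelle_priors`.
#' @param schedule [mcmc_schedule()].
#' @return list of class `estelle_fit`: `positions` data.frame (one row per
#'   twilight event: index, date, type, group, lon, lat, lon_lo, lon_hi,
#'   lat_lo, lat_hi at the 97.5% level), `samples` (final-run array
#'   iterations x groups x 2), `accept_rate`, `groups`.
#' @export
refine_positions_mcmc <- function(initial, twilights, calib, priors,
                                  schedule = mcmc_schedule()) {
  tw <- twilights[!twilights$excluded, ]
  tw <- tw[order(tw$time), ]
  n_ev <- nrow(tw)
  if (is.null(tw$group)) tw$group <- seq_len(n_ev)
  tw$group <- match(tw$group, unique(tw$group))  # contiguous 1..K
  K <- max(tw$group)
  b0 <- .solar_basis(tw$time)
  bm <- .solar_basis(tw$time - 300)
  bp <- .solar_basis(tw$time + 300)
  mod <- function(t) (as.numeric(t, units = "secs") / 60) %% 1440
  tw$dec0 <- b0$declination; tw$eq0 <- b0$eqtime; tw$min0 <- mod(tw$time)
  tw$decm <- bm$declination; tw$eqm <- bm$eqtime; tw$minm <- mod(tw$time - 300)
  tw$decp <- bp$declination; tw$eqp <- bp$eqtime; tw$minp <- mod(tw$time + 300)
  grp_sizes <- tabulate(tw$group, K)
  stationary <- grp_sizes > 2  # stopover/wintering groups
  # segment time steps between consecutive groups (hours, midpoints of events)
  tnum <- as.numeric(tw$time) / 3600
  t_first <- tapply(tnum, tw$group, min)
  t_last <- tapply(tnum, tw$group, max)
  seg_dt_h <- pmax(as.numeric(t_first[-1] - t_last[-K]), 0.5)

  # starting values: per-group mean of initial threshold positions
  theta <- matrix(NA_real_, K, 2)
  ini_lon <- stats::approx(seq_len(nrow(initial)), initial$lon,
                           seq_len(nrow(initial)), rule = 2)$y
  lat0 <- initial$lat
  lat0[initial$lat_indeterminate] <- NA
  if (all(is.na(lat0))) lat0 <- rep(calib$calib_lat, length(lat0))
  lat0 <- stats::approx(seq_along(lat0), lat0, seq_along(lat0), rule = 2)$y
  ev2pair <- pmin(pmax(findInterval(tw$time, initial$t1), 1), nrow(initial))
  for (k in seq_len(K)) {
    sel <- ev2pair[tw$group == k]
    theta[k, ] <- c(mean(ini_lon[sel]), mean(lat0[sel]))
  }
  anchored <- rep(FALSE, K)
  theta[1, ] <- priors$deployment; anchored[1] <- TRUE
  if (all(is.finite(priors$arrival))) { theta[K, ] <- priors$arrival; anchored[K] <- TRUE }

  # repair starting values with non-finite twilight likelihood by pulling
  # latitude toward the calibration latitude
  gl <- .twilight_group_loglik(theta, tw, calib)
  bad <- which(!is.finite(gl) & !anchored)
  for (k in bad) {
    for (w in seq(0.1, 1, by = 0.1)) {
      cand <- theta
      cand[k, 2] <- (1 - w) * theta[k, 2] + w * calib$calib_lat
      if (is.finite(.twilight_group_loglik(cand, tw, calib)[k])) {
        theta <- cand; break
      }
    }
  }
  gl <- .twilight_group_loglik(theta, tw, calib)
  if (any(!is.finite(gl[!anchored]))) {
    stop("non-finite initial log-target at position group(s) ",
         paste(which(!is.finite(gl) & !anchored), collapse = ", "))
  }
  ml <- .mask_loglik(theta, stationary, priors)
  if (any(!is.finite(ml[anchored]))) stop("mask violation at an anchored position")

  scale <- rep(schedule$init_scale, K)
  free <- which(!anchored)
  odd <- free[free %% 2 == 1]; even <- free[free %% 2 == 0]

  group_target <- function(theta, gl, sl, ml) {
    # per-group target: own twilights + adjacent segments + mask
    sl_left <- c(0, sl); sl_right <- c(sl, 0)
    gl + sl_left + sl_right + ml
  }

  run_block <- function(theta, block, scale) {
    if (!length(block)) return(list(theta = theta, acc = logical(0)))
    gl <- .twilight_group_loglik(theta, tw, calib)
    sl <- .segment_loglik(theta, seg_dt_h, priors)
    ml <- .mask_loglik(theta, stationary, priors)
    cur <- group_target(theta, gl, sl, ml)[block]
    prop <- theta
    prop[block, ] <- theta[block, ] +
      cbind(stats::rnorm(length(block), 0, scale[block]),
            stats::rnorm(length(block), 0, scale[block]))
    prop[block, 2] <- pmin(pmax(prop[block, 2], -89), 89)
    glp <- .twilight_group_loglik(prop, tw, calib)
    slp <- .segment_loglik(prop, seg_dt_h, priors)
    mlp <- .mask_loglik(prop, stationary, priors)
    new <- group_target(prop, glp, slp, mlp)[block]
    acc <- log(stats::runif(length(block))) < (new - cur)
    acc[!is.finite(new)] <- FALSE
    theta[block[acc], ] <- prop[block[acc], ]
    list(theta = theta, acc = acc)
  }

  sweep <- function(theta, scale) {
    a1 <- run_block(theta, odd, scale)
    a2 <- run_block(a1$theta, even, scale)
    acc <- rep(NA, K)
    acc[odd] <- a1$acc; acc[even] <- a2$acc
    list(theta = a2$theta, acc = acc)
  }

  for (i in seq_len(schedule$init)) theta <- sweep(theta, scale)$theta
  for (r in seq_len(schedule$tune_runs)) {
    acc_n <- rep(0, K)
    for (i in seq_len(schedule$tune_iter)) {
      s <- sweep(theta, scale)
      theta <- s$theta
      acc_n <- acc_n + ifelse(is.na(s$acc), 0, s$acc)
    }
    rate <- acc_n / schedule$tune_iter
    scale <- pmin(pmax(scale * exp(1.5 * (rate - schedule$target_accept)),
                       0.01), 20)
  }
  samples <- array(NA_real_, c(schedule$final, K, 2))
  acc_n <- rep(0, K)
  for (i in seq_len(schedule$final)) {
    s <- sweep(theta, scale)
    theta <- s$theta
    acc_n <- acc_n + ifelse(is.na(s$acc), 0, s$acc)
    samples[i, , ] <- theta
  }

  ci <- t(vapply(seq_len(K), function(k) {
    c(credible_interval(samples[, k, 1], samples[, k, 2])$box)
  }, numeric(4)))
  positions <- data.frame(
    index = seq_len(n_ev), date = tw$date, type = tw$type, group = tw$group,
    lon = colMeans(samples[, tw$group, 1, drop = FALSE]),
    lat = colMeans(samples[, tw$group, 2, drop = FALSE]),
    lon_lo = ci[tw$group, 1], lon_hi = ci[tw$group, 2],
    lat_lo = ci[tw$group, 3], lat_hi = ci[tw$group, 4]
  )
  structure(list(positions = positions, samples = samples,
                 accept_rate = acc_n / schedule$final,
                 groups = tw$group, stationary = stationary,
                 scale = scale),
            class = "estelle_fit")
}

#' Equal-tailed credible-interval box of a posterior position sample
#'
#' Per-axis equal-tailed quantile box: at level 0.975 the bounds are the
#' 1.25% and 98.75% sample quantiles of longitude and latitude.
#'
#' @param lon_samples,lat_samples posterior draws (>= 100).
#' @param level credible level (default 0.975).
#' @return list with `box` = c(lon_lo, lon_hi, lat_lo, lat_hi) and
#'   `width` = c(lon, lat) widths in degrees.
#' @export
credible_interval <- function(lon_samples, lat_samples, level = 0.975) {
  if (length(lon_samples) < 100) stop("need at least 100 posterior samples")
  a <- (1 - level) / 2
  qs <- c(stats::quantile(lon_samples, c(a, 1 - a), names = FALSE),
          stats::quantile(lat_samples, c(a, 1 - a), names = FALSE))
  list(box = qs, width = c(qs[2] - qs[1], qs[4] - qs[3]))
}
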