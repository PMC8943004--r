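#' Mixed models of migration tactics
#'
#' Binomial GLMMs for the probability of migrating / foraging per 5-min
#' interval as a function of biome category (barrier vs hospitable,
#' reference hospitable) interacting with period (dusk / night / dawn,
#' reference dusk), with the previous interval's outcome as an
#' autocorrelation covariate and a random intercept per individual;
#' Gaussian mixed models for daily altitude change and daily travel speed;
#' a zero-inflated model for flight altitude above ground; likelihood-ratio
#' tests; and Tukey-style barrier-minus-hospitable contrasts per period.
#' Fitting is maximum likelihood via glmmTMB (Laplace approximation);
#' contrasts via emmeans with multivariate-t adjustment.
#'
#' @name stats_models
NULL

#' Assemble the interval-level model frame
#'
#' One row per 5-min interval on non-stopover days, with the interval's
#' period classified at the day's position estimate; day-period rows are
#' dropped (the probability models concern dusk, night and dawn only), the
#' lagged outcome is computed within individual, and each individual's first
#' interval is dropped (no lag available).
#'
#' @param labels data.frame from [derive_binary_variables()] plus an
#'   `individual_id` column.
#' @param daily data.frame with columns individual_id, date, lon, lat,
#'   biome_category — the per-day position estimate and its biome.
#' @param stopover_dates Date vector (per individual use a data.frame with
#'   individual_id, date) of stopover days to exclude.
#' @return data.frame with individual_id, time, date, period, biome_category,
#'   migrating, foraging, prev_migrating, prev_foraging.
#' @export
build_model_frame <- function(labels, daily, stopover_dates = NULL) {
  stopifnot(all(c("individual_id", "time", "migrating", "foraging") %in% names(labels)))
  labels <- labels[order(labels$individual_id, labels$time), ]
  labels$date <- night_date(labels$time)
  key <- paste(labels$individual_id, labels$date)
  dkey <- paste(daily$individual_id, daily$date)
  m <- match(key, dkey)
  if (all(is.na(m))) stop("no overlap between labels and daily positions: check individual_id/date keys")
  frame <- labels
  frame$lon <- daily$lon[m]; frame$lat <- daily$lat[m]
  frame$biome_category <- daily$biome_category[m]
  frame <- frame[!is.na(frame$biome_category), ]
  frame$period <- classify_period(frame$time, frame$lon, frame$lat)
  # lag within individual before any row filtering tied to period
  lag1 <- function(x) c(NA, x[-length(x)])
  first <- !duplicated(frame$individual_id)
  frame$prev_migrating <- ave(as.integer(frame$migrating), frame$individual_id,
                              FUN = lag1)
  frame$prev_foraging <- ave(as.integer(frame$foraging), frame$individual_id,
                             FUN = lag1)
  frame <- frame[!first & !is.na(frame$prev_migrating), ]
  if (!is.null(stopover_dates)) {
    if (is.data.frame(stopover_dates)) {
      skey <- paste(stopover_dates$individual_id, stopover_dates$date)
      frame <- frame[!(paste(frame$individual_id, frame$date) %in% skey), ]
    } else {
      frame <- frame[!(frame$date %in% as.Date(stopover_dates)), ]
    }
  }
  frame <- frame[frame$period != "day", ]
  frame$period <- factor(frame$period, levels = c("dusk", "night", "dawn"))
  frame$biome_category <- factor(frame$biome_category,
                                 levels = c("hospitable", "barrier"))
  frame$individual_id <- factor(frame$individual_id)
  frame
}

# Quasi-Newton polish of a pinned-variance fit: nlminb stops with a
# residual gradient of ~1e-4 on these deliberately-degenerate problems;
# a BFGS pass from its solution recovers the GLM/OLS optimum to ~1e-9.
.polish_pinned <- function(model, out) {
  p <- tryCatch(
    stats::optim(model$fit$par, model$obj$fn, model$obj$gr, method = "BFGS",
                 control = list(reltol = 1e-16, maxit = 500)),
    error = function(e) NULL)
  if (!is.null(p) && is.finite(p$value) && p$value <= -out$loglik + 1e-8) {
    bi <- which(names(p$par) == "beta")
    if (length(bi) == nrow(out$coefficients)) {
      out$coefficients$estimate <- unname(p$par[bi])
      out$loglik <- -p$value
    }
  }
  out
}

.fit_result <- function(model, n_obs, n_groups, note = NULL) {
  ll <- stats::logLik(model)
  co <- if (inherits(model, "glmmTMB")) {
    summary(model)$coefficients$cond
  } else {
    summary(model)$coefficients
  }
  re_var <- if (inherits(model, "glmmTMB")) {
    vc <- glmmTMB::VarCorr(model)$cond
    if (length(vc)) as.numeric(vc[[1]][1, 1]) else 0
  } else 0
  conv <- if (inherits(model, "glmmTMB")) {
    isTRUE(model$fit$convergence == 0) &&
      (is.null(model$sdr) || isTRUE(model$sdr$pdHess))
  } else TRUE
  structure(list(
    model = model,
    coefficients = data.frame(term = rownames(co), estimate = co[, 1],
                              se = co[, 2], row.names = NULL),
    re_variance = re_var, loglik = as.numeric(ll),
    df = attr(ll, "df"), converged = conv,
    n_obs = n_obs, n_groups = n_groups, note = note
  ), class = "mixed_model_fit")
}

#' @export
print.mixed_model_fit <- function(x, ...) {
  cat(sprintf("mixed_model_fit: logLik %.2f (df %d), RE variance %.4g, %d obs / %d groups%s\n",
              x$loglik, x$df, x$re_variance, x$n_obs, x$n_groups,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(x$coefficients, digits = 4)
  invisible(x)
}

# separation guard: every category x period cell must contain both outcomes
.check_separation <- function(y, frame) {
  cell <- interaction(frame$biome_category, frame$period, drop = TRUE)
  bad <- tapply(y, cell, function(v) length(unique(v)) < 2)
  if (any(bad)) {
    stop("separation: outcome constant within cell(s) ",
         paste(names(bad)[bad], collapse = ", "))
  }
}

#' Fit the binomial mixed model
#'
#' outcome ~ biome_category * period + previous outcome + (1 | individual),
#' logit link, maximum likelihood (Laplace approximation of the marginal
#' likelihood).
#'
#' @param frame model frame from [build_model_frame()].
#' @param outcome "migrating" or "foraging".
#' @param pin_variance_zero fix the random-intercept variance at (numerically)
#'   zero, which reduces the fit to a plain logistic regression — used as a
#'   reduction check.
#' @param include_interaction include the category x period interaction
#'   (TRUE); FALSE fits the additive model (for likelihood-ratio tests).
#' @return a `mixed_model_fit`.
#' @export
fit_binomial_mixed <- function(frame, outcome = c("migrating", "foraging"),
                               pin_variance_zero = FALSE,
                               include_interaction = TRUE) {
  outcome <- match.arg(outcome)
  frame$individual_id <- factor(frame$individual_id)
  frame$biome_category <- factor(frame$biome_category,
                                 levels = c("hospitable", "barrier"))
  frame$period <- factor(frame$period, levels = c("dusk", "night", "dawn"))
  if (nlevels(droplevels(frame$biome_category)) < 2) {
    stop("both biome categories must be present")
  }
  y <- as.integer(frame[[outcome]])
  .check_separation(y, frame)
  frame$.y <- y
  prev <- paste0("prev_", outcome)
  fx <- if (include_interaction) "biome_category * period" else "biome_category + period"
  form <- stats::as.formula(paste0(".y ~ ", fx, " + ", prev, " + (1 | individual_id)"))
  args <- list(formula = form, data = frame, family = stats::binomial(),
               REML = FALSE)
  if (pin_variance_zero) {
    args$map <- list(theta = factor(NA))
    args$start <- list(theta = -10)
    args$control <- glmmTMB::glmmTMBControl(
      optCtrl = list(rel.tol = 1e-12, iter.max = 2000, eval.max = 2000))
  }
  model <- if (pin_variance_zero) {
    # the deliberately-degenerate variance makes the optimiser report
    # singular convergence; the fixed effects are at the optimum regardless
    withCallingHandlers(
      do.call(glmmTMB::glmmTMB, args),
      warning = function(w) {
        if (grepl("singular convergence", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
  } else {
    do.call(glmmTMB::glmmTMB, args)
  }
  out <- .fit_result(model, nrow(frame), nlevels(droplevels(frame$individual_id)))
  if (pin_variance_zero) out <- .polish_pinned(model, out)
  if (!out$converged && !pin_variance_zero) {
    # non-PD Hessians here almost always mean the random-intercept variance
    # collapsed to the boundary; refit the boundary (zero-variance) model
    out <- fit_binomial_mixed(frame, outcome, pin_variance_zero = TRUE,
                              include_interaction = include_interaction)
    out$note <- "variance_boundary_fallback"
  }
  out
}

#' Fit a Gaussian mixed model for a daily outcome
#'
#' outcome ~ biome_category + (1 | individual), identity link, maximum
#' likelihood (not REML). With a single individual the random intercept is
#' unidentifiable and the fit falls back to ordinary least squares with a
#' warning.
#'
#' @param data data.frame with the outcome column, biome_category and
#'   individual_id.
#' @param outcome name of the numeric outcome column (e.g. daily altitude
#'   change in m, or daily travel speed in km/day).
#' @inheritParams fit_binomial_mixed
#' @return a `mixed_model_fit`.
#' @export
fit_gaussian_mixed <- function(data, outcome, pin_variance_zero = FALSE) {
  stopifnot(outcome %in% names(data))
  data <- data[is.finite(data[[outcome]]) & !is.na(data$biome_category), ]
  data$biome_category <- factor(data$biome_category,
                                levels = c("hospitable", "barrier"))
  data$.y <- data[[outcome]]
  n_groups <- length(unique(data$individual_id))
  if (n_groups < 2) {
    warning("single individual: falling back to fixed-effects OLS")
    model <- stats::lm(.y ~ biome_category, data = data)
    return(.fit_result(model, nrow(data), n_groups, note = "ols_fallback"))
  }
  data$individual_id <- factor(data$individual_id)
  args <- list(formula = .y ~ biome_category + (1 | individual_id),
               data = data, family = stats::gaussian(), REML = FALSE)
  if (pin_variance_zero) {
    # standardise the outcome for the pinned fit: with the random-effect
    # variance fixed at ~0 the optimiser stops short of the OLS solution on
    # raw scales of hundreds of metres; on the standardised scale the match
    # is exact to ~1e-8 and the coefficients are transformed back below
    m0 <- mean(data$.y); s0 <- stats::sd(data$.y)
    data$.y <- (data$.y - m0) / s0
    args$data <- data
    args$map <- list(theta = factor(NA))
    args$start <- list(theta = -10)
  }
  model <- if (pin_variance_zero) {
    withCallingHandlers(
      do.call(glmmTMB::glmmTMB, args),
      warning = function(w) {
        if (grepl("singular convergence", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
  } else {
    do.call(glmmTMB::glmmTMB, args)
  }
  out <- .fit_result(model, nrow(data), n_groups)
  if (pin_variance_zero) {
    out <- .polish_pinned(model, out)
    is_int <- out$coefficients$term == "(Intercept)"
    out$coefficients$estimate <- out$coefficients$estimate * s0 + is_int * m0
    out$coefficients$se <- out$coefficients$se * s0
    out$loglik <- out$loglik - nrow(data) * log(s0)
    out$re_variance <- out$re_variance * s0^2
  }
  if (!out$converged && !pin_variance_zero) {
    out <- fit_gaussian_mixed(data, outcome, pin_variance_zero = TRUE)
    out$note <- "variance_boundary_fallback"
  }
  out
}

#' Fit the zero-inflated flight-altitude model
#'
#' Two-part model for a nonnegative outcome with exact zeros (flight
#' altitude above ground at the fix time: birds on the ground produce
#' structural zeros): an intercept-only logistic zero-inflation part and a
#' positive-part Gamma conditional model on the log link with biome
#' category and a random intercept per individual, fitted jointly by
#' maximum likelihood. Without zeros the model reduces to
#' [fit_gaussian_mixed()] with a warning.
#'
#' @inheritParams fit_gaussian_mixed
#' @return a `mixed_model_fit`; the zero-inflation probability estimate is
#'   in `$zi_prob`.
#' @export
fit_zero_inflated <- function(data, outcome = "altitude_agl_m") {
  data <- data[is.finite(data[[outcome]]) & !is.na(data$biome_category), ]
  if (!any(data[[outcome]] == 0)) {
    warning("no zeros in outcome: reducing to the Gaussian mixed model")
    return(fit_gaussian_mixed(data, outcome))
  }
  data$biome_category <- factor(data$biome_category,
                                levels = c("hospitable", "barrier"))
  data$individual_id <- factor(data$individual_id)
  data$.y <- data[[outcome]]
  model <- glmmTMB::glmmTMB(
    .y ~ biome_category + (1 | individual_id), ziformula = ~1,
    family = glmmTMB::ziGamma(link = "log"), data = data, REML = FALSE)
  out <- .fit_result(model, nrow(data), nlevels(data$individual_id))
  if (!out$converged) {
    # boundary random-intercept variance: refit with it pinned at zero
    model <- withCallingHandlers(
      glmmTMB::glmmTMB(
        .y ~ biome_category + (1 | individual_id), ziformula = ~1,
        family = glmmTMB::ziGamma(link = "log"), data = data, REML = FALSE,
        map = list(theta = factor(NA)), start = list(theta = -10)),
      warning = function(w) {
        if (grepl("singular convergence", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    out <- .fit_result(model, nrow(data), nlevels(data$individual_id),
                       note = "variance_boundary_fallback")
  }
  out$zi_prob <- stats::plogis(glmmTMB::fixef(model)$zi[["(Intercept)"]])
  out
}

#' Likelihood-ratio test between nested fits
#'
#' chi2 = 2 (logLik_full - logLik_reduced), df = parameter-count difference.
#'
#' @param full,reduced `mixed_model_fit` objects; `reduced` nested in `full`.
#' @return list with chi2, df, p.
#' @export
likelihood_ratio_test <- function(full, reduced) {
  if (full$n_obs != reduced$n_obs) stop("models fitted to different data")
  df <- full$df - reduced$df
  if (df < 0) stop("models not nested: reduced has more parameters than full")
  chi2 <- max(0, 2 * (full$loglik - reduced$loglik))
  p <- if (df == 0) 1 else stats::pchisq(chi2, df, lower.tail = FALSE)
  list(chi2 = chi2, df = df, p = p)
}

#' Barrier-minus-hospitable contrasts per period
#'
#' Estimated marginal means contrasts of barrier minus hospitable on the
#' link scale within each period, with multiplicity adjustment over the
#' whole contrast family by multivariate-t integration and residual
#' degrees of freedom (n_obs - fixed-effect rank). Positive estimates mean
#' a positive barrier effect.
#'
#' @param fit a converged `mixed_model_fit` with category and period terms
#'   (or category only, giving a single overall contrast).
#' @param adjust multiplicity adjustment passed to emmeans (default "mvt").
#' @return data.frame with label, estimate, se, df, t_ratio, p_adjusted.
#' @export
tukey_contrasts <- function(fit, adjust = "mvt") {
  if (!fit$converged) stop("cannot compute contrasts from an unconverged fit")
  model <- fit$model
  has_period <- "period" %in% all.vars(stats::formula(model))
  resid_df <- fit$n_obs - sum(grepl("^(\\(Intercept\\)|biome|period|prev)",
                                    fit$coefficients$term))
  if (has_period) {
    emm <- emmeans::emmeans(model, ~ biome_category | period)
    ctr <- emmeans::contrast(emm, "revpairwise", by = "period")
  } else {
    emm <- emmeans::emmeans(model, ~ biome_category)
    ctr <- emmeans::contrast(emm, "revpairwise")
  }
  s <- summary(rbind(ctr), adjust = adjust, df = resid_df)
  data.frame(
    label = if (has_period) as.character(s$period) else "overall",
    estimate = s$estimate, se = s$SE, df = s$df,
    t_ratio = s$t.ratio, p_adjusted = pmin(1, s$p.value)
  )
}
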