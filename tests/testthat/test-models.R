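# simulate an interval-level model frame with known effects
sim_frame <- function(seed, beta_dusk = 0.7, n_ind = 6, n_per = 600,
                      re_sd = 0.3) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_ind), function(i) {
    b0 <- rnorm(1, 0, re_sd)
    period <- sample(c("dusk", "night", "dawn"), n_per, TRUE)
    cat_ <- sample(c("hospitable", "barrier"), n_per, TRUE)
    y <- integer(n_per); prev <- 0L
    for (t in seq_len(n_per)) {
      eta <- -1 + b0 + 0.5 * prev + beta_dusk * (cat_[t] == "barrier" & period[t] == "dusk")
      y[t] <- rbinom(1, 1, plogis(eta))
      prev <- y[t]
    }
    data.frame(individual_id = sprintf("i%02d", i), migrating = y == 1,
               prev_migrating = c(0L, y[-n_per]), biome_category = cat_,
               period = period)
  }))
}

test_that("the model frame lags outcomes and excludes stopover and day rows", {
  t0 <- as.POSIXct("2018-10-05 17:00:00", tz = "UTC")  # evening at lon 20
  labels <- data.frame(
    individual_id = "a", time = t0 + 0:5 * 300,
    migrating = c(FALSE, TRUE, TRUE, FALSE, FALSE, TRUE),
    foraging = c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE))
  daily <- data.frame(individual_id = "a", date = as.Date("2018-10-05"),
                      lon = 20, lat = 10, biome_category = "barrier")
  fr <- build_model_frame(labels, daily)
  # first interval dropped; prev is the outcome one step back
  expect_identical(nrow(fr), 5L)
  expect_equal(fr$prev_migrating, c(0, 1, 1, 0, 0))
  expect_equal(fr$prev_foraging, c(0, 0, 0, 1, 1))
  expect_true(all(fr$period != "day"))
  # stopover date removed entirely
  fr2 <- build_model_frame(labels, daily,
                           stopover_dates = as.Date("2018-10-05"))
  expect_identical(nrow(fr2), 0L)
  # mismatched keys are an error
  bad_daily <- transform(daily, individual_id = "zzz")
  expect_error(build_model_frame(labels, bad_daily), "key")
})

test_that("binomial mixed model recovers known coefficients", {
  fr <- sim_frame(101)
  fit <- fit_binomial_mixed(fr, "migrating")
  expect_true(fit$converged)
  expect_identical(fit$n_groups, 6L)
  co <- fit$coefficients
  get <- function(term) co$estimate[co$term == term]
  se <- function(term) co$se[co$term == term]
  expect_lt(abs(get("(Intercept)") - (-1)), 3 * se("(Intercept)"))
  expect_lt(abs(get("prev_migrating") - 0.5), 3 * se("prev_migrating"))
  expect_lt(abs(get("biome_categorybarrier") - 0.7), 3 * se("biome_categorybarrier"))
  # all-zero outcome: separation diagnostic naming a cell
  fr0 <- fr; fr0$migrating <- FALSE
  expect_error(fit_binomial_mixed(fr0, "migrating"), "separation")
})

test_that("pinning the variance reduces the fits to GLM and OLS", {
  fr <- sim_frame(102, re_sd = 0)
  fitb <- fit_binomial_mixed(fr, "migrating", pin_variance_zero = TRUE)
  ref <- stats::glm(migrating ~ biome_category * period + prev_migrating,
                    binomial(),
                    transform(fr,
                              biome_category = factor(biome_category,
                                                      c("hospitable", "barrier")),
                              period = factor(period, c("dusk", "night", "dawn"))))
  expect_lt(max(abs(fitb$coefficients$estimate - coef(ref))), 1e-4)
  set.seed(103)
  dd <- data.frame(individual_id = rep(sprintf("i%d", 1:5), each = 40),
                   biome_category = sample(c("hospitable", "barrier"), 200, TRUE))
  dd$dz_m <- 800 + 500 * (dd$biome_category == "barrier") + rnorm(200, 0, 150)
  fitg <- fit_gaussian_mixed(dd, "dz_m", pin_variance_zero = TRUE)
  refg <- stats::lm(dz_m ~ biome_category,
                    transform(dd, biome_category = factor(biome_category,
                                                          c("hospitable", "barrier"))))
  expect_lt(max(abs(fitg$coefficients$estimate - coef(refg))), 1e-4)
})

test_that("a single individual falls back to OLS with a warning", {
  set.seed(104)
  dd <- data.frame(individual_id = "only", dz_m = rnorm(60, 900, 100),
                   biome_category = sample(c("hospitable", "barrier"), 60, TRUE))
  expect_warning(fit <- fit_gaussian_mixed(dd, "dz_m"), "single individual")
  expect_identical(fit$note, "ols_fallback")
  expect_identical(fit$re_variance, 0)
})

test_that("zero inflation probability is recovered and absence reduces the model", {
  set.seed(105)
  n <- 1200
  dd <- data.frame(individual_id = rep(sprintf("i%d", 1:6), each = n / 6),
                   biome_category = sample(c("hospitable", "barrier"), n, TRUE))
  mu <- exp(6 + 0.5 * (dd$biome_category == "barrier"))
  pos <- rgamma(n, shape = 4, rate = 4 / mu)
  dd$altitude_agl_m <- ifelse(runif(n) < 0.3, 0, pos)
  fit <- fit_zero_inflated(dd)
  expect_lt(abs(fit$zi_prob - 0.30), 0.05)
  ctr <- tukey_contrasts(fit)
  expect_gt(ctr$estimate[1], 0)
  # without zeros the model reduces to the Gaussian mixed fit
  dd2 <- dd; dd2$altitude_agl_m <- pos
  expect_warning(fit2 <- fit_zero_inflated(dd2), "no zeros")
  expect_null(fit2$zi_prob)
})

test_that("likelihood-ratio tests follow the 2*delta-logLik arithmetic", {
  fr <- sim_frame(106)
  full <- fit_binomial_mixed(fr, "migrating")
  red <- fit_binomial_mixed(fr, "migrating", include_interaction = FALSE)
  lrt <- likelihood_ratio_test(full, red)
  expect_equal(lrt$chi2, 2 * (full$loglik - red$loglik))
  expect_equal(lrt$df, 2)
  expect_equal(lrt$p, pchisq(lrt$chi2, 2, lower.tail = FALSE))
  # identical models: chi2 = 0, p = 1
  same <- likelihood_ratio_test(full, full)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  # reversed nesting is rejected
  expect_error(likelihood_ratio_test(red, full), "nested")
})

test_that("contrasts report barrier minus hospitable per period", {
  fr <- sim_frame(107, beta_dusk = 0.9, n_ind = 8, n_per = 800)
  fit <- fit_binomial_mixed(fr, "migrating")
  ctr <- tukey_contrasts(fit)
  expect_identical(ctr$label, c("dusk", "night", "dawn"))
  expect_equal(ctr$t_ratio, ctr$estimate / ctr$se, tolerance = 1e-8)
  expect_true(all(ctr$p_adjusted >= 0 & ctr$p_adjusted <= 1))
  expect_lt(ctr$p_adjusted[1], 0.05)   # injected dusk effect detected
  # a single-contrast family needs no adjustment
  set.seed(108)
  dd <- data.frame(individual_id = rep(sprintf("i%d", 1:5), each = 40),
                   biome_category = sample(c("hospitable", "barrier"), 200, TRUE))
  dd$speed <- 200 + 80 * (dd$biome_category == "barrier") + rnorm(200, 0, 60)
  f1 <- fit_gaussian_mixed(dd, "speed")
  c1 <- tukey_contrasts(f1)
  raw_p <- 2 * pt(-abs(c1$t_ratio), c1$df)
  expect_equal(c1$p_adjusted, raw_p, tolerance = 1e-6)
})

test_that("fixed effects are invariant to relabelling individuals", {
  fr <- sim_frame(109)
  fit1 <- fit_binomial_mixed(fr, "migrating")
  relab <- fr
  relab$individual_id <- factor(relab$individual_id,
                                labels = rev(sprintf("z%02d", 1:6)))
  fit2 <- fit_binomial_mixed(relab, "migrating")
  expect_equal(fit1$coefficients$estimate, fit2$coefficients$estimate,
               tolerance = 1e-6)
})
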