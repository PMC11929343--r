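test_that("the 4-subject fixture solves the partial-likelihood score exactly", {
  d <- data.frame(time = c(1, 2, 3, 4), event = c(1, 1, 0, 1),
                  x = c(1, 0, 1, 0))
  fit <- fit_cox(d, "x")
  # score equation u/(u+1) + u/(u+2) = 1 has root u = sqrt(2)
  expect_equal(unname(fit$coefficients), 0.5 * log(2), tolerance = 1e-6)
  expect_equal(fit$hr$hr, sqrt(2), tolerance = 1e-6)
  expect_equal(fit$n_events, 3)
  expect_equal(fit$ties_method, "efron")
})

test_that("Cox fits match the grid-search partial-likelihood oracle", {
  fixtures <- list(
    data.frame(time = c(1, 2, 3, 4), event = c(1, 1, 0, 1), x = c(1, 0, 1, 0)),
    # ties, to exercise the Efron correction
    data.frame(time = c(1, 1, 2, 2, 3), event = c(1, 1, 1, 0, 1),
               x = c(1, 0, 1, 1, 0)),
    data.frame(time = c(2, 2, 2, 5, 6, 7), event = c(1, 1, 0, 1, 1, 0),
               x = c(0.5, -1, 2, 0, 1, -0.5)),
    # balanced label swap: estimate must be zero by symmetry
    data.frame(time = c(1, 1, 2, 2), event = c(1, 1, 1, 1), x = c(1, 0, 0, 1)),
    data.frame(time = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10),
               event = c(1, 0, 1, 1, 0, 1, 1, 0, 1, 1),
               x = c(2, 1, 0, 1, 2, 0, 1, 0, 2, 1)))
  for (d in fixtures) {
    fit <- fit_cox(d, "x")
    oracle <- cox_grid_oracle(d$time, d$event, d$x)
    expect_equal(unname(fit$coefficients), oracle, tolerance = 1e-6)
  }
  expect_equal(unname(fit_cox(fixtures[[4]], "x")$coefficients), 0,
               tolerance = 1e-8)
})

test_that("Cox fitting rejects degenerate inputs", {
  d <- data.frame(time = c(1, 2, 3, 4), event = c(1, 0, 0, 0), x = c(1, 0, 1, 0))
  expect_error(fit_cox(d, "x"), "at least 2 events")
  d2 <- data.frame(time = 1:4, event = c(1, 1, 1, 0), x = rep(1, 4))
  expect_error(fit_cox(d2, "x"), "constant")
  # all events in one stratum of a binary covariate: monotone likelihood
  d3 <- data.frame(time = c(1, 2, 3, 10, 11, 12), event = c(1, 1, 1, 0, 0, 0),
                   x = c(1, 1, 1, 0, 0, 0))
  expect_error(fit_cox(d3, "x"), "separation")
})

test_that("the Schoenfeld test is calibrated under PH and detects violations", {
  rej_null <- mean(vapply(1:200, function(r) {
    d <- sim_ph_cohort(1000, beta = 0.3, seed = 9000 + r)
    schoenfeld_test(fit_cox(d, "x"))$p[1] < 0.05
  }, logical(1)))
  expect_gte(rej_null, 0.03)
  expect_lte(rej_null, 0.07)
  # a hazard ratio that reverses sign mid-follow-up is caught
  rej_tv <- mean(vapply(1:40, function(r) {
    d <- sim_reversal_cohort(2000, seed = 9500 + r)
    schoenfeld_test(fit_cox(d, "x"))$p[1] < 0.05
  }, logical(1)))
  expect_gt(rej_tv, 0.5)
  # the global row is present
  tab <- schoenfeld_test(fit_cox(sim_ph_cohort(300, 0.3, 1), "x"))
  expect_true("GLOBAL" %in% tab$term)
})

test_that("incidence summaries add up and are order/grouping consistent", {
  d <- data.frame(time = c(2, 4, 6, 8), event = c(1, 0, 1, 1),
                  g = c("a", "a", "b", "b"))
  overall <- incidence_summary(d)
  expect_equal(overall$person_years, 20)
  expect_equal(overall$events, 3)
  expect_equal(overall$rate_per_1000py, 150)
  by_g <- incidence_summary(d, "g")
  expect_equal(sum(by_g$person_years), overall$person_years)
  expect_equal(sum(by_g$events), overall$events)
  expect_equal(sum(by_g$n_subjects), overall$n_subjects)
  shuffled <- incidence_summary(d[c(3, 1, 4, 2), ], "g")
  expect_equal(shuffled, by_g)
  # one subject, two years of follow-up, one event: 500 per 1000 PY
  one <- incidence_summary(data.frame(time = 2, event = 1))
  expect_equal(one$rate_per_1000py, 500)
  # a group with no events has rate zero
  zero <- incidence_summary(data.frame(time = c(1, 1), event = c(0, 0),
                                       g = "a"), "g")
  expect_equal(zero$rate_per_1000py, 0)
})

test_that("linear mediator screening matches the normal-equations oracle", {
  # deterministic mediator: coefficient recovered exactly, p ~ 0
  d <- data.frame(expo = factor(rep(c("low", "high"), each = 20),
                                levels = c("low", "high")))
  d$bmi <- 2 * (d$expo == "high") + seq(0, 0.001, length.out = 40)
  sc <- screen_mediators_obs(d, "bmi", "expo")
  expect_equal(sc$contrasts$estimate, 2, tolerance = 1e-3)
  expect_lt(sc$contrasts$p, 1e-20)
  # 6-point hand dataset against the direct matrix solve
  d6 <- data.frame(y = c(1.2, 0.7, 2.9, 3.1, 1.8, 2.2),
                   x = c(0, 0, 1, 1, 0, 1),
                   z = c(0.3, -0.2, 0.5, 0.1, 0.0, -0.4))
  sc6 <- screen_mediators_obs(d6, "y", "x", "z")
  cf <- wls_oracle(cbind(1, d6$x, d6$z), d6$y, rep(1, 6))
  expect_equal(sc6$contrasts$estimate, cf[2], tolerance = 1e-10)
  # independence: rejection at the nominal rate across replicates
  rej <- mean(vapply(1:200, function(r) {
    set.seed(6800 + r)
    dd <- data.frame(x = rbinom(120, 1, 0.4), m = rnorm(120))
    screen_mediators_obs(dd, "m", "x")$contrasts$p < 0.05
  }, logical(1)))
  expect_gte(rej, 0.02)
  expect_lte(rej, 0.08)
  # collinearity is an error naming the aliased term
  dc <- data.frame(x = rnorm(30)); dc$m <- rnorm(30); dc$x2 <- 2 * dc$x
  expect_error(screen_mediators_obs(dc, "m", "x", "x2"), "x2")
})

test_that("difference-method mediation recovers a planted mediated fraction", {
  cs <- simulate_cohort(cohort_sim_config(n_subjects = 8000,
    exposure_prevalence = 0.3, hr_direct = exp(0.4),
    mediator_effect_on_hazard = 0.4, exposure_effect_on_mediator = 0.5,
    baseline_scale = 100, censor_time = 12, confounder_count = 3, seed = 31))
  dm <- difference_method(cs$records, "exposure", "mediator",
                          covariates = c("z1", "z2", "z3"),
                          n_boot = 80, seed = 2)
  # the reported pm is the difference formula applied to its own betas
  expect_equal(dm$pm_untruncated,
               (dm$beta_total - dm$beta_direct) / dm$beta_total,
               tolerance = 1e-12)
  truth <- cs$truth$pm   # 0.5 * 0.4 / (0.4 + 0.5*0.4) = 1/3
  expect_lt(abs(dm$pm - truth), 0.15)
  expect_false(dm$truncated)
  expect_true(dm$pm_ci95[1] < dm$pm && dm$pm < dm$pm_ci95[2])
  # identical seed reproduces the bootstrap interval exactly
  dm2 <- difference_method(cs$records, "exposure", "mediator",
                           covariates = c("z1", "z2", "z3"),
                           n_boot = 80, seed = 2)
  expect_identical(dm$pm_ci95, dm2$pm_ci95)
})

test_that("suppression yields a truncated zero PM and the hr scale is available", {
  # mediator tracks exposure but protects against the event: adjusting for
  # it pushes the direct effect above the total -> negative difference
  set.seed(77)
  n <- 6000
  x <- rbinom(n, 1, 0.4)
  m <- x + rnorm(n, sd = 0.3)
  T <- rexp(n, 0.05 * exp(0.6 * x - 0.3 * m))
  d <- data.frame(time = pmin(T, 15), event = as.integer(T <= 15),
                  x = x, med = m)
  dm <- difference_method(d, "x", "med", n_boot = 60, seed = 3)
  expect_true(dm$truncated)
  expect_equal(dm$pm, 0)
  expect_lt(dm$pm_untruncated, 0)
  dm_hr <- difference_method(d, "x", "med", n_boot = 20, seed = 3,
                             pm_scale = "hr")
  expect_equal(dm_hr$pm_scale, "hr")
})
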