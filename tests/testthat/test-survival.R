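test_that("the product-limit estimator handles the elementary cases", {
  km <- km_estimate(c(2, 3, 4), c(1, 0, 0))
  expect_equal(km_risk_at(km, 2), 1 / 3)
  expect_equal(km_risk_at(km, 1.9), 0)

  km0 <- km_estimate(c(5, 6, 7), c(0, 0, 0))
  expect_equal(km_risk_at(km0, c(1, 6, 10)), c(0, 0, 0))

  # uncensored data: KM equals the empirical survival function
  set.seed(1)
  t_ <- sample(1:50, 200, TRUE)
  km2 <- km_estimate(t_, rep(1, 200))
  for (tt in c(5, 20, 45)) {
    expect_equal(km_risk_at(km2, tt), mean(t_ <= tt))
  }
  # survival is non-increasing, starts at 1
  expect_true(all(diff(km2$curve$surv) <= 1e-12))
  expect_lte(km2$curve$surv[1], 1)
})

test_that("KM matches the exponential closed form on simulated data", {
  set.seed(2)
  lam <- 0.1
  n <- 5000
  km <- km_estimate(rexp(n, lam), rep(1, n))
  t0 <- 5
  truth <- 1 - exp(-lam * t0)
  se <- sqrt(truth * (1 - truth) / n)
  expect_lt(abs(km_risk_at(km, t0) - truth), 3 * se)
})

test_that("monthly rates follow the definition with a clamped interval", {
  entry <- rep(as.Date("2001-01-01"), 1000)
  end <- rep(as.Date("2001-03-01"), 1000)
  ev <- as.Date(c("2001-01-10", "2001-01-20"))
  mr <- monthly_rates(ev, entry, end)
  jan <- mr[month == as.Date("2001-01-01")]
  expect_equal(jan$n_at_risk, 1000L)
  expect_equal(jan$rate_per_1000, 2)
  feb <- mr[month == as.Date("2001-02-01")]
  expect_equal(feb$rate_per_1000, 0)
  expect_equal(feb$lo, 0)
  # at-risk rule: overlap with any day of the month
  mr2 <- monthly_rates(as.Date(character()), as.Date("2001-01-31"),
                       as.Date("2001-02-01"))
  expect_equal(mr2$n_at_risk, 1L)
})

test_that("monthly rates recover a stationary hazard", {
  set.seed(3)
  lam <- 3e-4
  n <- 3000
  entry <- rep(as.Date("2001-01-01"), n)
  t_ev <- rexp(n, lam)
  end_admin <- 365 * 4
  ev_day <- ifelse(t_ev < end_admin, floor(t_ev), NA)
  end <- entry + ifelse(is.na(ev_day), end_admin, ev_day)
  mr <- monthly_rates(entry[!is.na(ev_day)] + ev_day[!is.na(ev_day)],
                      entry, end)
  mr <- mr[-c(1, .N)]  # trim partial edge months
  expected <- 1000 * (1 - exp(-30.44 * lam))
  se <- sd(mr$rate_per_1000) / sqrt(nrow(mr))
  expect_lt(abs(mean(mr$rate_per_1000) - expected), 3 * se)
})

test_that("loess smoothing reproduces lines and reduces noise", {
  x <- seq(0, 10, length.out = 60)
  y_lin <- 2 + 3 * x
  expect_lt(max(abs(loess_smooth(x, y_lin) - y_lin)), 1e-8)
  y_const <- rep(4, 60)
  expect_lt(max(abs(loess_smooth(x, y_const) - 4)), 1e-8)
  set.seed(4)
  truth <- sin(x)
  noisy <- truth + rnorm(60, 0, 0.4)
  sm <- loess_smooth(x, noisy, span = 0.3)
  expect_lt(mean((sm - truth)^2), mean((noisy - truth)^2))
})

test_that("counting-process rows split at changes and conserve time", {
  fu <- data.frame(patient_id = 1L, entry = d_(0), end = d_(300))
  # no state changes, death at day 300
  rows <- build_counting_process(fu, states = NULL,
                                 outcomes = data.frame(patient_id = 1L,
                                                       date = d_(300)))
  expect_equal(nrow(rows), 1L)
  expect_equal(c(rows$start, rows$stop, rows$event), c(0, 300, 1))

  # therapy change at day 100, censored at 200
  fu2 <- data.frame(patient_id = 1L, entry = d_(0), end = d_(200))
  st <- data.frame(patient_id = 1L, start = d_(c(0, 100)),
                   end = d_(c(100, 200)),
                   state = c("none", "aspirin_mono"))
  rows2 <- build_counting_process(fu2, st, outcomes = data.frame(
    patient_id = integer(), date = d_(integer())))
  expect_equal(rows2$start, c(0, 100))
  expect_equal(rows2$stop, c(100, 200))
  expect_equal(rows2$state, c("none", "aspirin_mono"))
  expect_equal(rows2$event, c(0L, 0L))

  # outcome on the entry day gets half a day of exposure
  rows3 <- build_counting_process(fu, states = NULL,
                                  outcomes = data.frame(patient_id = 1L,
                                                        date = d_(0)))
  expect_equal(c(rows3$start, rows3$stop, rows3$event), c(0, 0.5, 1))
})

test_that("row durations sum to follow-up on random simulated histories", {
  ehr <- simulate_ehr(sim_config(n_patients = 300, seed = 17))
  cl <- default_codelist()
  co <- build_cohort(ehr, cl)
  fu <- co[, .(patient_id, entry = entry_date, end = end_of_follow_up)]
  tl <- therapy_timeline(build_episodes(ehr$prescriptions, codelist = cl), fu)
  ev <- phenotype_bleeding(ehr, cl)
  oc <- first_events(ev)[, .(patient_id, date = first_any_date)]
  rows <- build_counting_process(fu, tl, oc,
                                 fixed = co[, .(patient_id, sex)])
  agg <- rows[, .(dur = sum(stop - start), n_ev = sum(event)),
              by = patient_id]
  m <- fu[agg, on = "patient_id"]
  oc2 <- oc[!is.na(date)]
  m <- oc2[m, on = "patient_id"]
  exp_dur <- as.numeric(m$end - m$entry)
  has_ev <- !is.na(m$date) & m$date <= m$end
  exp_dur[has_ev] <- pmax(as.numeric(m$date - m$entry)[has_ev], 0.5)
  expect_equal(m$dur, exp_dur)
  # one terminal event row per patient with an in-window outcome
  expect_equal(sum(m$n_ev), sum(has_ev))
  expect_true(all(rows[event == 1,
                       .N == 1 && stop == max(stop), by = patient_id]$V1))
})

test_that("the Cox fit matches a grid-search oracle on tiny data", {
  # distinct event times, both exposure groups failing throughout follow-up,
  # so the partial-likelihood maximum is finite and unique
  cases <- list(
    data.table::data.table(
      patient_id = 1:8, start = 0,
      stop = c(2.1, 3.2, 4.3, 6.4, 7.5, 8.6, 9.7, 11.8),
      event = c(1, 0, 1, 1, 0, 1, 1, 0),
      x = c(0, 1, 1, 0, 0, 1, 0, 1)),
    data.table::data.table(
      patient_id = 1:10, start = 0,
      stop = c(1.5, 2.5, 3.5, 4.5, 5.5, 6.5, 7.5, 8.5, 9.5, 10.5),
      event = c(1, 1, 0, 1, 1, 1, 0, 1, 1, 0),
      x = c(1, 0, 1, 1, 0, 1, 0, 0, 1, 0)),
    # delayed entry: a counting-process-specific risk set
    data.table::data.table(
      patient_id = 1:6, start = c(0, 0, 1, 2, 0, 3),
      stop = c(4.1, 5.2, 6.3, 7.4, 8.5, 9.6),
      event = c(1, 0, 1, 1, 1, 0),
      x = c(1, 1, 0, 1, 0, 0)))
  for (rows in cases) {
    fit <- cox_td_fit(rows, "x")
    oracle <- optimize(function(b) oracle_partial_loglik(rows, b),
                       c(-5, 5), maximum = TRUE, tol = 1e-9)$maximum
    expect_lt(abs(fit$table$coef - oracle), 1e-4)
  }
})

test_that("degenerate designs are rejected", {
  rows <- data.table::data.table(patient_id = 1:4, start = 0, stop = 1:4,
                                 event = c(1, 0, 1, 0), x = 1)
  expect_error(cox_td_fit(rows, "x"), "zero variance")
  expect_error(cox_td_fit(rows, "nope"), "not in rows")
})

test_that("Efron and Breslow tie handling are both available and differ", {
  rows <- data.table::data.table(
    patient_id = 1:8, start = 0, stop = c(5, 5, 5, 8, 8, 9, 10, 11),
    event = c(1, 1, 0, 1, 1, 0, 1, 0), x = c(1, 0, 1, 1, 0, 0, 1, 0))
  fe <- cox_td_fit(rows, "x", ties = "efron")
  fb <- cox_td_fit(rows, "x", ties = "breslow")
  expect_false(isTRUE(all.equal(fe$table$coef, fb$table$coef)))
})

test_that("recurrent-bleeding clocks restart at the first non-fatal event", {
  ev <- data.table::data.table(
    patient_id = c(1L, 1L, 2L),
    event_id = 1:3, event_date = d_(c(100, 200, 50)),
    category = c("hospitalised", "primary_care", "hospitalised_ms"),
    prognostic_class = c("II", "III", "I"))
  fu <- data.frame(patient_id = 1:2, entry = d_(0), end = d_(400))
  rc <- recurrent_bleed_curves(ev, fu)
  # patient 1 recurs after 100 days; patient 2 is censored at 350
  expect_equal(rc$all$curve[n_event == 1, time], 100)
  expect_equal(rc$all$n, 2L)
  expect_equal(rc$ms$n, 1L)
  expect_equal(sum(rc$ms$curve$n_event), 0L)
})

test_that("an elevated post-bleed hazard raises recurrence incidence", {
  cfg <- sim_config(n_patients = 4000, seed = 23, hr_recurrent_bleed = 2.5,
                    record_jitter_days = 0,
                    p_record_in_source = c(primary_care = 1, hospital = 1,
                                           death_registry = 0.01),
                    p_uncoded_bleed = 0, p_false_bleed_code = 0)
  ehr <- simulate_ehr(cfg)
  cl <- default_codelist()
  ev <- phenotype_bleeding(ehr, cl, infer = FALSE)
  co <- build_cohort(ehr, cl)
  fu <- co[, .(patient_id, entry = entry_date, end = end_of_follow_up)]
  rc <- recurrent_bleed_curves(ev, fu)
  fe <- first_events(ev)[fu, on = "patient_id"]
  fe[, time := as.numeric(data.table::fifelse(is.na(first_any_date), end,
                                              first_any_date) - entry)]
  fe[, flag := as.integer(!is.na(first_any_date))]
  km_first <- km_estimate(fe$time, fe$flag)
  horizon <- 365 * 2
  expect_gt(km_risk_at(rc$all, horizon), km_risk_at(km_first, horizon))
})

test_that("diagnostic metrics agree with the exact binomial formulas", {
  m <- diagnostic_metrics(10, 0, 0, 10)
  expect_equal(m$estimate, rep(1, 4))
  m2 <- diagnostic_metrics(1, 1, 1, 1)
  expect_equal(m2$estimate, rep(0.5, 4))
  m3 <- diagnostic_metrics(15, 2, 5, 100)
  expect_equal(m3[metric == "ppv", estimate], 15 / 17)
  ci <- oracle_cp_interval(15, 17)
  expect_equal(m3[metric == "ppv", lower], ci[1], tolerance = 1e-8)
  expect_equal(m3[metric == "ppv", upper], ci[2], tolerance = 1e-8)
  # zero denominators give NA rather than an error
  m4 <- diagnostic_metrics(0, 0, 0, 5)
  expect_true(is.na(m4[metric == "ppv", estimate]))
})

test_that("log(-log) curves transform the KM estimate; trends are detected", {
  set.seed(8)
  n <- 400
  rows <- data.table::data.table(patient_id = 1:n, start = 0,
                                 stop = rexp(n, 0.05),
                                 event = rbinom(n, 1, 0.7),
                                 x = rbinom(n, 1, 0.5))
  fit <- cox_td_fit(rows, "x")
  pd <- ph_diagnostics(fit, rows, group = "x")
  expect_true(all(c("term", "p") %in% names(pd$schoenfeld)))
  # single-group log(-log) equals the transform of the KM curve
  g0 <- rows[x == 0]
  km <- km_estimate(g0$stop, g0$event)
  ll0 <- pd$loglog[group == "0"]
  keep <- km$curve$surv > 0 & km$curve$surv < 1
  expect_equal(ll0$loglog, log(-log(km$curve$surv[keep])), tolerance = 1e-8)

  # a strongly time-varying effect is flagged
  set.seed(9)
  n2 <- 4000
  x <- rbinom(n2, 1, 0.5)
  # hazard ratio flips over time for the exposed group
  t1 <- rexp(n2, 0.02 * exp(2.5 * x))
  t2 <- 30 + rexp(n2, 0.02 * exp(-2.5 * x))
  tt <- ifelse(t1 < 30, t1, t2)
  rows2 <- data.table::data.table(patient_id = 1:n2, start = 0, stop = tt,
                                  event = 1L, x = x)
  fit2 <- cox_td_fit(rows2, "x")
  pd2 <- ph_diagnostics(fit2)
  expect_lt(pd2$schoenfeld[term == "x", p], 0.01)
})

test_that("Schoenfeld trend p-values are well calibrated under the null", {
  set.seed(10)
  pvals <- replicate(120, {
    n <- 150
    rows <- data.frame(patient_id = 1:n, start = 0, stop = rexp(n, 0.1),
                       event = 1L, x = rnorm(n))
    fit <- cox_td_fit(rows, "x")
    ph_diagnostics(fit)$schoenfeld$p[1]
  })
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})
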