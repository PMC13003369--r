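test_that("with no censoring and no deaths the CIF is the empirical counting estimate", {
  set.seed(14)
  tt <- round(runif(200, 0.1, 9.9), 3)
  fu <- fu_table(tt, rep(1L, 200),
                 site = sample(outcome_sites("mof"), 200, replace = TRUE))
  cif <- aalen_johansen(fu, "mof")
  for (t in c(1, 2.5, 5, 8)) {
    expect_equal(as.numeric(observed_probability_at(cif, t)),
                 100 * mean(tt <= t), tolerance = 1e-12)
  }
})

test_that("with deaths only, fracture incidence is zero and death incidence empirical", {
  tt <- c(0.5, 1, 2, 4, 7)
  fu <- fu_table(tt, rep(2L, 5))
  cif <- aalen_johansen(fu, "all")
  expect_true(all(cif$cif_event == 0))
  expect_equal(as.numeric(observed_probability_at(cif, 3, what = "death")),
               100 * mean(tt <= 3), tolerance = 1e-12)
})

test_that("with a single cause the estimator reduces to one minus Kaplan-Meier", {
  co <- generate_cohort(simulation_config(
    n = 400L, seed = 55L,
    death_hazard_coefs = c(log_rate0 = -Inf, age_slope = 0.09)))
  fu <- resolve_followups(co, "all")
  cif <- aalen_johansen(fu, "all")
  km <- survival::survfit(survival::Surv(fu$time, fu$event == 1L) ~ 1)
  at <- match(km$time, cif$time)
  expect_equal(cif$cif_event[at], 1 - km$surv, tolerance = 1e-12)
})

test_that("six-subject hand-computed example is reproduced exactly", {
  # times 1..6: fracture, death, censor, fracture, death, censor
  fu <- fu_table(1:6, c(1L, 2L, 0L, 1L, 2L, 0L))
  cif <- aalen_johansen(fu, "all")
  # by hand: CIF_f(1) = 1/6; CIF_d(2) = 1/6; at t=4 CIF_f += (4/6)(1/3);
  # at t=5 CIF_d += (4/9)(1/2)
  expect_equal(cif$cif_event[cif$time == 1], 1 / 6, tolerance = 1e-12)
  expect_equal(cif$cif_event[cif$time == 4], 7 / 18, tolerance = 1e-12)
  expect_equal(cif$cif_death[cif$time == 5], 7 / 18, tolerance = 1e-12)
  obs <- observed_probability_at(cif, 10)
  expect_equal(as.numeric(obs), 100 * 7 / 18, tolerance = 1e-12)
  expect_true(attr(obs, "truncated"))
})

test_that("step evaluation carries the last value forward and is zero at t=0", {
  cif <- structure(data.frame(time = c(0, 1, 5, 9),
                              cif_event = c(0, 0.02, 0.07, 0.11),
                              cif_death = 0, surv = 1,
                              se = 0, variance = 0, n_at_risk = 10),
                   class = c("cif_estimate", "data.frame"))
  at10 <- observed_probability_at(cif, 10)
  expect_equal(as.numeric(at10), 11.0)
  expect_true(attr(at10, "truncated"))
  expect_equal(as.numeric(observed_probability_at(cif, 0)), 0)
  expect_equal(as.numeric(observed_probability_at(cif, 3)), 2.0)
})

test_that("degenerate inputs are rejected with informative errors", {
  expect_error(aalen_johansen(fu_table(numeric(0), integer(0)), "all"),
               "empty")
  expect_error(aalen_johansen(fu_table(c(1, -2, 3), c(1L, 0L, 0L)), "all"),
               "positive")
})

test_that("probability components always sum to one", {
  co <- shared_cohort()
  for (o in c("mof", "hip", "all")) {
    cif <- aalen_johansen(resolve_followups(co, o), o)
    expect_true(all(abs(cif$cif_event + cif$cif_death + cif$surv - 1) < 1e-10))
    expect_true(all(diff(cif$cif_event) >= -1e-12))
    expect_true(all(diff(cif$cif_death) >= -1e-12))
    expect_true(all(diff(cif$surv) <= 1e-12))
  }
})

test_that("incident filter suppresses prevalent-site codes and keeps new sites", {
  ev <- data.frame(
    patient_id = c("A", "A", "B", "C", "C"),
    date = c(-30, 40, 35, -100, 60),
    site = c("hip", "hip", "spine", "forearm", "hip"))
  idx <- data.frame(patient_id = c("A", "B", "C"), index_date = c(0, 0, 0))
  out <- incident_filter(ev, idx, washout_days = 180)
  expect_false("A" %in% out$patient_id)        # hip re-coded 70 days later
  expect_equal(out$site[out$patient_id == "B"], "spine")
  expect_equal(out$date[out$patient_id == "B"], 35)
  expect_equal(out$site[out$patient_id == "C"], "hip")  # different site
})

test_that("incident filter collapses duplicate rows instead of erroring", {
  ev <- data.frame(patient_id = c("A", "A", "A"),
                   date = c(10, 10, 10), site = c("hip", "hip", "hip"))
  out <- incident_filter(ev, 0, washout_days = 90)
  expect_equal(nrow(out), 1L)
  expect_equal(out$date, 10)
})

test_that("the variance estimator tracks the replicate spread of the CIF", {
  # constant hazards so the true CIF is available in closed form
  m <- default_marginals()
  m$age <- c(mean = 70, sd = 1, min = 70, max = 70)
  lf <- 0.05; ld <- 0.03
  hz <- c(b0 = log(lf), b1 = 0, b2 = 0, b3 = 0, b4 = 0, b5 = 0)
  est <- se_est <- numeric(300)
  for (i in 1:300) {
    co <- generate_cohort(simulation_config(
      n = 400L, seed = 9000L + i, hazard_coefs = hz,
      death_hazard_coefs = c(log_rate0 = log(ld), age_slope = 0),
      covariate_marginals = m, censor_rate = 0.235, max_followup = 24))
    cif <- aalen_johansen(resolve_followups(co, "all"), "all")
    at5 <- observed_probability_at(cif, 5)
    est[i] <- as.numeric(at5) / 100
    se_est[i] <- attr(at5, "se_pct") / 100
  }
  truth <- lf / (lf + ld) * (1 - exp(-(lf + ld) * 5))
  mc_se <- sd(est) / sqrt(300)
  expect_lt(abs(mean(est) - truth), 3 * mc_se)
  expect_lt(abs(sd(est) / mean(se_est) - 1), 0.15)
})
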