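test_that("the standardized mean difference formula is reproduced by hand", {
  # treated values {0.1, 0.9}: mean 0.5, sd 0.4; untreated {-0.1, 0.7}:
  # mean 0.3, sd 0.4 -> SMD = (0.5 - 0.3) / 0.4 = 0.5 exactly
  pats <- data.frame(ptx = c(TRUE, TRUE, FALSE, FALSE),
                     x = c(0.1, 0.9, -0.1, 0.7))
  s <- smd_table(pats, "x")
  expect_equal(s$smd_unweighted, 0.5, tolerance = 1e-12)
})

test_that("randomized treatment is balanced before weighting and weights near two", {
  co <- shared_cohort()
  pats <- co$patients
  set.seed(17)
  pats$ptx <- runif(nrow(pats)) < 0.5
  pr <- fit_propensity(pats)
  expect_lt(max(abs(pr$smd_table$smd_unweighted)), 0.1)
  expect_lt(abs(mean(pr$weights) - 2), 0.1)
})

test_that("confounded selection is imbalanced raw and balanced after weighting", {
  co <- shared_cohort()
  pr <- fit_propensity(co)
  expect_gte(max(abs(pr$smd_table$smd_unweighted)), 0.1)
  expect_lt(max(abs(pr$smd_table$smd_weighted)), 0.1)
  expect_true(all(pr$propensity > 0 & pr$propensity < 1))
  expect_true(all(pr$weights > 0))
})

test_that("person-period expansion conserves exposure and places events last", {
  fu <- fu_table(2.5, 1L)
  pp <- person_time_expand(fu, 1.0)
  expect_equal(pp$exposure, c(1, 1, 0.5))
  expect_equal(pp$tmid, c(0.5, 1.5, 2.25))
  expect_equal(pp$event, c(0L, 0L, 1L))

  fu2 <- fu_table(0.2, 1L)
  pp2 <- person_time_expand(fu2, 1.0)
  expect_equal(nrow(pp2), 1L)
  expect_equal(pp2$exposure, 0.2)
  expect_equal(pp2$event, 1L)

  set.seed(9)
  fu3 <- fu_table(runif(1000, 0.01, 15), sample(0:2, 1000, replace = TRUE))
  pp3 <- person_time_expand(fu3, 0.5)
  tot <- tapply(pp3$exposure, pp3$patient_id, sum)
  expect_lt(max(abs(tot[fu3$patient_id] - fu3$time)), 1e-9)
  expect_equal(sum(pp3$event), sum(fu3$event == 1L))
})

test_that("a single-stratum fit recovers the closed-form event rate", {
  # D events in T person-years with every covariate at zero: the only
  # identifiable coefficient is the intercept, log(D/T)
  n <- 40
  fu <- fu_table(rep(2.5, n), rep(c(1L, 0L), c(8, n - 8)))
  pp <- person_time_expand(fu, 10)  # one row per subject
  pp$age <- 0; pp$ptx <- FALSE; pp$pct <- 0
  fit <- fit_poisson_hazard(pp)
  expect_equal(fit$beta[["intercept"]], log(8 / (2.5 * n)), tolerance = 1e-8)
  expect_equal(fit$events_fitted, fit$events_observed, tolerance = 1e-6)
})

test_that("the weighted score equation balances fitted and observed events", {
  co <- shared_cohort()
  pr <- fit_propensity(co)
  pdat <- co$patients[, c("patient_id", "age", "ptx")]
  pdat$pct <- shared_scores()$mof_pct
  pp <- person_time_expand(resolve_followups(co, "mof"), 0.5, data = pdat)
  fit <- fit_poisson_hazard(pp, weights = pr)
  expect_lt(abs(fit$events_fitted - fit$events_observed), 1e-6)
  expect_true(all(is.finite(fit$beta)))
  ev <- eigen(fit$covariance, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
  .fixture_env$hazard_fit <- fit
})

test_that("shrinking the person-period interval barely moves the treatment effect", {
  co <- shared_cohort()
  pdat <- co$patients[, c("patient_id", "age", "ptx")]
  pdat$pct <- shared_scores()$mof_pct
  fu <- resolve_followups(co, "mof")
  f1 <- fit_poisson_hazard(person_time_expand(fu, 1.0, data = pdat))
  f2 <- fit_poisson_hazard(person_time_expand(fu, 0.25, data = pdat))
  expect_lt(abs(f1$beta[["ptx"]] - f2$beta[["ptx"]]), 0.01)
})

test_that("zero events or missing columns fail loudly", {
  fu <- fu_table(rep(1, 20), rep(0L, 20))
  pp <- person_time_expand(fu, 1.0)
  pp$age <- 60; pp$ptx <- FALSE; pp$pct <- 5
  expect_error(fit_poisson_hazard(pp), "events")
  pp2 <- pp; pp2$age <- NULL
  expect_error(fit_poisson_hazard(pp2), "age")
})

test_that("hazard-ratio curves are log-linear with delta-method bands", {
  fit <- .fixture_env$hazard_fit
  skip_if(is.null(fit), "shared fit not built")
  cv <- hr_curve(fit, seq(0, 20, by = 0.5))
  # exact log-linearity: ln hr(a) + ln hr(c) = 2 ln hr((a+c)/2)
  lh <- log(cv$hr)
  expect_equal(lh[1] + lh[41], 2 * lh[21], tolerance = 1e-12)
  # at score zero the interval comes from V44 alone
  at0 <- hr_curve(fit, 0)
  se0 <- sqrt(fit$covariance["ptx", "ptx"])
  expect_equal(at0$hr, exp(fit$beta[["ptx"]]), tolerance = 1e-12)
  expect_equal(at0$ci_high, exp(fit$beta[["ptx"]] + 1.96 * se0),
               tolerance = 1e-3)
  expect_true(all(cv$ci_low <= cv$hr & cv$hr <= cv$ci_high))
})

test_that("benefit threshold detection matches an analytic crossing", {
  mk_fit <- function(b4, b5, v4, v5) {
    structure(list(beta = c(intercept = -6, t = 0, age = 0, score = 0,
                            ptx = b4, score_ptx = b5),
                   covariance = diag(c(1e-4, 1e-6, 1e-6, 1e-6, v4, v5)) |>
                     `dimnames<-`(list(c("intercept", "t", "age", "score",
                                         "ptx", "score_ptx"),
                                       c("intercept", "t", "age", "score",
                                         "ptx", "score_ptx")))),
              class = "hazard_fit")
  }
  # choose b4 so the upper 95% bound crosses 1 exactly at F = 2.9
  b5 <- -0.1; v4 <- 0.01; v5 <- 1e-4
  b4 <- -b5 * 2.9 - qnorm(0.975) * sqrt(v4 + 2.9^2 * v5)
  cv <- hr_curve(mk_fit(b4, b5, v4, v5), seq(0, 10, by = 0.5))
  expect_equal(find_threshold(cv), 3.0)
  # everywhere-significant benefit: threshold is the grid minimum
  cv2 <- hr_curve(mk_fit(-1, -0.01, 1e-6, 1e-8), seq(1, 10, by = 0.5))
  expect_equal(find_threshold(cv2), 1)
  # no benefit anywhere: absent
  cv3 <- hr_curve(mk_fit(0.2, 0.001, 1e-4, 1e-6), seq(0, 10, by = 0.5))
  expect_true(is.na(find_threshold(cv3)))
})

test_that("the interaction Wald test has the expected quantile behaviour", {
  mk <- function(b5, v55) {
    structure(list(beta = c(intercept = -6, t = 0, age = 0, score = 0,
                            ptx = -0.1, score_ptx = b5),
                   covariance = diag(c(1, 1, 1, 1, 1, v55)) |>
                     `dimnames<-`(list(c("intercept", "t", "age", "score",
                                         "ptx", "score_ptx"),
                                       c("intercept", "t", "age", "score",
                                         "ptx", "score_ptx")))),
              class = "hazard_fit")
  }
  expect_equal(interaction_test(mk(0, 1))$p, 1.0)
  it <- interaction_test(mk(qnorm(0.975) * 2, 4))
  expect_equal(it$p, 0.05, tolerance = 1e-9)
})

test_that("a strong simulated interaction is detected with high power", {
  hz <- c(b0 = -6.79, b1 = 0.01, b2 = 0.03, b3 = 0.05, b4 = -0.1, b5 = -0.05)
  reject <- logical(5)
  for (i in 1:5) {
    co <- generate_cohort(simulation_config(n = 50000L, seed = 3000L + i,
                                            hazard_coefs = hz))
    pdat <- co$patients[, c("patient_id", "age", "ptx")]
    pdat$pct <- co$truth$mof_pct
    pp <- person_time_expand(resolve_followups(co, "all"), 0.5, data = pdat)
    fit <- fit_poisson_hazard(pp)
    reject[i] <- interaction_test(fit)$p < 0.05
  }
  expect_gte(mean(reject), 0.8)
})

test_that("propensity fitting requires both arms", {
  co <- shared_cohort()
  pats <- co$patients
  pats$ptx <- TRUE
  expect_error(fit_propensity(pats), "treated and untreated")
})
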