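flat_model <- function(lf, ld) {
  surrogate_model(
    mof = list(log_rate0 = lf, age_slope = 0, bmi_slope = 0, coefs = c()),
    mortality = c(log_rate0 = ld, age_slope = 0))
}

test_that("quadrature reproduces the constant-hazard closed form", {
  # competing constant hazards: P = lf/(lf+ld) * (1 - exp(-(lf+ld)H))
  m <- flat_model(log(0.01), log(0.02))
  got <- ten_year_probability(base_patient(), m, "mof")
  want <- 100 * 0.01 / 0.03 * (1 - exp(-0.03 * 10))
  expect_equal(as.numeric(got), want, tolerance = 1e-6)
})

test_that("zero fracture hazard gives probability zero", {
  m <- flat_model(-Inf, log(0.02))
  expect_equal(as.numeric(ten_year_probability(base_patient(), m, "mof")), 0)
})

test_that("probability is monotone in adverse risk factors", {
  m <- surrogate_model()
  lo <- ten_year_probability(base_patient(), m, "mof")
  hi <- ten_year_probability(base_patient(prior_fracture = TRUE), m, "mof")
  expect_gt(hi, lo)
  # and nonincreasing in the competing mortality hazard
  m2 <- surrogate_model(mortality = c(log_rate0 = -4.40 + log(2),
                                      age_slope = 0.090))
  expect_lt(ten_year_probability(base_patient(), m2, "mof"), lo)
})

test_that("scores ignore irrelevant fields and preserve order", {
  co <- shared_cohort()
  p <- co$patients[1:50, ]
  s1 <- score_cohort(p)
  p2 <- p[rev(seq_len(nrow(p))), ]
  s2 <- score_cohort(p2)
  expect_equal(s2$mof_pct, rev(s1$mof_pct))
  p3 <- p
  p3$patient_id <- paste0("renamed_", seq_len(nrow(p)))
  expect_equal(score_cohort(p3)$mof_pct, s1$mof_pct)
})

test_that("halving the quadrature step changes scores by under 0.01 points", {
  p <- base_patient(prior_fracture = TRUE, age = 80)
  a <- ten_year_probability(p, surrogate_model(step = 0.05), "mof")
  b <- ten_year_probability(p, surrogate_model(step = 0.025), "mof")
  expect_lt(abs(as.numeric(a) - as.numeric(b)), 0.01)
})

test_that("a missing covariate fails naming the field", {
  p <- base_patient()
  p$bmi <- NULL
  expect_error(ten_year_probability(p, surrogate_model(), "mof"), "bmi")
  p2 <- base_patient()
  p2$current_smoking <- NA
  expect_error(ten_year_probability(p2, surrogate_model(), "mof"),
               "current_smoking")
})

test_that("score_cohort handles empty and duplicated cohorts", {
  expect_equal(nrow(score_cohort(shared_cohort()$patients[0, ])), 0L)
  trip <- base_patient()[c(1, 1, 1), ]
  s <- score_cohort(trip)
  expect_equal(length(unique(s$mof_pct)), 1L)
  expect_equal(length(unique(s$hip_pct)), 1L)
})

test_that("scores correlate with the true simulated fracture hazard", {
  co <- shared_cohort()
  idx <- seq_len(5000)
  rho <- stats::cor(shared_scores()$mof_pct[idx],
                    co$truth$fracture_log_rate0[idx], method = "spearman")
  expect_gt(rho, 0)
})

test_that("surrogate models round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  m <- surrogate_model(mof = list(log_rate0 = -5.4))
  write_surrogate_model(m, path)
  m2 <- read_surrogate_model(path)
  expect_equal(m2$mof$log_rate0, -5.4)
  expect_equal(ten_year_probability(base_patient(), m2, "mof"),
               ten_year_probability(base_patient(), m, "mof"),
               tolerance = 1e-12)
  expect_equal(ten_year_probability(base_patient(), m2, "hip"),
               ten_year_probability(base_patient(), m, "hip"),
               tolerance = 1e-12)
})

test_that("parental-history imputation honours its prevalence", {
  pats <- base_patient()[rep(1, 200), ]
  pats$patient_id <- sprintf("U%03d", 1:200)
  pats$parental_hip_fracture <- rep(c("unknown", "no"), each = 100)

  none <- impute_parental_history(pats, prevalence = 0, n_resamples = 3,
                                  seed = 5)
  expect_true(all(vapply(none, identical, logical(1), y = pats)))

  all_yes <- impute_parental_history(pats, prevalence = 1, n_resamples = 3,
                                     seed = 5)
  for (r in all_yes) {
    expect_true(all(r$parental_hip_fracture[1:100] == "yes"))
    expect_true(all(r$parental_hip_fracture[101:200] == "no"))
  }
  expect_error(impute_parental_history(pats, prevalence = 1.5), "prevalence")
})

test_that("imputed-positive fraction matches a binomial draw at 10%", {
  pats <- base_patient()[rep(1, 10000), ]
  pats$patient_id <- sprintf("V%05d", 1:10000)
  pats$parental_hip_fracture <- "unknown"
  res <- impute_parental_history(pats, prevalence = 0.10, n_resamples = 100,
                                 seed = 11)
  frac <- vapply(res, function(r) mean(r$parental_hip_fracture == "yes"),
                 numeric(1))
  se <- sqrt(0.1 * 0.9 / (10000 * 100))
  expect_lt(abs(mean(frac) - 0.10), 3 * se)
})
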