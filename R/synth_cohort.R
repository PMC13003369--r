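#' Default covariate marginals for a synthetic PHPT cohort
#'
#' Returns the probability tables used to draw patient covariates. The
#' defaults encode the published characteristics of a large US primary
#' hyperparathyroidism cohort (about 59 000 adults aged 40-90 identified
#' from a national EHR network): 75.2 % female, 25.0 % treated with
#' parathyroidectomy, mean age 65.9 (SD 10.8) years, and the corresponding
#' prevalences of race and ethnicity groups, inclusion decade, calcium
#' bands and comorbidities. Parental hip fracture history defaults to
#' entirely `"unknown"`, as it does in EHR extracts, which is what the
#' probabilistic-imputation sensitivity analysis exercises.
#'
#' Categorical entries are named probability vectors summing to 1;
#' continuous entries (`age`, `bmi`, `height_female`, `height_male`) are
#' truncated-normal specifications `(mean, sd, min, max)`.
#'
#' @return a named list of marginal specifications.
#' @export
default_marginals <- function() {
  list(
    age = c(mean = 65.9, sd = 10.8, min = 40, max = 90),
    sex = c(female = 0.752, male = 0.248),
    race_ethnicity = c(Asian = 1456, Black = 13636, Hispanic = 2741,
                       White = 41361) / 59194,
    inclusion_period = c(`2000s` = 2561, `2010s` = 28747,
                         `2020s` = 27886) / 59194,
    highest_calcium_band = c(lt11.5 = 44262, ge11.5 = 9494,
                             unknown = 5438) / 59194,
    parental_hip_fracture = c(yes = 0, no = 0, unknown = 1),
    bmi = c(mean = 30.3, sd = 7.2, min = 15, max = 60),
    height_female = c(mean = 162, sd = 7, min = 130, max = 200),
    height_male = c(mean = 176, sd = 7, min = 140, max = 210),
    prior_fracture = 7807 / 59194,
    current_smoking = 7638 / 59194,
    glucocorticoid_use = 186 / 59194,
    rheumatoid_arthritis = 2204 / 59194,
    secondary_osteoporosis = 11949 / 59194,
    alcohol_excess = 1840 / 59194,
    osteopenia = 7013 / 59194,
    osteoporosis = 9436 / 59194,
    ckd_stage3plus = 8881 / 59194,
    kidney_stones = 6820 / 59194,
    antiosteoporosis_med = 11972 / 59194,
    ptx = 0.250
  )
}

#' Simulation configuration for synthetic PHPT cohorts
#'
#' Bundles every knob of the synthetic-cohort generator. The defaults are
#' the package's study conditions: covariate marginals from
#' [default_marginals()], a confounded logistic surgical-selection model
#' (so inverse-probability weighting has real work to do), a log-linear
#' cause-specific fracture hazard
#' \deqn{h(t) = \exp(\beta_0 + \beta_1 t + \beta_2\,\mathrm{age} +
#'   \beta_3\,\mathrm{score} + \beta_4\,\mathrm{PTX} +
#'   \beta_5\,\mathrm{score}\times\mathrm{PTX}),}
#' with the score in percent, a Gompertz death hazard shared with the
#' surrogate calculator, and exponential loss to follow-up tuned so median
#' observed follow-up is about 2.7 years. Default hazard coefficients give
#' a marginal ten-year MOF incidence near 8 % and a PTX hazard ratio of
#' roughly 0.85-0.90 at the median MOF score.
#'
#' @param n cohort size (>= 0).
#' @param seed integer RNG seed; the whole cohort is deterministic given it.
#' @param hazard_coefs numeric length 6, `(b0, b1, b2, b3, b4, b5)` on the
#'   log-hazard scale: intercept, per-year time trend, per-year of age,
#'   per-percentage-point of MOF score, treatment main effect, and
#'   score-by-treatment interaction.
#' @param death_hazard_coefs `(log_rate0, age_slope)` of the Gompertz death
#'   hazard at the reference age of the scoring model.
#' @param censor_rate per-year exponential rate of loss to follow-up.
#' @param selection_coefs named log-odds of the treatment-assignment
#'   (surgical selection) logistic model; age is centred at 66 years. The
#'   intercept is solved internally so the expected treated fraction equals
#'   `covariate_marginals$ptx`.
#' @param covariate_marginals marginal tables, see [default_marginals()].
#' @param site_probs multinomial over fracture sites
#'   `(hip, spine, forearm, humerus, other)`.
#' @param fracture_model `"loglinear"` (default, the six-coefficient hazard
#'   above) or `"surrogate"`, in which each patient's fracture intensity is
#'   exactly the surrogate calculator's MOF cause-specific hazard — the
#'   configuration under which observed incidence matches the risk score by
#'   construction (used for self-calibration checks).
#' @param surrogate the [surrogate_model()] used to score patients inside
#'   the generator (and to define hazards when
#'   `fracture_model = "surrogate"`).
#' @param max_followup administrative end of observation in years.
#' @param sim_step piecewise-constant grid (years) used to invert the
#'   time-varying fracture hazard.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n = 10000L,
                              seed = 20260101L,
                              hazard_coefs = c(b0 = -6.79, b1 = 0.010,
                                               b2 = 0.030, b3 = 0.050,
                                               b4 = -0.100, b5 = -0.004),
                              death_hazard_coefs = c(log_rate0 = -4.40,
                                                     age_slope = 0.090),
                              censor_rate = 0.235,
                              selection_coefs = c(age = -0.035, female = 0.15,
                                                  osteopenia = 0.55,
                                                  osteoporosis = 0.55,
                                                  ckd_stage3plus = -1.10,
                                                  race_Black = -0.70,
                                                  kidney_stones = 0.35,
                                                  calcium_ge11.5 = 0.20,
                                                  current_smoking = -0.20,
                                                  secondary_osteoporosis = -0.25,
                                                  alcohol_excess = -0.50),
                              covariate_marginals = default_marginals(),
                              site_probs = c(hip = 0.15, spine = 0.30,
                                             forearm = 0.20, humerus = 0.10,
                                             other = 0.25),
                              fracture_model = c("loglinear", "surrogate"),
                              surrogate = surrogate_model(),
                              max_followup = 24,
                              sim_step = 0.1) {
  fracture_model <- match.arg(fracture_model)
  cfg <- structure(list(
    n = as.integer(n), seed = as.integer(seed),
    hazard_coefs = hazard_coefs,
    death_hazard_coefs = death_hazard_coefs,
    censor_rate = censor_rate,
    selection_coefs = selection_coefs,
    covariate_marginals = covariate_marginals,
    site_probs = site_probs / sum(site_probs),
    fracture_model = fracture_model,
    surrogate = surrogate,
    max_followup = max_followup,
    sim_step = sim_step
  ), class = "simulation_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (cfg$n < 0L) stop("n must be nonnegative")
  if (cfg$censor_rate < 0) stop("censor_rate must be nonnegative")
  if (length(cfg$hazard_coefs) != 6L)
    stop("hazard_coefs must have length 6")
  if (cfg$max_followup <= 0 || cfg$sim_step <= 0)
    stop("max_followup and sim_step must be positive")
  for (nm in c("sex", "race_ethnicity", "inclusion_period",
               "highest_calcium_band", "parental_hip_fracture")) {
    tab <- cfg$covariate_marginals[[nm]]
    if (abs(sum(tab) - 1) > 1e-9)
      stop("marginal probability table for ", nm, " does not sum to 1")
  }
  invisible(cfg)
}

# truncated-normal draw via inverse-cdf (exact, vectorized)
.rtruncnorm <- function(n, spec) {
  lo <- pnorm(spec[["min"]], spec[["mean"]], spec[["sd"]])
  hi <- pnorm(spec[["max"]], spec[["mean"]], spec[["sd"]])
  qnorm(runif(n, lo, hi), spec[["mean"]], spec[["sd"]])
}

.rcat <- function(n, tab) {
  names(tab)[1L + findInterval(runif(n), cumsum(tab) / sum(tab),
                               rightmost.closed = TRUE)]
}

.draw_patients <- function(cfg) {
  m <- cfg$covariate_marginals
  n <- cfg$n
  sex <- .rcat(n, m$sex)
  height <- ifelse(sex == "female",
                   .rtruncnorm(n, m$height_female),
                   .rtruncnorm(n, m$height_male))
  bmi <- .rtruncnorm(n, m$bmi)
  height <- round(height, 1)
  weight <- round(bmi * (height / 100)^2, 1)
  data.frame(
    patient_id = sprintf("P%07d", seq_len(n)),
    age = round(.rtruncnorm(n, m$age), 1),
    sex = sex,
    race_ethnicity = .rcat(n, m$race_ethnicity),
    height = height,
    weight = weight,
    bmi = round(weight / (height / 100)^2, 2),
    prior_fracture = runif(n) < m$prior_fracture,
    parental_hip_fracture = .rcat(n, m$parental_hip_fracture),
    current_smoking = runif(n) < m$current_smoking,
    glucocorticoid_use = runif(n) < m$glucocorticoid_use,
    rheumatoid_arthritis = runif(n) < m$rheumatoid_arthritis,
    secondary_osteoporosis = runif(n) < m$secondary_osteoporosis,
    alcohol_excess = runif(n) < m$alcohol_excess,
    osteopenia = runif(n) < m$osteopenia,
    osteoporosis = runif(n) < m$osteoporosis,
    ckd_stage3plus = runif(n) < m$ckd_stage3plus,
    kidney_stones = runif(n) < m$kidney_stones,
    highest_calcium_band = .rcat(n, m$highest_calcium_band),
    inclusion_period = .rcat(n, m$inclusion_period),
    antiosteoporosis_med = runif(n) < m$antiosteoporosis_med,
    stringsAsFactors = FALSE
  )
}

# linear predictor of the surgical-selection model (without intercept)
.selection_lp <- function(patients, coefs) {
  cf <- function(nm) if (nm %in% names(coefs)) coefs[[nm]] else 0
  cf("age") * (patients$age - 66) +
    cf("female") * (patients$sex == "female") +
    cf("osteopenia") * patients$osteopenia +
    cf("osteoporosis") * patients$osteoporosis +
    cf("ckd_stage3plus") * patients$ckd_stage3plus +
    cf("race_Black") * (patients$race_ethnicity == "Black") +
    cf("kidney_stones") * patients$kidney_stones +
    cf("calcium_ge11.5") * (patients$highest_calcium_band == "ge11.5") +
    cf("current_smoking") * patients$current_smoking +
    cf("secondary_osteoporosis") * patients$secondary_osteoporosis +
    cf("alcohol_excess") * patients$alcohol_excess
}

#' Generate a synthetic PHPT cohort with follow-up
#'
#' Draws `config$n` patients from the configured covariate marginals,
#' scores them with the surrogate calculator, assigns parathyroidectomy by
#' a confounded logistic selection model (intercept solved so the expected
#' treated fraction matches the marginal), and then simulates, per patient:
#'
#' * a marked fracture process with the configured cause-specific hazard
#'   (piecewise-constant inversion on a `sim_step` grid; fracture sites
#'   drawn from `site_probs`), allowed to produce recurrent events;
#' * a death time from the Gompertz death hazard (closed-form inversion);
#' * loss to follow-up from an exponential, capped administratively at
#'   `max_followup`.
#'
#' The returned follow-up is time-to-first-event for the all-fracture
#' outcome (event 0 = censored, 1 = fracture with a site, 2 = death). The
#' complete simulated fracture-event stream and the per-patient end of
#' observation are also returned so that outcome-specific follow-up (e.g.
#' first MOF) can be derived with [resolve_followups()] without censoring
#' patients at non-qualifying fracture sites.
#'
#' @param config a [simulation_config()].
#' @return an object of class `phpt_cohort`: a list with elements
#'   `patients`, `followups`, `events` (all fracture events:
#'   `patient_id`, `time`, `site`), `observation` (`patient_id`,
#'   `end_time`, `end_event`), `truth` (per-patient simulation ground
#'   truth: baseline fracture log-rate, scores, treatment propensity) and
#'   `config`.
#' @export
generate_cohort <- function(config = simulation_config()) {
  validate_config(config)
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old))
  set.seed(config$seed)

  empty <- function() {
    structure(list(
      patients = .draw_patients(modifyList_config(config, 0L)),
      followups = data.frame(patient_id = character(0), time = numeric(0),
                             event = integer(0), fracture_site = character(0)),
      events = data.frame(patient_id = character(0), time = numeric(0),
                          site = character(0)),
      observation = data.frame(patient_id = character(0),
                               end_time = numeric(0), end_event = integer(0)),
      truth = data.frame(patient_id = character(0)),
      config = config), class = "phpt_cohort")
  }
  if (config$n == 0L) return(empty())

  patients <- .draw_patients(config)
  scores <- score_cohort(patients, config$surrogate)

  # treatment assignment: logistic selection with calibrated intercept
  lp <- .selection_lp(patients, config$selection_coefs)
  target <- config$covariate_marginals$ptx
  c0 <- uniroot(function(c) mean(plogis(c + lp)) - target,
                interval = c(-20, 20), tol = 1e-10)$root
  prop <- plogis(c0 + lp)
  ptx <- runif(config$n) < prop
  patients$ptx <- ptx

  # per-patient fracture log-rate at t = 0 and time trend
  if (config$fracture_model == "loglinear") {
    b <- config$hazard_coefs
    for (i in seq_along(b)) {
      # -Inf is a legitimate "hazard forced to zero" surrogate; NaN/+Inf are not
      if (is.na(b[[i]]) || b[[i]] == Inf)
        stop("non-finite hazard coefficient: b", i - 1L)
    }
    log_rate0 <- b[[1]] + b[[3]] * patients$age + b[[4]] * scores$mof_pct +
      (b[[5]] + b[[6]] * scores$mof_pct) * ptx
    b1 <- b[[2]]
  } else {
    log_rate0 <- .fracture_log_hazard(patients, config$surrogate, "mof")
    b1 <- 0
  }
  if (any(!is.finite(exp(log_rate0))))
    stop("non-finite fracture hazard: coefficient overflow in b0/b2/b3/b4/b5")

  # death: Gompertz in attained age, closed-form inversion
  d <- config$death_hazard_coefs
  aref <- config$surrogate$age_ref
  A <- exp(d[[1]] + d[[2]] * (patients$age - aref))
  Ed <- rexp(config$n)
  t_death <- if (d[[2]] == 0) Ed / A else log1p(d[[2]] * Ed / A) / d[[2]]

  # marked fracture process: unit-rate representation on the transformed
  # time scale; H(t) piecewise-linear from the sim_step grid. Events are
  # simulated up to min(death, administrative end) — censoring is drawn
  # afterwards, so the latent event history is invariant to censor_rate.
  risk_end <- pmin(t_death, config$max_followup)
  grid <- seq(0, config$max_followup, by = config$sim_step)
  gmid <- grid[-length(grid)] + diff(grid) / 2
  shape <- cumsum(exp(b1 * gmid) * diff(grid))  # cumulative at grid[-1]
  shape_fun_t <- c(0, shape)                     # at grid points
  rate <- exp(log_rate0)
  # cumulative fracture hazard at the end of each patient's at-risk window
  Hend <- rate * approx(grid, shape_fun_t, xout = risk_end, rule = 2)$y
  nev <- rpois(config$n, Hend)
  ev_pat <- rep(seq_len(config$n), nev)
  events <- data.frame(patient_id = character(0), time = numeric(0),
                       site = character(0))
  if (length(ev_pat)) {
    u <- runif(length(ev_pat)) * Hend[ev_pat] / rate[ev_pat]
    # invert patient-free cumulative shape (shared across patients)
    tt <- approx(shape_fun_t, grid, xout = u, rule = 2)$y
    site <- .rcat(length(ev_pat), config$site_probs)
    o <- order(ev_pat, tt)
    events <- data.frame(patient_id = patients$patient_id[ev_pat[o]],
                         time = tt[o], site = site[o],
                         stringsAsFactors = FALSE)
    events <- events[events$time > 0, , drop = FALSE]
  }

  t_cens <- if (config$censor_rate > 0) rexp(config$n, config$censor_rate)
            else rep(Inf, config$n)
  end_time <- pmin(t_death, t_cens, config$max_followup)
  end_event <- ifelse(t_death <= pmin(t_cens, config$max_followup), 2L, 0L)

  cohort <- structure(list(
    patients = patients,
    followups = NULL,
    events = events,
    observation = data.frame(patient_id = patients$patient_id,
                             end_time = end_time, end_event = end_event,
                             stringsAsFactors = FALSE),
    truth = data.frame(patient_id = patients$patient_id,
                       fracture_log_rate0 = log_rate0,
                       mof_pct = scores$mof_pct, hip_pct = scores$hip_pct,
                       propensity = prop,
                       stringsAsFactors = FALSE),
    config = config), class = "phpt_cohort")
  cohort$followups <- resolve_followups(cohort, "all")
  cohort
}

# internal: a config copy with a different n (used for the n = 0 shortcut)
modifyList_config <- function(cfg, n) {
  cfg$n <- as.integer(n)
  cfg
}

#' Outcome-specific time-to-first-event follow-up
#'
#' Derives, from the full simulated fracture-event stream, the follow-up
#' table for a given fracture outcome: the event is the first fracture at a
#' qualifying site (MOF = hip, spine, distal forearm or proximal humerus;
#' hip = hip only; all = any recorded site), and a fracture at a
#' non-qualifying site leaves the patient at risk rather than censoring
#' them — death and loss to follow-up alone end observation.
#'
#' @param cohort a `phpt_cohort`.
#' @param outcome_def `"mof"`, `"hip"` or `"all"`.
#' @return data frame `patient_id`, `time`, `event`
#'   (0 censored / 1 fracture / 2 death), `fracture_site`.
#' @export
resolve_followups <- function(cohort, outcome_def = c("all", "mof", "hip")) {
  outcome_def <- match.arg(outcome_def)
  sites <- outcome_sites(outcome_def)
  obs <- cohort$observation
  ev <- cohort$events
  ev <- ev[ev$site %in% sites, , drop = FALSE]
  first <- ev[!duplicated(ev$patient_id), , drop = FALSE]  # events are sorted
  idx <- match(obs$patient_id, first$patient_id)
  ftime <- first$time[idx]
  fsite <- first$site[idx]
  has_fx <- !is.na(ftime) & ftime <= obs$end_time
  data.frame(
    patient_id = obs$patient_id,
    time = ifelse(has_fx, ftime, obs$end_time),
    event = ifelse(has_fx, 1L, obs$end_event),
    fracture_site = ifelse(has_fx, fsite, "none"),
    stringsAsFactors = FALSE
  )
}

#' Fracture sites defining each outcome
#'
#' @param outcome_def `"mof"`, `"hip"` or `"all"`.
#' @return character vector of qualifying sites.
#' @export
outcome_sites <- function(outcome_def = c("all", "mof", "hip")) {
  switch(match.arg(outcome_def),
         mof = c("hip", "spine", "forearm", "humerus"),
         hip = "hip",
         all = c("hip", "spine", "forearm", "humerus", "other"))
}

#' @export
print.phpt_cohort <- function(x, ...) {
  fu <- x$followups
  cat(sprintf("Synthetic PHPT cohort: %d patients (seed %d)\n",
              nrow(x$patients), x$config$seed))
  if (nrow(fu)) {
    cat(sprintf("  %.1f%% treated with PTX; median follow-up %.2f years\n",
                100 * mean(x$patients$ptx), stats::median(fu$time)))
    cat(sprintf("  first events: %d fractures, %d deaths, %d censored\n",
                sum(fu$event == 1L), sum(fu$event == 2L), sum(fu$event == 0L)))
  }
  invisible(x)
}
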