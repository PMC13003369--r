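#' Surrogate ten-year fracture-probability model
#'
#' Constructs a transparent two-cause hazard model that maps clinical risk
#' factors to ten-year probabilities of major osteoporotic fracture (MOF)
#' and hip fracture, in the spirit of FRAX-style calculators. The true
#' coefficients of proprietary clinical calculators are not public, so this
#' surrogate is an explicit cause-specific exponential (fracture) plus
#' Gompertz (mortality) model with documented coefficients. It takes the
#' same clinical inputs a clinician would supply without bone mineral
#' density: age, sex, race and ethnicity, body-mass index, prior fracture,
#' parental hip fracture, smoking, glucocorticoid use, rheumatoid
#' arthritis, secondary osteoporosis and alcohol excess.
#'
#' Default coefficients are a scenario calibration chosen so that on the
#' default synthetic cohort the population median MOF score is close to
#' 6.4 % and the median hip score close to 1.0 %, typical magnitudes for an
#' elderly, predominantly female cohort; they make no claim to reproduce
#' any proprietary calculator's output.
#'
#' @param mof named list overriding MOF fracture-hazard parameters
#'   (`log_rate0` at the reference patient, `age_slope` per year,
#'   `bmi_slope` per kg/m^2 about `bmi_ref`, and a named `coefs` vector of
#'   log-hazard increments for binary/categorical risk factors).
#' @param hip named list overriding hip fracture-hazard parameters, same
#'   structure as `mof`.
#' @param mortality numeric: Gompertz mortality log-hazard, `log_rate0`
#'   at `age_ref` and `age_slope` per year of attained age.
#' @param age_ref reference age in years for all age slopes.
#' @param horizon projection horizon in years (default 10).
#' @param step quadrature step in years for the competing-risk integral.
#' @return an object of class `surrogate_model`.
#' @seealso [ten_year_probability()], [score_cohort()]
#' @export
surrogate_model <- function(mof = list(), hip = list(), mortality = NULL,
                            age_ref = 65, horizon = 10, step = 0.05) {
  def_mof <- list(
    log_rate0 = -5.19, age_slope = 0.050, bmi_slope = -0.015, bmi_ref = 25,
    coefs = c(female = 0.35, prior_fracture = 0.60, parental_hip_fracture = 0.40,
              current_smoking = 0.25, glucocorticoid_use = 0.50,
              rheumatoid_arthritis = 0.30, secondary_osteoporosis = 0.35,
              alcohol_excess = 0.35,
              race_Asian = -0.25, race_Black = -0.50, race_Hispanic = -0.25))
  def_hip <- list(
    log_rate0 = -6.99, age_slope = 0.100, bmi_slope = -0.045, bmi_ref = 25,
    coefs = c(female = 0.30, prior_fracture = 0.60, parental_hip_fracture = 0.70,
              current_smoking = 0.45, glucocorticoid_use = 0.60,
              rheumatoid_arthritis = 0.35, secondary_osteoporosis = 0.45,
              alcohol_excess = 0.50,
              race_Asian = -0.25, race_Black = -0.50, race_Hispanic = -0.25))
  def_mort <- c(log_rate0 = -4.40, age_slope = 0.090)

  merge_cause <- function(def, user) {
    stopifnot(is.list(user))
    for (nm in names(user)) def[[nm]] <- user[[nm]]
    def
  }
  model <- structure(list(
    mof = merge_cause(def_mof, mof),
    hip = merge_cause(def_hip, hip),
    mortality = if (is.null(mortality)) def_mort else mortality,
    age_ref = age_ref, horizon = horizon, step = step
  ), class = "surrogate_model")
  if (model$horizon <= 0) stop("horizon must be positive")
  if (model$step <= 0) stop("step must be positive")
  model
}

#' @export
print.surrogate_model <- function(x, ...) {
  cat("Surrogate ten-year fracture probability model\n")
  cat(sprintf("  horizon %g years, quadrature step %g years, reference age %g\n",
              x$horizon, x$step, x$age_ref))
  cat(sprintf("  MOF baseline log-rate %.2f, hip %.2f, mortality %.2f (Gompertz slope %.3f/y)\n",
              x$mof$log_rate0, x$hip$log_rate0,
              x$mortality[["log_rate0"]], x$mortality[["age_slope"]]))
  invisible(x)
}

# covariates the surrogate requires on every patient record
.risk_fields <- c("age", "sex", "race_ethnicity", "bmi", "prior_fracture",
                  "parental_hip_fracture", "current_smoking",
                  "glucocorticoid_use", "rheumatoid_arthritis",
                  "secondary_osteoporosis", "alcohol_excess")

.check_risk_fields <- function(patients) {
  for (f in .risk_fields) {
    if (is.null(patients[[f]]))
      stop("missing required covariate: ", f)
    if (anyNA(patients[[f]]))
      stop("missing values in required covariate: ", f)
  }
  invisible(TRUE)
}

# per-patient constant fracture log-hazard under one cause of the surrogate
.fracture_log_hazard <- function(patients, model, outcome = c("mof", "hip")) {
  outcome <- match.arg(outcome)
  cz <- model[[outcome]]
  b <- cz$coefs
  cf <- function(nm) if (nm %in% names(b)) b[[nm]] else 0
  lp <- cz$log_rate0 +
    cz$age_slope * (patients$age - model$age_ref) +
    cz$bmi_slope * (patients$bmi - cz$bmi_ref) +
    cf("female") * (patients$sex == "female") +
    cf("prior_fracture") * patients$prior_fracture +
    cf("parental_hip_fracture") * (patients$parental_hip_fracture == "yes") +
    cf("current_smoking") * patients$current_smoking +
    cf("glucocorticoid_use") * patients$glucocorticoid_use +
    cf("rheumatoid_arthritis") * patients$rheumatoid_arthritis +
    cf("secondary_osteoporosis") * patients$secondary_osteoporosis +
    cf("alcohol_excess") * patients$alcohol_excess +
    cf("race_Asian") * (patients$race_ethnicity == "Asian") +
    cf("race_Black") * (patients$race_ethnicity == "Black") +
    cf("race_Hispanic") * (patients$race_ethnicity == "Hispanic")
  as.numeric(lp)
}

# Gompertz mortality hazard at attained age (age + s)
.mortality_hazard <- function(age, s, model) {
  exp(model$mortality[["log_rate0"]] +
        model$mortality[["age_slope"]] * (age + s - model$age_ref))
}

# vectorized competing-risk integral:
#   P = 100 * integral_0^H h_f(s) exp(-int_0^s (h_f + h_d)) ds
# by fixed-step trapezoid quadrature; h_f constant per patient, h_d Gompertz.
.ten_year_matrix <- function(patients, model, outcome) {
  .check_risk_fields(patients)
  n <- nrow(patients)
  if (n == 0L) return(numeric(0))
  hf <- exp(.fracture_log_hazard(patients, model, outcome))
  s <- seq(0, model$horizon, by = model$step)
  k <- length(s)
  # cumulative hazard separates: C(i, s) = a_i * R(s) + hf_i * s, with
  # a_i the patient's Gompertz level and R the reference mortality shape
  slope <- model$mortality[["age_slope"]]
  a <- .mortality_hazard(patients$age, 0, model)
  r <- exp(slope * s)
  dt <- diff(s)
  Rcum <- c(0, cumsum((r[-k] + r[-1L]) / 2 * dt))  # trapezoid of r
  C <- outer(a, Rcum) + outer(hf, s)
  # trapezoid weights for the outer integral
  wt <- c(dt[1L] / 2, (dt[-1L] + dt[-(k - 1L)]) / 2, dt[k - 1L] / 2)
  100 * hf * drop(exp(-C) %*% wt)
}

#' Ten-year fracture probability for one patient
#'
#' Projects the probability that a patient fractures within the model
#' horizon (default 10 years), treating death as a competing risk that
#' removes the patient from risk of fracture:
#' \deqn{P = 100 \int_0^H h_f(s)\, e^{-\int_0^s (h_f + h_d)\,du}\, ds,}
#' where \eqn{h_f} is the patient's cause-specific fracture hazard and
#' \eqn{h_d} a Gompertz mortality hazard in attained age. The integral is
#' evaluated by fixed-step trapezoid quadrature. An unknown parental hip
#' fracture history is treated as negative, matching the convention used
#' when the item is unavailable in electronic health records.
#'
#' @param patient a one-row data frame (or list coercible to one) carrying
#'   the clinical covariates; a missing or NA required field is an error
#'   naming the field.
#' @param model a [surrogate_model()].
#' @param outcome `"mof"` (major osteoporotic fracture: hip, spine, distal
#'   forearm or proximal humerus) or `"hip"`.
#' @return probability expressed in percent (0 to 100).
#' @examples
#' pat <- data.frame(age = 66, sex = "female", race_ethnicity = "White",
#'                   bmi = 30, prior_fracture = FALSE,
#'                   parental_hip_fracture = "no", current_smoking = FALSE,
#'                   glucocorticoid_use = FALSE, rheumatoid_arthritis = FALSE,
#'                   secondary_osteoporosis = FALSE, alcohol_excess = FALSE)
#' ten_year_probability(pat, surrogate_model(), "mof")
#' @export
ten_year_probability <- function(patient, model = surrogate_model(),
                                 outcome = c("mof", "hip")) {
  outcome <- match.arg(outcome)
  if (!is.data.frame(patient)) patient <- as.data.frame(patient)
  if (nrow(patient) != 1L) stop("patient must be a single record")
  .ten_year_matrix(patient, model, outcome)
}

#' Score a cohort with the surrogate calculator
#'
#' Vectorized, order-preserving application of [ten_year_probability()] to
#' every patient; returns both the MOF and hip probabilities in percent.
#'
#' @param patients a patient data frame as produced by [generate_cohort()],
#'   or a `phpt_cohort` object (its `patients` element is used).
#' @param model a [surrogate_model()].
#' @return data frame with columns `patient_id`, `mof_pct`, `hip_pct`.
#' @export
score_cohort <- function(patients, model = surrogate_model()) {
  if (inherits(patients, "phpt_cohort")) patients <- patients$patients
  if (nrow(patients) == 0L)
    return(data.frame(patient_id = character(0), mof_pct = numeric(0),
                      hip_pct = numeric(0)))
  data.frame(
    patient_id = patients$patient_id,
    mof_pct = .ten_year_matrix(patients, model, "mof"),
    hip_pct = .ten_year_matrix(patients, model, "hip"),
    stringsAsFactors = FALSE
  )
}

#' Probabilistic imputation of parental hip fracture history
#'
#' Parental hip fracture history is frequently unrecorded in EHR-derived
#' cohorts and is then entered as negative. To quantify the impact of that
#' assumption, this resampler independently assigns a positive history,
#' with the supplied prevalence, to every patient whose recorded history is
#' `"unknown"`, repeating the assignment across `n_resamples` datasets.
#' Downstream consumers rescore each resample and summarise across
#' resamples (see [sensitivity_calibration()]).
#'
#' @param patients patient data frame or `phpt_cohort`.
#' @param prevalence probability in \[0, 1\] that an unknown history is
#'   positive (default 0.10, a typical Western-population estimate).
#' @param n_resamples number of resampled datasets (default 100).
#' @param seed integer seed; the resample stream is deterministic given it.
#' @return a list of `n_resamples` patient data frames.
#' @export
impute_parental_history <- function(patients, prevalence = 0.10,
                                    n_resamples = 100, seed = 1L) {
  if (inherits(patients, "phpt_cohort")) patients <- patients$patients
  if (!is.numeric(prevalence) || prevalence < 0 || prevalence > 1)
    stop("prevalence must lie in [0, 1]")
  unknown <- which(patients$parental_hip_fracture == "unknown")
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old))
  set.seed(as.integer(seed))
  lapply(seq_len(n_resamples), function(i) {
    out <- patients
    if (length(unknown)) {
      pos <- unknown[runif(length(unknown)) < prevalence]
      out$parental_hip_fracture[pos] <- "yes"
    }
    out
  })
}

#' Serialize a surrogate model to YAML
#'
#' Writes every coefficient of a [surrogate_model()] to a YAML file, so a
#' scoring configuration can be archived alongside a run and reloaded with
#' [read_surrogate_model()].
#'
#' @param model a `surrogate_model`.
#' @param path output YAML file path.
#' @return `path`, invisibly.
#' @export
write_surrogate_model <- function(model, path) {
  ser <- list(
    mof = lapply(model$mof, as.list),
    hip = lapply(model$hip, as.list),
    mortality = as.list(model$mortality),
    age_ref = model$age_ref, horizon = model$horizon, step = model$step)
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' Read a surrogate model from YAML
#'
#' @param path YAML file written by [write_surrogate_model()].
#' @return a `surrogate_model`.
#' @export
read_surrogate_model <- function(path) {
  raw <- yaml::read_yaml(path)
  de <- function(x) {
    x$coefs <- unlist(x$coefs)
    x[c("log_rate0", "age_slope", "bmi_slope", "bmi_ref")] <-
      lapply(x[c("log_rate0", "age_slope", "bmi_slope", "bmi_ref")],
             as.numeric)
    x
  }
  surrogate_model(mof = de(raw$mof), hip = de(raw$hip),
                  mortality = unlist(raw$mortality),
                  age_ref = raw$age_ref, horizon = raw$horizon,
                  step = raw$step)
}

.save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
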