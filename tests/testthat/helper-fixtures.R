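# shared fixtures, memoised so expensive cohorts are built once per run

.fixture_env <- new.env(parent = emptyenv())

shared_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- generate_cohort(
      simulation_config(n = 20000L, seed = 424242L))
    .fixture_env$scores <- score_cohort(.fixture_env$cohort)
  }
  .fixture_env$cohort
}

shared_scores <- function() {
  shared_cohort()
  .fixture_env$scores
}

# one clinically unremarkable reference patient; fields overridable
base_patient <- function(...) {
  p <- data.frame(
    patient_id = "X1", age = 66, sex = "female", race_ethnicity = "White",
    height = 162, weight = 73.5, bmi = 28, prior_fracture = FALSE,
    parental_hip_fracture = "no", current_smoking = FALSE,
    glucocorticoid_use = FALSE, rheumatoid_arthritis = FALSE,
    secondary_osteoporosis = FALSE, alcohol_excess = FALSE,
    stringsAsFactors = FALSE)
  mods <- list(...)
  for (nm in names(mods)) p[[nm]] <- mods[[nm]]
  p
}

# exhaustive case-control pair counting, ties counting one half
pair_count_auc <- function(case_scores, ctrl_scores) {
  s <- 0
  for (x in case_scores)
    s <- s + sum(x > ctrl_scores) + 0.5 * sum(x == ctrl_scores)
  s / (length(case_scores) * length(ctrl_scores))
}

# follow-up table builder for hand-constructed examples
fu_table <- function(time, event, site = NULL) {
  if (is.null(site)) site <- ifelse(event == 1L, "hip", "none")
  data.frame(patient_id = sprintf("S%03d", seq_along(time)),
             time = time, event = as.integer(event), fracture_site = site,
             stringsAsFactors = FALSE)
}
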