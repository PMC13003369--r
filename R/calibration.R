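#' Decile calibration of estimated vs observed ten-year fracture risk
#'
#' Ranks patients by their estimated ten-year probability, cuts the cohort
#' into ten equal-count groups (stable sort; boundary patients fall in the
#' lower decile), and compares, per decile, the mean estimated probability
#' with the observed Aalen-Johansen cumulative incidence at the horizon
#' (95% CI from the Aalen-Johansen variance by normal approximation,
#' truncated to \[0, 100\]). The ten (estimated, observed) points are
#' summarised by an unweighted ordinary-least-squares calibration line;
#' perfect calibration has slope 1 and intercept 0.
#'
#' @param scores data frame `patient_id`, `pct` — estimated ten-year
#'   probability in percent (e.g. a column of [score_cohort()] output).
#' @param followups outcome-resolved follow-up table
#'   (see [resolve_followups()]).
#' @param outcome_def `"mof"`, `"hip"` or `"all"`.
#' @param horizon evaluation time in years (default 10).
#' @return object of class `calibration_result`: list with `deciles`
#'   (data frame `decile`, `n`, `mean_estimated_pct`, `observed_pct`,
#'   `observed_ci_low`, `observed_ci_high`), `slope`, `intercept`.
#' @export
decile_calibration <- function(scores, followups,
                               outcome_def = c("mof", "hip", "all"),
                               horizon = 10) {
  outcome_def <- match.arg(outcome_def)
  if (nrow(scores) < 10L) stop("at least 10 patients are required")
  idx <- match(scores$patient_id, followups$patient_id)
  if (anyNA(idx)) stop("scores and follow-up tables key different patients")
  fu <- followups[idx, , drop = FALSE]
  pct <- scores$pct
  if (length(unique(pct)) == 1L)
    stop("all scores identical; deciles undefined")
  grp <- decile_assign(pct)
  rows <- lapply(1:10, function(g) {
    sel <- grp == g
    cif <- aalen_johansen(fu[sel, , drop = FALSE], outcome_def)
    obs <- observed_probability_at(cif, horizon)
    se <- attr(obs, "se_pct")
    data.frame(decile = g, n = sum(sel),
               mean_estimated_pct = mean(pct[sel]),
               observed_pct = as.numeric(obs),
               observed_ci_low = max(0, as.numeric(obs) - 1.96 * se),
               observed_ci_high = min(100, as.numeric(obs) + 1.96 * se))
  })
  dec <- do.call(rbind, rows)
  fit <- lm(observed_pct ~ mean_estimated_pct, data = dec)
  structure(list(deciles = dec,
                 slope = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]),
                 outcome_def = outcome_def, horizon = horizon),
            class = "calibration_result")
}

# equal-count decile assignment: stable rank, boundary to the lower decile
decile_assign <- function(pct) {
  n <- length(pct)
  ord <- order(pct)                      # stable in R
  bounds <- floor(n * (0:10) / 10)
  grp <- integer(n)
  grp[ord] <- rep(1:10, times = diff(bounds))
  grp
}

#' Calibration under probabilistic parental-history imputation
#'
#' Reruns scoring and decile calibration across resampled datasets in which
#' unknown parental hip fracture history is probabilistically assigned
#' positive (see [impute_parental_history()]), and fits the calibration
#' line to the across-resample mean observed and estimated risks per
#' decile.
#'
#' @param cohort a `phpt_cohort` (patients plus follow-up/event stream).
#' @param model the [surrogate_model()] used for rescoring.
#' @param score_kind which score calibrates which outcome: `"mof"` or
#'   `"hip"`; the outcome definition matches the score kind.
#' @param prevalence assumed prevalence of positive parental history among
#'   unknowns (default 0.10).
#' @param n_resamples number of resampled datasets (default 100).
#' @param seed integer seed for the resampling stream.
#' @param horizon evaluation time in years.
#' @return a `calibration_result` whose `deciles` hold across-resample
#'   means; attribute `n_resamples` records the resample count.
#' @export
sensitivity_calibration <- function(cohort, model = surrogate_model(),
                                    score_kind = c("mof", "hip"),
                                    prevalence = 0.10, n_resamples = 100,
                                    seed = 1L, horizon = 10) {
  score_kind <- match.arg(score_kind)
  if (!is.numeric(prevalence) || prevalence < 0 || prevalence > 1)
    stop("prevalence must lie in [0, 1]")
  patients <- cohort$patients
  followups <- resolve_followups(cohort, score_kind)
  unknown <- which(patients$parental_hip_fracture == "unknown")

  # scores only change through the parental-history field, so the two
  # possible values per unknown patient are precomputed once
  base <- score_cohort(patients, model)[[paste0(score_kind, "_pct")]]
  alt <- base
  if (length(unknown)) {
    pats_yes <- patients[unknown, , drop = FALSE]
    pats_yes$parental_hip_fracture <- "yes"
    alt[unknown] <- score_cohort(pats_yes, model)[[paste0(score_kind, "_pct")]]
  }

  old <- .save_rng_state()
  on.exit(.restore_rng_state(old))
  set.seed(as.integer(seed))
  acc_est <- acc_obs <- matrix(NA_real_, n_resamples, 10)
  for (r in seq_len(n_resamples)) {
    pct <- base
    if (length(unknown)) {
      pos <- unknown[runif(length(unknown)) < prevalence]
      pct[pos] <- alt[pos]
    }
    cal <- decile_calibration(
      data.frame(patient_id = patients$patient_id, pct = pct),
      followups, score_kind, horizon)
    acc_est[r, ] <- cal$deciles$mean_estimated_pct
    acc_obs[r, ] <- cal$deciles$observed_pct
  }
  dec <- data.frame(decile = 1:10,
                    n = NA_integer_,
                    mean_estimated_pct = colMeans(acc_est),
                    observed_pct = colMeans(acc_obs),
                    observed_ci_low = NA_real_,
                    observed_ci_high = NA_real_)
  dec$n <- as.integer(round(nrow(patients) / 10))
  fit <- lm(observed_pct ~ mean_estimated_pct, data = dec)
  structure(list(deciles = dec,
                 slope = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]),
                 outcome_def = score_kind, horizon = horizon,
                 n_resamples = n_resamples),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("Decile calibration (%s, %g-year horizon)\n",
              x$outcome_def, x$horizon))
  cat(sprintf("  slope %.3f, intercept %.2f percentage points\n",
              x$slope, x$intercept))
  print(format(x$deciles, digits = 3), ...)
  invisible(x)
}
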