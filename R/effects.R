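#' Surgical propensity model and inverse-probability-of-treatment weights
#'
#' Fits a logistic model for receipt of parathyroidectomy on the factors
#' expected to drive surgical selection (age, sex, race and ethnicity,
#' inclusion decade, BMI, alcohol excess, smoking, rheumatoid arthritis,
#' osteopenia, osteoporosis, secondary osteoporosis, fracture history,
#' glucocorticoid use, antiosteoporosis medication, CKD, kidney stones and
#' highest calcium band) and derives average-treatment-effect IPTW weights,
#' \eqn{1/p} for treated and \eqn{1/(1-p)} for untreated patients.
#' Standardized mean differences (SMD) between arms are reported for every
#' covariate before and after weighting; the weighted SMD uses the same
#' formula with weighted means and variances. Weighted SMDs at or above
#' 0.1 trigger a balance warning.
#'
#' @param patients patient data frame (with logical `ptx`) or `phpt_cohort`.
#' @param stabilize multiply weights by the marginal treatment/control
#'   probabilities (default FALSE).
#' @param truncate optional length-2 probability vector, e.g.
#'   `c(0.01, 0.99)`: weights are truncated at these weight quantiles.
#' @return object of class `propensity_result`: list with `propensity`,
#'   `weights` (both in patient order), `smd_table`
#'   (`covariate`, `smd_unweighted`, `smd_weighted`), `model`.
#' @export
fit_propensity <- function(patients, stabilize = FALSE, truncate = NULL) {
  if (inherits(patients, "phpt_cohort")) patients <- patients$patients
  if (length(unique(patients$ptx)) < 2L)
    stop("cohort must contain both treated and untreated patients")
  covs <- c("age", "sex", "race_ethnicity", "inclusion_period", "bmi",
            "alcohol_excess", "current_smoking", "rheumatoid_arthritis",
            "osteopenia", "osteoporosis", "secondary_osteoporosis",
            "prior_fracture", "glucocorticoid_use", "antiosteoporosis_med",
            "ckd_stage3plus", "kidney_stones", "highest_calcium_band")
  covs <- covs[covs %in% names(patients)]
  df <- patients[, c("ptx", covs)]
  fit <- suppressWarnings(
    glm(as.formula(paste("ptx ~", paste(covs, collapse = " + "))),
        family = binomial(), data = df))
  p <- fitted(fit)
  if (any(p < 1e-10) || any(p > 1 - 1e-10)) {
    cf <- coef(fit)[-1L]
    worst <- names(cf)[which.max(abs(cf))]
    stop("propensity model separation; largest coefficient on: ", worst)
  }
  w <- ifelse(df$ptx, 1 / p, 1 / (1 - p))
  if (stabilize) {
    pt <- mean(df$ptx)
    w <- w * ifelse(df$ptx, pt, 1 - pt)
  }
  if (!is.null(truncate)) {
    qs <- quantile(w, truncate)
    w <- pmin(pmax(w, qs[1L]), qs[2L])
  }
  smd <- smd_table(patients, covs, weights = w)
  if (any(abs(smd$smd_weighted) >= 0.1, na.rm = TRUE))
    warning("weighted SMD >= 0.1 for: ",
            paste(smd$covariate[abs(smd$smd_weighted) >= 0.1], collapse = ", "))
  structure(list(propensity = p, weights = w, smd_table = smd, model = fit,
                 patient_id = patients$patient_id),
            class = "propensity_result")
}

#' Standardized mean differences between treatment arms
#'
#' SMD of each covariate between treated and untreated patients:
#' \eqn{(\bar x_1 - \bar x_0)/\sqrt{(s_1^2 + s_0^2)/2}}. Categorical
#' covariates are expanded into level indicators. With `weights`, the
#' weighted SMD applies the identical formula with weighted means and
#' weighted variances.
#'
#' @param patients patient data frame with logical `ptx`.
#' @param covariates character vector of covariate columns.
#' @param weights optional positive weights.
#' @return data frame `covariate`, `smd_unweighted`, `smd_weighted`.
#' @export
smd_table <- function(patients, covariates, weights = NULL) {
  g <- patients$ptx
  expand <- function(nm) {
    x <- patients[[nm]]
    if (is.numeric(x)) {
      setNames(list(x), nm)
    } else if (is.logical(x)) {
      setNames(list(as.numeric(x)), nm)
    } else {
      lv <- sort(unique(x))
      setNames(lapply(lv, function(l) as.numeric(x == l)),
               paste(nm, lv, sep = "."))
    }
  }
  cols <- do.call(c, lapply(covariates, expand))
  one <- function(x, w) {
    m1 <- weighted.mean(x[g], w[g]); m0 <- weighted.mean(x[!g], w[!g])
    v1 <- weighted.mean((x[g] - m1)^2, w[g])
    v0 <- weighted.mean((x[!g] - m0)^2, w[!g])
    if (v1 + v0 == 0) return(0)
    (m1 - m0) / sqrt((v1 + v0) / 2)
  }
  u <- rep(1, nrow(patients))
  data.frame(
    covariate = names(cols),
    smd_unweighted = vapply(cols, one, numeric(1), w = u),
    smd_weighted = if (is.null(weights)) NA_real_
                   else vapply(cols, one, numeric(1), w = weights),
    row.names = NULL
  )
}

#' Person-period expansion of follow-up
#'
#' Splits each subject's follow-up into consecutive intervals of width
#' `interval_years` (last interval partial), so that a Poisson likelihood
#' with a log-exposure offset approximates the continuous-time hazard
#' model. Each row carries the interval's exposure time, the time
#' covariate at the midpoint of the exposed part, and the event indicator
#' on the subject's final row only. Exposure sums to total follow-up
#' exactly.
#'
#' @param followups outcome-resolved follow-up table.
#' @param interval_years interval width in years (default 0.5).
#' @param data optional per-patient data frame (keyed by `patient_id`)
#'   whose columns (e.g. `age`, `pct`, `ptx`) are merged onto the rows.
#' @return data frame `patient_id`, `tstart`, `exposure`, `tmid`, `event`.
#' @export
person_time_expand <- function(followups, interval_years = 0.5, data = NULL) {
  if (interval_years <= 0) stop("interval_years must be positive")
  time <- followups$time
  k <- pmax(1L, ceiling(time / interval_years))
  id <- rep(seq_along(time), k)
  slot <- sequence(k)
  tstart <- (slot - 1) * interval_years
  exposure <- pmin(time[id] - tstart, interval_years)
  last <- slot == k[id]
  out <- data.frame(
    patient_id = followups$patient_id[id],
    tstart = tstart,
    exposure = exposure,
    tmid = tstart + exposure / 2,
    event = as.integer(last & followups$event[id] == 1L)
  )
  if (!is.null(data)) {
    j <- match(out$patient_id, data$patient_id)
    if (anyNA(j)) stop("person-period patients missing from data")
    add <- setdiff(names(data), c("patient_id", names(out)))
    out <- cbind(out, data[j, add, drop = FALSE])
    rownames(out) <- NULL
  }
  out
}

#' Weighted Poisson hazard model with score-by-treatment interaction
#'
#' Fits, on a person-period table, the piecewise-exponential cause-specific
#' fracture hazard
#' \deqn{h(t) = \exp(\beta_0 + \beta_1 t + \beta_2\,\mathrm{age} +
#'   \beta_3\,\mathrm{score} + \beta_4\,\mathrm{PTX} +
#'   \beta_5\,\mathrm{score}\times\mathrm{PTX})}
#' by weighted Poisson maximum likelihood with a log-exposure offset
#' (IRLS; convergence when the relative deviance change is below 1e-10,
#' at most 100 iterations). The score is in percent, so \eqn{\beta_5} has
#' units per percentage point. Age is baseline age, constant across a
#' subject's person-periods. Competing deaths end exposure but are not
#' events (cause-specific hazard). The reported covariance is the inverse
#' of the weighted Fisher information — the covariance matrix of the
#' weighted Poisson regression, from which delta-method confidence
#' intervals are derived downstream.
#'
#' @param person_periods output of [person_time_expand()], carrying
#'   columns `age`, `ptx` and the score column.
#' @param weights per-subject IPTW weights: data frame `patient_id`,
#'   `weight`, a [fit_propensity()] result, or NULL for unweighted.
#' @param score_col name of the score column in percent
#'   (default `"pct"`).
#' @return object of class `hazard_fit`: `beta` (named length 6),
#'   `covariance` (6x6), `n_intervals`, `loglik`, `events_observed`,
#'   `events_fitted`.
#' @export
fit_poisson_hazard <- function(person_periods, weights = NULL,
                               score_col = "pct") {
  pp <- person_periods
  for (col in c("tmid", "age", "ptx", "event", "exposure", score_col)) {
    if (is.null(pp[[col]])) stop("person-period table lacks column: ", col)
  }
  w <- rep(1, nrow(pp))
  if (inherits(weights, "propensity_result"))
    weights <- data.frame(patient_id = weights$patient_id,
                          weight = weights$weights)
  if (is.data.frame(weights)) {
    j <- match(pp$patient_id, weights$patient_id)
    if (anyNA(j)) stop("weights missing for some subjects")
    w <- weights$weight[j]
  } else if (is.numeric(weights)) {
    w <- weights
  }
  if (sum(w * pp$event) <= 0) stop("no (weighted) events; hazard not identifiable")
  score <- pp[[score_col]]
  X <- cbind(intercept = 1, t = pp$tmid, age = pp$age, score = score,
             ptx = as.numeric(pp$ptx), score_ptx = score * as.numeric(pp$ptx))
  fit <- suppressWarnings(
    glm.fit(X, pp$event, weights = w, offset = log(pp$exposure),
            family = poisson(),
            control = list(epsilon = 1e-10, maxit = 100)))
  mu <- fit$fitted.values
  if (!fit$converged) {
    grad <- crossprod(X, w * (pp$event - mu))
    stop("Poisson hazard fit did not converge in 100 iterations; ",
         "gradient norm ", format(sqrt(sum(grad^2))))
  }
  # aliased (collinear or constant-zero) columns: coefficient pinned to 0,
  # zero rows/columns in the covariance
  aliased <- is.na(fit$coefficients)
  fit$coefficients[aliased] <- 0
  keep <- which(!aliased)
  info <- crossprod(X[, keep, drop = FALSE],
                    X[, keep, drop = FALSE] * (w * mu))
  covb <- matrix(0, ncol(X), ncol(X),
                 dimnames = list(colnames(X), colnames(X)))
  covb[keep, keep] <- solve(info)
  ll <- sum(w * stats::dpois(pp$event, mu, log = TRUE))
  structure(list(beta = setNames(fit$coefficients, colnames(X)),
                 covariance = covb,
                 n_intervals = nrow(pp),
                 loglik = ll,
                 events_observed = sum(w * pp$event),
                 events_fitted = sum(w * mu),
                 score_col = score_col),
            class = "hazard_fit")
}

#' Hazard-ratio-versus-score curve with delta-method bands
#'
#' The fitted model implies a treatment hazard ratio that is log-linear in
#' the score: \eqn{\mathrm{HR}(F) = \exp(\beta_4 + \beta_5 F)}, with
#' \eqn{\mathrm{var}\{\log \mathrm{HR}(F)\} = V_{44} + 2F V_{45} + F^2
#' V_{55}} by the delta method, and 95% bands symmetric on the log scale.
#'
#' @param fit a [fit_poisson_hazard()] result.
#' @param score_grid score values in percent at which to evaluate.
#' @param level confidence level (default 0.95).
#' @return object of class `hr_curve`: data frame `score`, `hr`, `ci_low`,
#'   `ci_high`; attribute `threshold` from [find_threshold()].
#' @export
hr_curve <- function(fit, score_grid, level = 0.95) {
  V <- fit$covariance
  b4 <- fit$beta[["ptx"]]; b5 <- fit$beta[["score_ptx"]]
  loghr <- b4 + b5 * score_grid
  v <- V["ptx", "ptx"] + 2 * score_grid * V["ptx", "score_ptx"] +
    score_grid^2 * V["score_ptx", "score_ptx"]
  if (any(v < 0)) stop("negative delta-method variance")
  z <- qnorm(1 - (1 - level) / 2)
  out <- data.frame(score = score_grid, hr = exp(loghr),
                    ci_low = exp(loghr - z * sqrt(v)),
                    ci_high = exp(loghr + z * sqrt(v)))
  out <- structure(out, class = c("hr_curve", "data.frame"))
  attr(out, "threshold") <- find_threshold(out)
  out
}

#' Surgical-benefit threshold on a hazard-ratio curve
#'
#' The smallest grid score above which treatment is consistently associated
#' with reduced fracture risk: the minimal score \eqn{s^*} such that the
#' upper confidence bound of the hazard ratio stays below 1 at every grid
#' point at or beyond \eqn{s^*}. `NA` when no such score exists.
#'
#' @param curve an [hr_curve()].
#' @return score in percent, or `NA`.
#' @export
find_threshold <- function(curve) {
  ok <- curve$ci_high < 1
  tail_ok <- rev(cumprod(rev(ok))) > 0
  if (!any(tail_ok)) return(NA_real_)
  min(curve$score[tail_ok])
}

#' Wald test of the score-by-treatment interaction
#'
#' Tests whether the treatment benefit varies with the score:
#' \eqn{z = \beta_5 / \sqrt{V_{55}}}, two-sided p from the normal
#' reference. Also reports the interaction hazard ratio per percentage
#' point of score with its confidence interval.
#'
#' @param fit a [fit_poisson_hazard()] result.
#' @param level confidence level (default 0.95).
#' @return list `hr_per_unit`, `ci_low`, `ci_high`, `z`, `p`.
#' @export
interaction_test <- function(fit, level = 0.95) {
  b5 <- fit$beta[["score_ptx"]]
  se <- sqrt(fit$covariance["score_ptx", "score_ptx"])
  z <- b5 / se
  zq <- qnorm(1 - (1 - level) / 2)
  list(hr_per_unit = exp(b5),
       ci_low = exp(b5 - zq * se), ci_high = exp(b5 + zq * se),
       z = z, p = 2 * pnorm(-abs(z)))
}

#' @export
print.hazard_fit <- function(x, ...) {
  cat("Weighted Poisson piecewise-exponential hazard fit\n")
  se <- sqrt(diag(x$covariance))
  tab <- data.frame(beta = x$beta, se = se)
  print(format(tab, digits = 4))
  cat(sprintf("  %d person-period rows, log-likelihood %.2f, events %.1f\n",
              x$n_intervals, x$loglik, x$events_observed))
  invisible(x)
}

#' @export
print.hr_curve <- function(x, ...) {
  thr <- attr(x, "threshold")
  cat(sprintf("Hazard-ratio curve over %d score points; benefit threshold: %s\n",
              nrow(x), if (is.na(thr)) "none" else sprintf("%.2f%%", thr)))
  print(format(as.data.frame(x), digits = 3), ...)
  invisible(x)
}

#' @export
print.propensity_result <- function(x, ...) {
  cat(sprintf("Surgical propensity model: %d patients, %.1f%% treated\n",
              length(x$propensity), 100 * mean(x$model$y)))
  cat(sprintf("  max |SMD| unweighted %.3f, weighted %.3f\n",
              max(abs(x$smd_table$smd_unweighted)),
              max(abs(x$smd_table$smd_weighted))))
  invisible(x)
}
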