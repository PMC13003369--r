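#' Aalen-Johansen cumulative incidence of fracture with competing mortality
#'
#' Estimates the cumulative incidence function (CIF) of first fracture for
#' a given outcome definition, treating death as a competing risk and loss
#' to follow-up as independent right censoring. The estimator is the
#' Aalen-Johansen product-limit transition estimator (the competing-risk
#' generalisation of Kaplan-Meier), evaluated at the exact observed event
#' times with no binning; tied transitions of different types at the same
#' time are handled simultaneously from the common at-risk set, and
#' censorings at a tied time are removed after events.
#'
#' Follow-up tables should be outcome-resolved (see [resolve_followups()]),
#' so that a fracture at a site outside the outcome definition leaves the
#' patient at risk. If an unresolved table is supplied, first fractures at
#' non-qualifying sites are treated as censoring at that time, with a
#' warning — an approximation that is only needed when the full event
#' stream is unavailable.
#'
#' @param followups data frame with `time` (> 0, years), `event`
#'   (0 censored, 1 fracture, 2 death) and `fracture_site`.
#' @param outcome_def `"mof"`, `"hip"` or `"all"`.
#' @return object of class `cif_estimate`: a data frame with `time`,
#'   `cif_event`, `cif_death`, `surv`, `se` (standard error of
#'   `cif_event`), `variance` and `n_at_risk`, starting at time 0.
#' @export
aalen_johansen <- function(followups, outcome_def = c("all", "mof", "hip")) {
  outcome_def <- match.arg(outcome_def)
  if (is.null(followups) || nrow(followups) == 0L)
    stop("empty follow-up table")
  bad <- which(!is.finite(followups$time) | followups$time <= 0)
  if (length(bad))
    stop("follow-up times must be positive and finite; offending rows: ",
         paste(head(bad, 10L), collapse = ", "))
  ev <- followups$event
  if (!is.null(followups$fracture_site)) {
    nonq <- ev == 1L & !(followups$fracture_site %in% outcome_sites(outcome_def))
    if (any(nonq)) {
      warning(sum(nonq), " first fracture(s) at non-qualifying sites treated ",
              "as censored; supply outcome-resolved follow-up to keep these ",
              "patients at risk")
      ev[nonq] <- 0L
    }
  }
  state <- factor(ev, levels = c(0L, 1L, 2L),
                  labels = c("censor", "fracture", "death"))
  sf <- survival::survfit(survival::Surv(followups$time, state) ~ 1)
  ist <- match(c("fracture", "death"), sf$states)
  cif_event <- sf$pstate[, ist[1L]]
  cif_death <- sf$pstate[, ist[2L]]
  se_event <- sf$std.err[, ist[1L]]
  out <- data.frame(
    time = c(0, sf$time),
    cif_event = c(0, cif_event),
    cif_death = c(0, cif_death),
    surv = c(1, 1 - cif_event - cif_death),
    se = c(0, se_event),
    variance = c(0, se_event^2),
    n_at_risk = c(nrow(followups),
                  sf$n.risk[, match("(s0)", sf$states)])
  )
  structure(out, class = c("cif_estimate", "data.frame"))
}

#' Evaluate a cumulative incidence curve at a time point
#'
#' Right-continuous step evaluation of the fracture CIF, in percent. When
#' `t` exceeds the last observed time the last value is carried forward and
#' the result is flagged as truncated (attribute `truncated`).
#'
#' @param cif a [aalen_johansen()] estimate.
#' @param t evaluation time in years (default 10).
#' @param what `"event"` (fracture, default) or `"death"`.
#' @return probability in percent, with attributes `truncated` (logical)
#'   and `se_pct` (standard error, percent scale).
#' @export
observed_probability_at <- function(cif, t = 10, what = c("event", "death")) {
  what <- match.arg(what)
  if (t < 0) stop("t must be nonnegative")
  col <- if (what == "event") "cif_event" else "cif_death"
  idx <- findInterval(t, cif$time)
  truncated <- t > max(cif$time)
  val <- if (idx == 0L) 0 else cif[[col]][idx]
  se <- if (idx == 0L) 0 else cif$se[idx]
  structure(100 * val, truncated = truncated, se_pct = 100 * se)
}

#' Incident-fracture filter over coded fracture events
#'
#' EHR and claims data record fracture diagnosis codes repeatedly, both for
#' new (incident) fractures and for follow-up care of old (prevalent) ones.
#' This filter is a documented, configurable stand-in for validated
#' claims-based incident-fracture algorithms: a post-index code at a given
#' site is suppressed when any code at the same site occurred within
#' `washout_days` before it (including pre-index codes), and the earliest
#' surviving post-index code per patient is returned as that patient's
#' incident fracture. Duplicate `(patient, date, site)` rows are collapsed.
#'
#' @param coded_events data frame with `patient_id`, `date` (numeric days
#'   or `Date`) and `site`.
#' @param index_date single value, or data frame `patient_id`, `index_date`.
#' @param washout_days site-specific washout window in days (default 365).
#' @return data frame `patient_id`, `date`, `site`: first incident fracture
#'   per patient after their index date.
#' @export
incident_filter <- function(coded_events, index_date, washout_days = 365) {
  if (washout_days < 0) stop("washout_days must be nonnegative")
  ev <- unique(coded_events[, c("patient_id", "date", "site")])
  ev$date <- as.numeric(ev$date)
  if (is.data.frame(index_date)) {
    ev$index <- as.numeric(index_date$index_date)[
      match(ev$patient_id, index_date$patient_id)]
    if (anyNA(ev$index)) stop("index date missing for some patients")
  } else {
    ev$index <- as.numeric(index_date)
  }
  ev <- ev[order(ev$patient_id, ev$site, ev$date), , drop = FALSE]
  key <- paste(ev$patient_id, ev$site, sep = "\r")
  prev_key <- c("", head(key, -1L))
  prev_date <- c(-Inf, head(ev$date, -1L))
  gap <- ifelse(key == prev_key, ev$date - prev_date, Inf)
  keep <- ev$date > ev$index & gap > washout_days
  inc <- ev[keep, , drop = FALSE]
  inc <- inc[order(inc$patient_id, inc$date), , drop = FALSE]
  inc <- inc[!duplicated(inc$patient_id), c("patient_id", "date", "site")]
  rownames(inc) <- NULL
  inc
}

#' @export
print.cif_estimate <- function(x, ...) {
  cat(sprintf("Aalen-Johansen cumulative incidence: %d subjects, %d time points\n",
              x$n_at_risk[1L], nrow(x) - 1L))
  last <- nrow(x)
  cat(sprintf("  at t = %.2f y: fracture %.2f%%, death %.2f%%, event-free %.2f%%\n",
              x$time[last], 100 * x$cif_event[last], 100 * x$cif_death[last],
              100 * x$surv[last]))
  invisible(x)
}
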