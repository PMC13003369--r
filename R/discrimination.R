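#' Time-dependent AUROC with censoring and competing mortality
#'
#' Cumulative/dynamic time-dependent discrimination of a fracture risk
#' score: at each evaluation time `t`, cases are subjects with the outcome
#' fracture by `t` (cumulative sensitivity) and controls are subjects still
#' under observation and event-free beyond `t` (dynamic specificity).
#' Right censoring is corrected by inverse-probability-of-censoring
#' weighting (IPCW): the censoring distribution G is estimated by
#' Kaplan-Meier, pooled over treatment arms; a case observed at time
#' \eqn{T_i \le t} receives weight \eqn{1/G(T_i^-)} and a control weight
#' \eqn{1/G(t)}. The AUROC is the weighted probability that a random case
#' outranks a random control, ties counting one half.
#'
#' Subjects dead before `t` without the outcome fracture are, by default,
#' excluded from the comparison set (`competing = "exclude"`); setting
#' `competing = "control"` retains them as controls with weight
#' \eqn{1/G(T_i^-)}, the alternative convention under competing risks.
#'
#' Standard errors come from an influence-function linearisation of the
#' weighted two-sample U-statistic (treating the estimated censoring
#' weights as fixed), with asymptotic normal confidence intervals. An
#' evaluation time with no cases or no controls is flagged `undefined`
#' (NA estimate), not an error.
#'
#' @param scores data frame `patient_id`, `pct`.
#' @param followups outcome-resolved follow-up table.
#' @param outcome_def `"mof"`, `"hip"` or `"all"` (metadata only; resolve
#'   the follow-up table first).
#' @param eval_times evaluation horizons in years (default 1:10).
#' @param competing `"exclude"` or `"control"`, see Details.
#' @param level confidence level (default 0.95).
#' @return object of class `td_auroc`: data frame with `time`, `n_case`,
#'   `n_control`, `auc`, `se`, `ci_low`, `ci_high`, `undefined`.
#' @export
td_auroc <- function(scores, followups, outcome_def = c("mof", "hip", "all"),
                     eval_times = 1:10, competing = c("exclude", "control"),
                     level = 0.95) {
  outcome_def <- match.arg(outcome_def)
  competing <- match.arg(competing)
  idx <- match(scores$patient_id, followups$patient_id)
  if (anyNA(idx)) stop("scores and follow-up tables key different patients")
  fu <- followups[idx, , drop = FALSE]
  marker <- scores$pct
  time <- fu$time
  event <- fu$event
  n <- length(marker)
  z <- qnorm(1 - (1 - level) / 2)

  # Kaplan-Meier of the censoring distribution (censoring as the event)
  cs <- survival::survfit(survival::Surv(time, event == 0L) ~ 1)
  G_at <- function(t, left = FALSE) {
    tt <- if (left) t - 1e-12 else t
    i <- findInterval(tt, cs$time)
    ifelse(i == 0L, 1, cs$surv[pmax(i, 1L)])
  }

  res <- lapply(eval_times, function(t) {
    is_case <- event == 1L & time <= t
    is_ctrl <- time > t
    if (competing == "control") {
      dead <- event == 2L & time <= t
      is_ctrl <- is_ctrl | dead
    }
    w <- numeric(n)
    w[is_case] <- 1 / G_at(time[is_case], left = TRUE)
    w[is_ctrl & time > t] <- 1 / G_at(t)
    if (competing == "control") {
      dc <- is_ctrl & time <= t
      w[dc] <- 1 / G_at(time[dc], left = TRUE)
    }
    if (!any(is_case) || !any(is_ctrl)) {
      return(data.frame(time = t, n_case = sum(is_case),
                        n_control = sum(is_ctrl), auc = NA_real_,
                        se = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                        undefined = TRUE))
    }
    a <- ifelse(is_case, w, 0)
    b <- ifelse(is_ctrl, w, 0)
    cw <- .concordance_sums(marker, a, b)
    A <- cw$S / n^2
    abar <- mean(a); bbar <- mean(b)
    B <- abar * bbar
    theta <- A / B
    # influence-function linearisation of the ratio of V-statistics
    psi <- ((a * cw$u + b * cw$v) / n - 2 * A -
              theta * (a * bbar + b * abar - 2 * B)) / B
    se <- sqrt(sum(psi^2)) / n
    data.frame(time = t, n_case = sum(is_case), n_control = sum(is_ctrl),
               auc = theta, se = se,
               ci_low = max(0, theta - z * se),
               ci_high = min(1, theta + z * se),
               undefined = FALSE)
  })
  out <- do.call(rbind, res)
  structure(out, class = c("td_auroc", "data.frame"),
            outcome_def = outcome_def, competing = competing)
}

# For every subject k:
#   u[k] = sum_j b_j K(m_k, m_j)  (weighted controls outranked by k)
#   v[k] = sum_i a_i K(m_i, m_k)  (weighted cases outranking k)
#   S    = sum_i a_i u_i
# with K(x, y) = 1(x > y) + 0.5 * 1(x == y), computed by sorting.
.concordance_sums <- function(marker, a, b) {
  o <- order(marker)
  m <- marker[o]
  as <- a[o]; bs <- b[o]
  grp <- cumsum(c(TRUE, m[-1L] != m[-length(m)]))  # tie groups
  bg <- tapply(bs, grp, sum)
  ag <- tapply(as, grp, sum)
  cum_b <- cumsum(bg)          # control mass at or below each tie group
  cum_a_rev <- rev(cumsum(rev(ag)))  # case mass at or above each group
  # below-strictly + half of own tie group
  u_g <- c(0, head(cum_b, -1L)) + 0.5 * bg
  v_g <- c(tail(cum_a_rev, -1L), 0) + 0.5 * ag
  u <- numeric(length(marker)); v <- numeric(length(marker))
  u[o] <- u_g[grp]
  v[o] <- v_g[grp]
  list(u = u, v = v, S = sum(a * u))
}

#' @export
print.td_auroc <- function(x, ...) {
  cat(sprintf("Time-dependent AUROC (%s outcome, competing deaths: %s)\n",
              attr(x, "outcome_def"), attr(x, "competing")))
  print(format(as.data.frame(x), digits = 3), ...)
  invisible(x)
}
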