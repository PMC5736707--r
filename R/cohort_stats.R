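# Cohort-level association statistics: Fisher exact test on 2x2 tables,
# Kaplan-Meier curves and the log-rank test with an O/E hazard-ratio
# summary. These delegate to the standard implementations (stats,
# survival) behind a stable interface.

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Two-sided p by probability-mass ordering: the sum of hypergeometric
#' probabilities of all tables with the observed margins whose
#' probability does not exceed the observed table's.
#'
#' @param tab 2x2 matrix or equivalent (rows = groups, cols = outcome).
#' @return Two-sided p-value.
#' @examples
#' fisher_exact(matrix(c(9, 8, 10, 34), 2))  # 0.032
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(identical(dim(tab), c(2L, 2L)), all(tab >= 0))
  fisher.test(tab)$p.value
}

#' Kaplan-Meier curves and log-rank test
#'
#' Product-limit survival estimates per group, the 1-df log-rank
#' chi-square and p-value, and the observed/expected hazard-ratio
#' summary `HR = (O1/E1) / (O2/E2)` where group 1 is the second factor
#' level (so with a logical `groups`, `TRUE` vs `FALSE`).
#'
#' @param times Follow-up times.
#' @param events Event indicators (1/TRUE = event, 0/FALSE = censored).
#' @param groups Two-level grouping factor.
#' @return Object of class `km_logrank`: `curves` (data.frame with
#'   `group`, `time`, `n_risk`, `n_event`, `survival`), `chi2`, `p`,
#'   `hr`, `obs`, `exp`.
#' @export
km_logrank <- function(times, events, groups) {
  groups <- as.factor(groups)
  stopifnot(nlevels(groups) == 2)
  events <- as.integer(as.logical(events))
  sf <- survival::survfit(survival::Surv(times, events) ~ groups)
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  strata <- rep(names(sf$strata), sf$strata)
  curves <- data.frame(group = sub("^groups=", "", strata),
                       time = sf$time, n_risk = sf$n.risk,
                       n_event = sf$n.event, survival = sf$surv)
  obs <- sd$obs; expd <- sd$exp
  hr <- (obs[2] / expd[2]) / (obs[1] / expd[1])
  structure(list(curves = curves, chi2 = unname(sd$chisq),
                 p = unname(pchisq(sd$chisq, df = 1, lower.tail = FALSE)),
                 hr = unname(hr), obs = unname(obs), exp = unname(expd)),
            class = "km_logrank")
}

#' @export
print.km_logrank <- function(x, ...) {
  cat(sprintf("log-rank chi2 = %.3f, p = %.4g, HR (O/E) = %.3g\n",
              x$chi2, x$p, x$hr))
  invisible(x)
}

#' Association of evolved status with progression
#'
#' Cross-tabulates evolved status against progression (Fisher exact)
#' and compares time-to-progression between evolved and non-evolved
#' patients (Kaplan-Meier / log-rank).
#'
#' @param patients Data.frame with `patient_id` and `evolved` (from
#'   [classify_cohort()]).
#' @param outcomes Data.frame with `patient_id`, `followup_day`,
#'   `progressed` (see [read_outcomes()]).
#' @return List with `table` (2x2), `fisher_p`, `km` (a `km_logrank`).
#' @export
outcome_association <- function(patients, outcomes) {
  m <- merge(patients, outcomes, by = "patient_id")
  tab <- matrix(c(sum(m$evolved & m$progressed),
                  sum(!m$evolved & m$progressed),
                  sum(m$evolved & !m$progressed),
                  sum(!m$evolved & !m$progressed)), 2,
                dimnames = list(evolved = c("yes", "no"),
                                progressed = c("yes", "no")))
  km <- km_logrank(m$followup_day, m$progressed, m$evolved)
  list(table = tab, fisher_p = fisher_exact(tab), km = km)
}
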