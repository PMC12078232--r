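#' Kaplan-Meier product-limit estimator
#'
#' Right-continuous step estimate of local-control survival, S(0) = 1,
#' with the standard convention that events at a time point are processed
#' before censorings at the same time. Computed via [survival::survfit()].
#'
#' @param time_months non-negative follow-up times.
#' @param event 0/1 event indicator (1 = local failure).
#' @return An object of class `km_curve`: list with `time`, `surv`,
#'   `n_risk`, `n_event`, the step function `fn`, and the underlying
#'   `survfit` object.
#' @export
kaplan_meier <- function(time_months, event) {
  if (any(time_months < 0) || anyNA(time_months)) {
    ctv_stop("ctv_survival_error", "times must be finite and non-negative")
  }
  stopifnot(length(time_months) >= 1, all(event %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(time_months, event) ~ 1,
                           conf.type = "none")
  fn <- stats::stepfun(fit$time, c(1, fit$surv), right = FALSE)
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event, fn = fn, fit = fit),
            class = "km_curve")
}

#' Survival probability at a fixed horizon
#'
#' Value of the Kaplan-Meier step function at `horizon_months` — e.g. the
#' 3-year local-control rate is the curve at 36 months.
#'
#' @param km a `km_curve` from [kaplan_meier()].
#' @param horizon_months non-negative horizon.
#' @return probability in `[0, 1]` (1 at horizon 0).
#' @export
lc_rate_at <- function(km, horizon_months) {
  stopifnot(inherits(km, "km_curve"), horizon_months >= 0)
  km$fn(horizon_months)
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic with hypergeometric variance, p-value from
#' the chi-square distribution with 1 degree of freedom. Invariant to
#' swapping the group labels.
#'
#' @param time_months follow-up times.
#' @param event 0/1 event indicators.
#' @param group two-level group labels.
#' @return list with `chisq`, `p_value`, and the per-group observed and
#'   expected event counts.
#' @export
log_rank <- function(time_months, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2) {
    ctv_stop("ctv_survival_error", "log_rank needs exactly two groups")
  }
  if (sum(event) < 1) {
    ctv_stop("ctv_survival_error", "log_rank needs at least one event")
  }
  sd_fit <- survival::survdiff(survival::Surv(time_months, event) ~ group)
  list(chisq = unname(sd_fit$chisq),
       p_value = pchisq(sd_fit$chisq, df = 1, lower.tail = FALSE),
       observed = sd_fit$obs, expected = sd_fit$exp)
}

#' Univariate Cox regression for a binary covariate
#'
#' Hazard ratio, Wald 95% confidence interval and p-value from a Cox
#' proportional-hazards fit of one binary covariate, maximized by
#' Newton-Raphson with Breslow handling of tied event times (Efron
#' available via `ties`); convergence tolerance 1e-8, at most 50
#' iterations.
#'
#' @param time_months follow-up times.
#' @param event 0/1 event indicators (>= 1 event per group required).
#' @param group binary covariate (0/1, logical, or two-level factor).
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return list with `hr`, `ci_lower`, `ci_upper`, `p_value`, `beta`, `se`.
#' @export
cox_univariate_binary <- function(time_months, event, group,
                                  ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  g <- as.integer(as.factor(group)) - 1L
  if (length(unique(g)) != 2) {
    ctv_stop("ctv_survival_error", "both covariate levels must be present")
  }
  if (any(tapply(event, g, sum) < 1)) {
    ctv_stop("ctv_survival_error", "at least one event required in each group")
  }
  fit <- survival::coxph(
    survival::Surv(time_months, event) ~ g, ties = ties,
    control = survival::coxph.control(eps = 1e-8, iter.max = 50))
  beta <- unname(fit$coefficients)
  se <- sqrt(unname(fit$var[1, 1]))
  if (!is.finite(beta) || !is.finite(se) || se > 100) {
    ctv_stop("ctv_survival_error",
             "monotone likelihood: Cox estimate diverges (all events ordered in one group)")
  }
  z <- beta / se
  list(hr = exp(beta),
       ci_lower = exp(beta - 1.96 * se),
       ci_upper = exp(beta + 1.96 * se),
       p_value = 2 * pnorm(-abs(z)),
       beta = beta, se = se)
}

#' 2x2 contingency statistics
#'
#' Odds ratio with Woolf (log-normal) 95% confidence interval and a
#' continuity-corrected chi-square p-value, switching to Fisher's exact
#' test when any expected cell count is below 5. Layout: rows are the two
#' groups, columns the two outcomes, entered as `a, b` (row 1) and
#' `c, d` (row 2); OR = ad/bc.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @return list with `odds_ratio`, `ci_lower`, `ci_upper`, `p_value`,
#'   `test` (`"chisq"` or `"fisher"`).
#' @export
#' @examples
#' contingency_2x2(65, 31, 21, 63)$odds_ratio # ~6.29
contingency_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    ctv_stop("ctv_contingency_error", "cell counts must be non-negative integers")
  }
  m <- matrix(cells, 2, 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    ctv_stop("ctv_contingency_error", "zero margin: statistics undefined")
  }
  or <- (a * d) / (b * c)
  se_log <- sqrt(sum(1 / cells)) # infinite when any cell is 0 -> CI degenerate
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected < 5)) {
    p <- fisher.test(m)$p.value
    test <- "fisher"
  } else {
    p <- chisq.test(m, correct = TRUE)$p.value
    test <- "chisq"
  }
  list(odds_ratio = or,
       ci_lower = exp(log(or) - 1.96 * se_log),
       ci_upper = exp(log(or) + 1.96 * se_log),
       p_value = p, test = test)
}

#' Two-arm local-control contrast
#'
#' Convenience wrapper reproducing the standard local-control comparison
#' for a binary covariate: per-arm Kaplan-Meier curves and fixed-horizon
#' control rates, the log-rank test, and the univariate Cox hazard ratio.
#'
#' @param time_months,event,group as in [log_rank()].
#' @param horizon_months fixed horizon for the control rate (default 36,
#'   i.e. 3 years).
#' @return list with `lc_rate` (per group), `log_rank`, `cox`, `km`
#'   (per-group `km_curve`s) and group sizes.
#' @export
local_control_contrast <- function(time_months, event, group,
                                   horizon_months = 36) {
  group <- as.factor(group)
  lv <- levels(droplevels(group))
  stopifnot(length(lv) == 2)
  km <- lapply(lv, function(l) {
    kaplan_meier(time_months[group == l], event[group == l])
  })
  names(km) <- lv
  list(
    lc_rate = vapply(km, lc_rate_at, numeric(1), horizon_months = horizon_months),
    log_rank = log_rank(time_months, event, group),
    cox = cox_univariate_binary(time_months, event, group),
    km = km,
    n = table(group)
  )
}
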