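# ---- survival statistics -----------------------------------------------------
# Thin, typed wrappers around the survival package (Kaplan-Meier product
# limit, log-rank, Cox partial likelihood with Efron tie handling).

#' Kaplan-Meier product-limit estimate
#'
#' @param times Non-negative follow-up times.
#' @param events Event indicators (1 = event, 0 = censored).
#' @return List: `time`, `n_risk`, `n_event`, `n_censor`, `surv`
#'   (non-increasing, starts from 1 at time 0).
#' @export
km_estimate <- function(times, events) {
  stopifnot(length(times) == length(events))
  if (length(times) == 0L) stop("empty input")
  if (any(times < 0)) stop("negative times")
  if (any(!events %in% c(0, 1))) stop("events must be 0/1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  list(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
       n_censor = fit$n.censor, surv = fit$surv)
}

#' Log-rank test between survival groups
#'
#' Standard observed-vs-expected chi-square statistic (k - 1 degrees of
#' freedom for k groups).
#'
#' @param times,events As in [km_estimate()].
#' @param groups Group labels, one per subject; every group must be non-empty.
#' @return List: `chisq`, `df`, `p`.
#' @export
logrank_test <- function(times, events, groups) {
  stopifnot(length(times) == length(events), length(times) == length(groups))
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  if (any(table(g) == 0L)) stop("empty group")
  fit <- survival::survdiff(survival::Surv(times, events) ~ g)
  df <- length(fit$n) - 1L
  list(chisq = unname(fit$chisq), df = df,
       p = stats::pchisq(fit$chisq, df = df, lower.tail = FALSE))
}

#' Univariate Cox proportional-hazards regression
#'
#' Partial-likelihood fit with Efron tie correction. Perfect separation
#' (monotone likelihood) is detected from the fit diagnostics and flagged
#' rather than silently reported.
#'
#' @param covariate Numeric covariate, one value per subject (non-constant).
#' @param times,events As in [km_estimate()].
#' @return List: `beta`, `hr`, `se`, `z`, `p`, `ci_lower`, `ci_upper`
#'   (95% Wald CI on the HR scale), `score_chisq` (score test statistic),
#'   `flagged_separation`.
#' @export
cox_univariate <- function(covariate, times, events) {
  stopifnot(length(covariate) == length(times), length(times) == length(events))
  if (any(!is.finite(covariate))) stop("covariate must be finite")
  if (stats::sd(covariate) == 0) stop("constant covariate")
  if (sum(events) < 1L) stop("no events")
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(times, events) ~ covariate, ties = "efron",
                    control = survival::coxph.control(eps = 1e-9, iter.max = 100)),
    warning = function(w) invokeRestart("muffleWarning"))
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(diag(fit$var)))
  separated <- !is.finite(beta) || abs(beta) > 15 || !is.finite(se)
  z <- beta / se
  s <- summary(fit)
  list(beta = beta, hr = exp(beta), se = se, z = z,
       p = 2 * stats::pnorm(-abs(z)),
       ci_lower = exp(beta - 1.96 * se), ci_upper = exp(beta + 1.96 * se),
       score_chisq = unname(s$sctest["test"]),
       flagged_separation = separated)
}

#' Median split of a continuous score
#'
#' Helper for the common dichotomization of per-sample scores at the cohort
#' median: values strictly above the median are "high", the rest "low".
#'
#' @param x Named numeric vector.
#' @return Named character vector of "high"/"low".
#' @export
median_split <- function(x) {
  m <- stats::median(x)
  stats::setNames(ifelse(x > m, "high", "low"), names(x))
}
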