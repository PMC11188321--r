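#' Kaplan-Meier estimate with median and landmark rates
#'
#' Product-limit estimator of the survival function; the median is the first
#' time at which S(t) <= 0.5 (NA when never reached, i.e. "not reached"),
#' and survival rates are reported at the landmark months requested.
#'
#' @param time follow-up times (months).
#' @param event event indicator (1 = progression/death, 0 = censored).
#' @param landmarks months at which to report S(t) (default 12/36/60).
#' @return list: `curve` (data.frame time/n_risk/surv/lower/upper),
#'   `median`, `rates` (named vector; NA when follow-up ends earlier).
#' @export
kmEstimate <- function(time, event, landmarks = c(12, 36, 60)) {
  stopifnot(length(time) >= 1, all(time >= 0), all(event %in% 0:1))
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  med <- unname(summary(sf)$table["median"])
  rates <- vapply(landmarks, function(t) {
    if (t < min(sf$time)) return(1)
    i <- max(which(sf$time <= t))
    sf$surv[i]
  }, numeric(1))
  # rates beyond the last follow-up are extrapolations; keep the last value
  list(curve = data.frame(time = sf$time, n_risk = sf$n.risk,
                          surv = sf$surv, lower = sf$lower,
                          upper = sf$upper),
       median = med,
       rates = stats::setNames(rates, paste0("S", landmarks)))
}

#' Log-rank test between survival groups
#'
#' @param time follow-up times.
#' @param event event indicators (0/1).
#' @param group group labels (>= 2 non-empty groups).
#' @return list: `statistic` (chi-square), `df`, `p`.
#' @export
logrankTest <- function(time, event, group) {
  group <- as.factor(group)
  if (any(table(group) == 0) || nlevels(droplevels(group)) < 2)
    stop("log-rank test needs at least two non-empty groups")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd$n) - 1
  list(statistic = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards ratio of a group covariate
#'
#' Partial-likelihood Cox fit (Efron tie handling) of a binary group
#' covariate; hazard ratio with Wald 95% CI and p-value. Monotone likelihood
#' (e.g. one group with no events at all comparable times) is detected and
#' raised as an explicit error.
#'
#' @param time follow-up times (months).
#' @param event event indicators (0/1).
#' @param group binary covariate (e.g. high vs low RadScore); the hazard
#'   ratio is for `group = 1` (or the second factor level) vs the reference.
#' @return list: `hr`, `ci` (length 2), `p`, `n` (group sizes),
#'   `coefficient`.
#' @export
coxHR <- function(time, event, group) {
  g <- if (is.factor(group)) as.integer(group) - 1L else as.integer(group)
  if (length(unique(g)) < 2) stop("group covariate is constant")
  if (sum(event[g == 0]) == 0 && sum(event[g == 1]) == 0)
    stop("no events in either group")
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ g, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|converge", conditionMessage(w)))
        stop("monotone partial likelihood: groups do not overlap in risk")
      invokeRestart("muffleWarning")
    })
  b <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  if (abs(b) > 15)
    stop("monotone partial likelihood: groups do not overlap in risk")
  z <- b / se
  list(hr = exp(b), ci = exp(b + c(-1.96, 1.96) * se),
       p = 2 * stats::pnorm(-abs(z)),
       n = c(low = sum(g == 0), high = sum(g == 1)), coefficient = b)
}
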