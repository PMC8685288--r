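#' Simulate right-censored pseudo individual-patient data
#'
#' Draws event times from a Weibull curve by inverse-CDF
#' (\eqn{t = (-\ln U/\lambda)^{1/\gamma}}) and applies administrative
#' (type I) censoring at a fixed follow-up time, optionally after a uniform
#' accrual window (each subject's follow-up is then
#' `admin_censor_time - entry`, entry ~ U(0, accrual)). This emulates the
#' structure of trial time-to-event data so the fitting stage is testable
#' without any external data.
#'
#' @param n Number of subjects.
#' @param curve A [weibull_curve()] for the event-time distribution.
#' @param admin_censor_time Administrative censoring time, months.
#' @param seed Integer seed; draws are reproducible.
#' @param arm Arm label recorded on every row.
#' @param accrual Length of the uniform accrual window in months (0 = all
#'   subjects enter at time zero).
#' @return A tibble with columns `time` (months), `event` (`TRUE` = event
#'   observed, `FALSE` = right-censored), `arm`.
#' @export
simulate_ipd <- function(n, curve, admin_censor_time = Inf, seed = 1,
                         arm = "arm", accrual = 0) {
  stopifnot(n >= 1, inherits(curve, "weibull_curve"),
            admin_censor_time >= 0, accrual >= 0)
  set.seed(seed)
  u <- stats::runif(n)
  t_event <- (-log(u) / curve$rate)^(1 / curve$shape)
  follow_up <- if (accrual > 0) {
    pmax(admin_censor_time - stats::runif(n, 0, accrual), 0)
  } else {
    rep(admin_censor_time, n)
  }
  tibble::tibble(
    time = pmin(t_event, follow_up),
    event = t_event <= follow_up,
    arm = arm
  )
}

#' Kaplan-Meier product-limit estimate
#'
#' Computes the product-limit survival estimate of right-censored data via
#' [survival::survfit()] and returns it as a tidy step table (steps at
#' event times only). With no censoring this equals one minus the empirical
#' CDF.
#'
#' @param data A data frame with columns `time` and `event` (logical or
#'   0/1), e.g. from [simulate_ipd()].
#' @return A tibble of class `km_curve` with columns `time`, `n_risk`,
#'   `n_event`, `survival`, containing a leading `(0, 1)` row and one row
#'   per distinct event time.
#' @export
km_estimate <- function(data) {
  stopifnot(nrow(data) > 0, all(c("time", "event") %in% names(data)))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           data = as.data.frame(data))
  s <- summary(fit, censored = FALSE)
  out <- tibble::tibble(time = c(0, s$time),
                        n_risk = c(nrow(data), s$n.risk),
                        n_event = c(0, s$n.event),
                        survival = c(1, s$surv))
  class(out) <- c("km_curve", class(out))
  out
}

#' @export
surv_prob.km_curve <- function(curve, t) {
  km_step(curve, t)
}
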