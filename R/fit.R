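#' Fit a Weibull accelerated-failure-time model to right-censored data
#'
#' Maximum-likelihood Weibull fit in the AFT parameterisation
#' (`intercept`, `log_scale`), the unconstrained scale on which normal
#' parameter uncertainty keeps the derived shape and rate positive. Fitting
#' is delegated to [survival::survreg()] (`dist = "weibull"`), whose
#' coefficient vector is exactly this parameterisation; standard errors come
#' from the observed-information variance matrix.
#'
#' @param data A data frame with columns `time` (> 0, months) and `event`
#'   (logical or 0/1; `TRUE` = event observed).
#' @return An object of class `weibull_fit`: AFT coefficients and standard
#'   errors, the derived `shape` and `rate`, counts and log-likelihood, and
#'   the underlying `survreg` fit. Has [tidy()] and [glance()] methods, and
#'   [as_curve()] converts it to a [weibull_curve()].
#' @examples
#' ipd <- simulate_ipd(500, weibull_curve(1, 0.1), admin_censor_time = 30, seed = 42)
#' fit <- fit_weibull_aft(ipd)
#' tidy(fit)
#' @export
fit_weibull_aft <- function(data) {
  stopifnot(all(c("time", "event") %in% names(data)))
  event <- as.logical(data$event)
  if (any(data$time <= 0)) stop("all times must be positive", call. = FALSE)
  if (sum(event) < 2) {
    stop("need at least 2 observed events to fit a Weibull model", call. = FALSE)
  }
  fit <- survival::survreg(survival::Surv(time, event) ~ 1,
                           data = data.frame(time = data$time, event = event),
                           dist = "weibull")
  if (!is.null(fit$flag) && fit$flag > 0 || any(!is.finite(coef(fit)))) {
    stop("Weibull fit did not converge", call. = FALSE)
  }
  se <- sqrt(diag(fit$var))
  sr <- aft_to_shape_rate(unname(stats::coef(fit)[1]), log(fit$scale))
  structure(list(
    intercept = unname(stats::coef(fit)[1]),
    log_scale = log(fit$scale),
    se_intercept = unname(se[1]),
    se_log_scale = unname(se[2]),
    shape = sr$shape, rate = sr$rate,
    n = nrow(data), n_events = sum(event),
    loglik = fit$loglik[1],
    fit = fit
  ), class = "weibull_fit")
}

#' Convert a fitted model to a survival curve
#'
#' @param x A [fit_weibull_aft()] result.
#' @return A [weibull_curve()].
#' @export
as_curve <- function(x) {
  UseMethod("as_curve")
}

#' @export
as_curve.weibull_fit <- function(x) {
  weibull_curve_aft(x$intercept, x$log_scale)
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf("<weibull_fit> n = %d (%d events)\n", x$n, x$n_events))
  cat(sprintf("  intercept %.5f (se %.5f), log_scale %.5f (se %.5f)\n",
              x$intercept, x$se_intercept, x$log_scale, x$se_log_scale))
  cat(sprintf("  shape %.5f, rate %.5f\n", x$shape, x$rate))
  invisible(x)
}

#' @export
tidy.weibull_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "log_scale", "shape", "rate"),
    estimate = c(x$intercept, x$log_scale, x$shape, x$rate),
    std.error = c(x$se_intercept, x$se_log_scale, NA_real_, NA_real_)
  )
}

#' @export
glance.weibull_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events, logLik = x$loglik,
                 median = median_survival(as_curve(x)))
}
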