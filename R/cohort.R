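#' Cohort model configuration
#'
#' Settings shared by every trace and accrual computation: cycle length and
#' horizon (months), annual discount rate applied as
#' \eqn{(1+r)^{-t/12}} at cycle midpoints, half-cycle correction flag,
#' health-state utilities, and the structural variant.
#'
#' The default structure is a partitioned-survival reading — state occupancy
#' taken directly from the OS and PFS curves, with the progressed-disease
#' share equal to their difference. The `markov_competing` variant instead
#' propagates per-cycle exits, treating progression and death as competing
#' risks out of the progression-free state and applying the OS hazard to the
#' progressed state.
#'
#' @param cycle_length Cycle length in months (1 month = 30.4375 days).
#' @param horizon Time horizon in months; must be a positive multiple of
#'   `cycle_length`. 240 months is effectively lifetime here: cohort
#'   survival is far below 0.1 percent by then for all base-case curves.
#' @param annual_discount Annual discount rate for costs and QALYs.
#' @param half_cycle Apply half-cycle correction (average of start- and
#'   end-of-cycle occupancy)?
#' @param utility_pf,utility_pd Health-state utilities in `[0, 1]` for the
#'   progression-free and progressed states (death has utility 0).
#' @param structure `"partitioned"` or `"markov_competing"`.
#' @return A list of class `model_config`.
#' @export
model_config <- function(cycle_length = 1, horizon = 240,
                         annual_discount = 0.03, half_cycle = TRUE,
                         utility_pf = 0.767, utility_pd = 0.647,
                         structure = c("partitioned", "markov_competing")) {
  structure_v <- match.arg(structure)
  stopifnot(cycle_length > 0, horizon > 0,
            annual_discount >= 0, annual_discount < 1,
            utility_pf >= 0, utility_pf <= 1,
            utility_pd >= 0, utility_pd <= 1)
  n_cycles <- horizon / cycle_length
  if (abs(n_cycles - round(n_cycles)) > 1e-8) {
    stop("horizon must be a positive multiple of cycle_length", call. = FALSE)
  }
  structure(list(cycle_length = cycle_length, horizon = horizon,
                 annual_discount = annual_discount, half_cycle = half_cycle,
                 utility_pf = utility_pf, utility_pd = utility_pd,
                 structure = structure_v, n_cycles = as.integer(round(n_cycles))),
            class = "model_config")
}

#' Build a per-cycle state-occupancy trace
#'
#' Propagates a cohort through the three states progression-free (`pf`),
#' progressed disease (`pd`) and dead over the model horizon. Under the
#' partitioned structure, `pf = S_PFS(t)`, `dead = 1 - S_OS(t)` and
#' `pd = S_OS(t) - S_PFS(t)` (clamped at zero, with a warning, should the
#' independently fitted PFS curve exceed OS). Under the competing-hazard
#' Markov structure, per-cycle exit probabilities from the two curves drive
#' the transitions and rows sum to one by construction.
#'
#' @param os_curve,pfs_curve `survival_curve` objects for overall and
#'   progression-free survival.
#' @param config A [model_config()].
#' @return A tibble of class `cohort_trace` with columns `cycle`, `time`
#'   (months at end of cycle), `pf`, `pd`, `dead`, and `discount` (the
#'   midpoint discount factor for the cycle ending at `time`; 1 in row 0).
#'   The configuration is attached as attribute `config`.
#' @export
build_trace <- function(os_curve, pfs_curve, config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  k <- 0:config$n_cycles
  t <- k * config$cycle_length
  s_os <- surv_prob(os_curve, t)
  s_pfs <- surv_prob(pfs_curve, t)

  if (config$structure == "partitioned") {
    pf <- s_pfs
    dead <- 1 - s_os
    pd <- s_os - s_pfs
    if (any(pd < -1e-9)) {
      warning("PFS exceeds OS at some cycles; PD occupancy clamped at 0",
              call. = FALSE)
      pf <- pmin(pf, s_os)
    }
    pd <- pmax(pd, 0)
  } else {
    n <- config$n_cycles
    pf <- pd <- dead <- numeric(n + 1L)
    pf[1] <- 1
    for (i in seq_len(n)) {
      q_os <- if (s_os[i] > 0) 1 - s_os[i + 1] / s_os[i] else 1
      q_pfs <- if (s_pfs[i] > 0) 1 - s_pfs[i + 1] / s_pfs[i] else 1
      q_os <- min(max(q_os, 0), 1)
      q_pfs <- min(max(q_pfs, q_os), 1)  # total exit from PF at least death
      pf[i + 1] <- pf[i] * (1 - q_pfs)
      pd[i + 1] <- pd[i] * (1 - q_os) + pf[i] * (q_pfs - q_os)
      dead[i + 1] <- dead[i] + pf[i] * q_os + pd[i] * q_os
    }
  }

  midpoint <- pmax(t - config$cycle_length / 2, 0)
  out <- tibble::tibble(
    cycle = k, time = t, pf = pf, pd = pd, dead = dead,
    discount = (1 + config$annual_discount)^(-midpoint / 12)
  )
  class(out) <- c("cohort_trace", class(out))
  attr(out, "config") <- config
  out
}

#' Discounted person-time spent in a state
#'
#' Sums occupancy over cycles times the cycle length. With half-cycle
#' correction the occupancy used for cycle `k` is the average of the
#' occupancies at its start and end (so at zero discount the result is the
#' trapezoid integral of the occupancy curve); without it, end-of-cycle
#' occupancy is used. Discounting applies the factor
#' \eqn{(1+r)^{-t/12}} evaluated at the cycle midpoint.
#'
#' @param trace A [build_trace()] result.
#' @param state One of `"pf"`, `"pd"`, `"dead"`.
#' @param discounted Apply the configured discount rate?
#' @return Person-months per cohort member.
#' @export
state_time <- function(trace, state = c("pf", "pd", "dead"),
                       discounted = TRUE) {
  state <- match.arg(state)
  config <- attr(trace, "config")
  stopifnot(inherits(config, "model_config"))
  occ <- trace[[state]]
  n <- length(occ) - 1L
  w <- if (config$half_cycle) (occ[-(n + 1L)] + occ[-1L]) / 2 else occ[-1L]
  disc <- if (discounted) trace$discount[-1L] else rep(1, n)
  sum(w * disc) * config$cycle_length
}

#' Discounted state times for both accruing states
#'
#' @param trace A [build_trace()] result.
#' @param discounted Apply the configured discount rate?
#' @return A one-row tibble with `pf_months` and `pd_months`.
#' @export
state_times <- function(trace, discounted = TRUE) {
  tibble::tibble(
    pf_months = state_time(trace, "pf", discounted),
    pd_months = state_time(trace, "pd", discounted)
  )
}
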