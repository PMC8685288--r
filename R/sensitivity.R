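#' Default one-way sensitivity parameter table
#'
#' Every cost, utility and Weibull shape/rate parameter varied by plus or
#' minus 10 percent of its base value (the published perturbed placebo OS
#' shape, 0.89911, is exactly 0.9 times its base value, which fixes the
#' range convention). Utility upper bounds are capped at 1.
#'
#' @param inputs Model inputs, see [gist_inputs()].
#' @param rel_range Half-width of the relative range (0.1 = +/-10 percent).
#' @return A tibble with columns `parameter`, `base`, `low`, `high`.
#' @export
default_dsa_params <- function(inputs = gist_inputs(), rel_range = 0.1) {
  base <- c(
    drug_cost_monthly = inputs$arms$ripretinib$drug_cost_monthly,
    bsc_cost_monthly = inputs$arms$ripretinib$bsc_cost_monthly,
    ae_onetime_cost = inputs$arms$ripretinib$ae_onetime_cost,
    ct_cost_per_cycle = inputs$arms$ripretinib$ct_cost_per_cycle,
    utility_pf = inputs$config$utility_pf,
    utility_pd = inputs$config$utility_pd
  )
  for (a in names(inputs$curves)) {
    for (e in names(inputs$curves[[a]])) {
      cv <- inputs$curves[[a]][[e]]
      base[[paste(e, a, "shape", sep = "_")]] <- cv$shape
      base[[paste(e, a, "rate", sep = "_")]] <- cv$rate
    }
  }
  out <- tibble::tibble(parameter = names(base), base = unname(base),
                        low = unname(base) * (1 - rel_range),
                        high = unname(base) * (1 + rel_range))
  out$high[out$parameter %in% c("utility_pf", "utility_pd")] <-
    pmin(out$high[out$parameter %in% c("utility_pf", "utility_pd")], 1)
  out
}

#' One-way deterministic sensitivity sweep (tornado table)
#'
#' Re-evaluates the ICER with each parameter set to its low and high value,
#' all others at base. Rows are ordered by descending ICER range width;
#' evaluations whose comparison is dominant, dominated or undefined carry
#' their flag instead of a number and are excluded from the width ordering.
#'
#' @param params Parameter table, see [default_dsa_params()].
#' @param model A [ce_model()] evaluator (built from default inputs if omitted).
#' @return A tibble of class `tornado_table` with columns `parameter`,
#'   `base`, `low`, `high`, `icer_low`, `icer_high`, `status_low`,
#'   `status_high`, `width`, plus the base-case ICER as attribute
#'   `icer_base`.
#' @export
one_way_sweep <- function(params = default_dsa_params(), model = ce_model()) {
  stopifnot(all(c("parameter", "base", "low", "high") %in% names(params)),
            all(params$low <= params$base + 1e-12),
            all(params$base <= params$high + 1e-12))
  eval_at <- function(parameter, value) {
    ov <- stats::setNames(list(value), parameter)
    model(ov)
  }
  res <- purrr::pmap_dfr(params, function(parameter, base, low, high) {
    lo <- eval_at(parameter, low)
    hi <- eval_at(parameter, high)
    tibble::tibble(parameter = parameter, base = base, low = low, high = high,
                   icer_low = lo$icer, icer_high = hi$icer,
                   status_low = lo$status, status_high = hi$status)
  })
  res$width <- ifelse(res$status_low == "ok" & res$status_high == "ok",
                      abs(res$icer_high - res$icer_low), NA_real_)
  res <- dplyr::arrange(res, dplyr::desc(!is.na(.data$width)),
                        dplyr::desc(.data$width))
  attr(res, "icer_base") <- model(list())$icer
  class(res) <- c("tornado_table", class(res))
  res
}

#' Price sweep over the monthly drug price
#'
#' Re-runs the base case over a grid of monthly intervention-drug prices
#' (applied to both the intervention PF drug cost and the comparator
#' crossover term), all other inputs at base. Incremental effectiveness is
#' constant across rows.
#'
#' @param prices Nonnegative vector of monthly prices (USD). Defaults to
#'   the published grid, 10 to 100 percent of the list price.
#' @param inputs Model inputs, see [gist_inputs()].
#' @param fixture Calibrated state-time fixture (computed if omitted); pass
#'   `NULL` to sweep on raw Weibull traces.
#' @return A tibble of class `price_sweep_table` with columns `price`,
#'   `total_cost`, `total_qaly`, `incremental_cost`, `incremental_qaly`,
#'   `icer`, `status`.
#' @export
price_sweep <- function(prices = seq(3200, 32000, by = 3200),
                        inputs = gist_inputs(),
                        fixture = calibrate_fixture(inputs = inputs)) {
  stopifnot(all(prices >= 0))
  res <- purrr::map_dfr(prices, function(p) {
    cmp <- base_case(inputs, fixture = fixture, price = p)
    tibble::tibble(price = p,
                   total_cost = cmp$arms$cost_total[1],
                   total_qaly = cmp$arms$qaly_total[1],
                   incremental_cost = cmp$incremental_cost,
                   incremental_qaly = cmp$incremental_qaly,
                   icer = cmp$icer, status = cmp$status)
  })
  class(res) <- c("price_sweep_table", class(res))
  res
}

#' Value-based price threshold
#'
#' Finds the monthly drug price at which the ICER equals a willingness-to-pay
#' threshold. The cost response is affine in price (slope equal to the
#' discounted drug-month differential), so a closed-form linear inversion is
#' used, verified by a model re-run; if the recipe is not affine (verification
#' off by more than `tol`), bisection on `[0, price_max]` takes over.
#'
#' @param wtp Willingness-to-pay in USD per QALY.
#' @param inputs Model inputs, see [gist_inputs()].
#' @param fixture Calibrated state-time fixture (computed if omitted);
#'   `NULL` for raw Weibull traces.
#' @param tol Tolerance on the achieved ICER, USD per QALY.
#' @param price_max Upper bracket for the bisection fallback.
#' @return Monthly price in USD (a length-1 numeric).
#' @export
threshold_price <- function(wtp, inputs = gist_inputs(),
                            fixture = calibrate_fixture(inputs = inputs),
                            tol = 0.5, price_max = 1e6) {
  icer_at <- function(p) {
    cmp <- base_case(inputs, fixture = fixture, price = p)
    if (cmp$status != "ok") -Inf else cmp$icer
  }
  p0 <- inputs$arms$ripretinib$drug_cost_monthly
  i0 <- icer_at(p0)
  i_zero <- icer_at(0)
  if (is.finite(i_zero) && i_zero > wtp) {
    stop("willingness-to-pay unreachable at any nonnegative price", call. = FALSE)
  }
  # linear inversion through (0, icer(0)) and (p0, icer(p0))
  p_star <- p0 * (wtp - i_zero) / (i0 - i_zero)
  if (is.finite(p_star) && p_star >= 0 &&
      abs(icer_at(p_star) - wtp) <= tol) {
    return(p_star)
  }
  lo <- 0
  hi <- price_max
  if (icer_at(hi) < wtp) stop("willingness-to-pay above any ICER in the bracket", call. = FALSE)
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (icer_at(mid) > wtp) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Default probabilistic sensitivity specifications
#'
#' Gamma distributions for the cost inputs, beta for the utilities, and
#' normal distributions for the Weibull survival coefficients on the
#' (intercept, log_scale) scale — where derived shape and rate remain
#' positive for any draw. The source analysis does not state its
#' dispersions; the defaults here are a coefficient of variation of 0.2 for
#' costs, 0.1 for utilities, and an absolute standard error of 0.1 for the
#' AFT coefficients.
#'
#' @param inputs Model inputs, see [gist_inputs()].
#' @param cv_cost,cv_utility Coefficients of variation for cost and utility
#'   parameters.
#' @param se_survival Absolute standard error for AFT intercept and
#'   log_scale coefficients.
#' @return A tibble with columns `parameter`, `base`, `distribution`
#'   (`"gamma"`, `"beta"`, `"normal"` or `"fixed"`), `dispersion` (CV for
#'   gamma/beta, absolute SE for normal).
#' @export
default_psa_specs <- function(inputs = gist_inputs(), cv_cost = 0.2,
                              cv_utility = 0.1, se_survival = 0.1) {
  specs <- tibble::tibble(
    parameter = c("drug_cost_monthly", "bsc_cost_monthly",
                  "ae_onetime_cost", "ct_cost_per_cycle",
                  "utility_pf", "utility_pd"),
    base = c(inputs$arms$ripretinib$drug_cost_monthly,
             inputs$arms$ripretinib$bsc_cost_monthly,
             inputs$arms$ripretinib$ae_onetime_cost,
             inputs$arms$ripretinib$ct_cost_per_cycle,
             inputs$config$utility_pf, inputs$config$utility_pd),
    distribution = c(rep("gamma", 4), rep("beta", 2)),
    dispersion = c(rep(cv_cost, 4), rep(cv_utility, 2))
  )
  surv <- inputs$survival_params
  specs_surv <- tibble::tibble(
    parameter = c(paste(surv$endpoint, surv$arm, "intercept", sep = "_"),
                  paste(surv$endpoint, surv$arm, "log_scale", sep = "_")),
    base = c(surv$intercept, surv$log_scale),
    distribution = "normal",
    dispersion = se_survival
  )
  dplyr::bind_rows(specs, specs_surv)
}

# deterministic per-parameter stream seed so adding a parameter does not
# reshuffle the draws of the others
param_seed <- function(seed, name) {
  h <- as.double(seed %% 2147483647L)
  for (b in utf8ToInt(name)) h <- (h * 31 + b) %% 2147483647
  as.integer(h) + 1L
}

# draw n values for one PSA spec row; moments matched to (base, dispersion)
draw_param <- function(parameter, base, distribution, dispersion, n, seed) {
  if (distribution == "fixed" || dispersion == 0) return(rep(base, n))
  set.seed(param_seed(seed, parameter))
  switch(distribution,
    gamma = {
      stopifnot(base > 0)
      shape <- 1 / dispersion^2
      stats::rgamma(n, shape = shape, rate = shape / base)
    },
    beta = {
      stopifnot(base > 0, base < 1)
      v <- (dispersion * base)^2
      if (v >= base * (1 - base)) {
        stop("beta moment matching infeasible for ", parameter,
             ": variance >= mean(1-mean)", call. = FALSE)
      }
      k <- base * (1 - base) / v - 1
      stats::rbeta(n, shape1 = base * k, shape2 = (1 - base) * k)
    },
    normal = stats::rnorm(n, mean = base, sd = dispersion),
    stop("unknown distribution: ", distribution, call. = FALSE)
  )
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n` parameter sets from the specified distributions (moments
#' matched to each base value and dispersion), re-evaluates the model for
#' each, and records incremental cost and effectiveness. A single root
#' `seed` spawns an independent reproducible stream per parameter, so
#' adding a parameter does not reshuffle the draws of the others.
#'
#' @param n Number of Monte Carlo draws.
#' @param seed Integer root seed.
#' @param specs Specification table, see [default_psa_specs()].
#' @param model A [ce_model()] evaluator (built from default inputs if omitted).
#' @return A tibble of class `psa_samples`: `draw`, one column per drawn
#'   parameter, `incremental_cost`, `incremental_qaly`, `icer`, `status`.
#' @export
psa_run <- function(n = 10000, seed = 1, specs = default_psa_specs(),
                    model = ce_model()) {
  stopifnot(n >= 1)
  draws <- purrr::pmap(specs, draw_param, n = n, seed = seed)
  names(draws) <- specs$parameter
  draw_tbl <- tibble::as_tibble(draws)
  res <- purrr::map_dfr(seq_len(n), function(i) {
    model(as.list(draw_tbl[i, ]))[, c("incremental_cost", "incremental_qaly",
                                      "icer", "status")]
  })
  out <- dplyr::bind_cols(tibble::tibble(draw = seq_len(n)), draw_tbl, res)
  class(out) <- c("psa_samples", class(out))
  out
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value `w`, the fraction of PSA draws with
#' nonnegative net monetary benefit, \eqn{w\,\Delta E - \Delta C \ge 0}.
#'
#' @param samples A [psa_run()] result (or any data frame with
#'   `incremental_cost` and `incremental_qaly` columns).
#' @param wtp_grid Vector of willingness-to-pay values (USD/QALY).
#' @return A tibble of class `ceac_curve` with columns `wtp` and
#'   `prob_cost_effective`.
#' @export
ceac <- function(samples, wtp_grid = seq(0, 300000, by = 5000)) {
  stopifnot(nrow(samples) > 0)
  out <- tibble::tibble(
    wtp = wtp_grid,
    prob_cost_effective = vapply(wtp_grid, function(w) {
      mean(w * samples$incremental_qaly - samples$incremental_cost >= 0)
    }, numeric(1))
  )
  class(out) <- c("ceac_curve", class(out))
  out
}
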