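test_that("AFT coefficients map onto every published shape/rate pair", {
  tab <- table1_weibulls()
  sr <- aft_to_shape_rate(tab$intercept, tab$log_scale)
  expect_true(all(rel_err(sr$shape, tab$shape) < 1e-3))
  expect_true(all(rel_err(sr$rate, tab$rate) < 1e-3))
  # identity case
  expect_equal(as.numeric(aft_to_shape_rate(0, 0)), c(1, 1))
})

test_that("surv_prob evaluates the Weibull survivor function", {
  tab <- table1_weibulls()
  rip_os <- weibull_curve(1.535033646, 0.013971806)
  expect_equal(surv_prob(rip_os, 0), 1)
  # frozen from direct high-precision evaluation of exp(-lambda * 12^gamma)
  expect_equal(round(surv_prob(rip_os, 12), 3), 0.531)
  # closed-form median inversion for every published curve
  for (i in seq_len(nrow(tab))) {
    cv <- weibull_curve(tab$shape[i], tab$rate[i])
    t_med <- (log(2) / tab$rate[i])^(1 / tab$shape[i])
    expect_equal(surv_prob(cv, t_med), 0.5, tolerance = 1e-12)
  }
  expect_error(surv_prob(rip_os, -1), "nonnegative")
})

test_that("surv_prob is nonincreasing on grids for every curve type", {
  grid <- seq(0, 120, by = 0.25)
  tab <- table1_weibulls()
  for (i in seq_len(nrow(tab))) {
    s <- surv_prob(weibull_curve(tab$shape[i], tab$rate[i]), grid)
    expect_true(all(diff(s) <= 0))
    expect_true(all(s >= 0 & s <= 1))
  }
  hyb <- hybrid_curve(
    km = data.frame(time = c(0, 2, 5), survival = c(1, 0.8, 0.55)),
    tail = weibull_curve(1.2, 0.08), junction = 5
  )
  s <- surv_prob(hyb, grid)
  expect_true(all(diff(s) <= 1e-12))
})

test_that("median_survival inverts the curve", {
  placebo_os <- weibull_curve(0.999014696, 0.105568583)
  expect_equal(round(median_survival(placebo_os), 1), 6.6)
  # exponential with rate log(2) has unit median
  expect_equal(median_survival(weibull_curve(1, log(2))), 1)
  rip_pfs <- weibull_curve(1.096622663, 0.102752314)
  expect_equal(median_survival(rip_pfs), 5.70, tolerance = 1e-3)
  # |S(median) - 0.5| < 1e-6 holds for hybrid curves via bisection too
  hyb <- hybrid_curve(
    km = data.frame(time = c(0, 3), survival = c(1, 0.8)),
    tail = weibull_curve(1.3, 0.05), junction = 3
  )
  expect_lt(abs(surv_prob(hyb, median_survival(hyb)) - 0.5), 1e-6)
  flat <- hybrid_curve(km = data.frame(time = 0, survival = 1),
                       tail = weibull_curve(1, 1e-9), junction = 0)
  expect_error(median_survival(flat, horizon = 100), "does not reach")
})

test_that("restricted_mean matches the Gamma-function closed form", {
  # exponential: discount-free restricted mean tends to 1/rate
  expect_equal(restricted_mean(weibull_curve(1, 0.25), horizon = 400), 4,
               tolerance = 1e-4)
  tab <- table1_weibulls()
  for (i in seq_len(nrow(tab))) {
    rm <- restricted_mean(weibull_curve(tab$shape[i], tab$rate[i]),
                          horizon = 240)
    expect_lt(rel_err(rm, weibull_mean_closed_form(tab$shape[i], tab$rate[i])),
              0.005)
  }
  placebo <- table1_weibulls()[table1_weibulls()$arm == "placebo", ]
  expect_equal(restricted_mean(weibull_curve(placebo$shape[2], placebo$rate[2]), 240),
               2.03, tolerance = 0.005)
  expect_equal(restricted_mean(weibull_curve(placebo$shape[1], placebo$rate[1]), 240),
               9.50, tolerance = 0.005)
  # discounting shrinks the integral
  cv <- weibull_curve(1.2, 0.1)
  expect_lt(restricted_mean(cv, 240, annual_discount = 0.03),
            restricted_mean(cv, 240))
})

test_that("per-cycle exit probabilities follow the hazard", {
  expo <- weibull_curve(1, 0.2)
  p <- per_cycle_exit_prob(expo, 1:20, cycle_len = 1)
  expect_equal(p, rep(1 - exp(-0.2), 20), tolerance = 1e-12)
  rip_os <- weibull_curve(1.535033646, 0.013971806)
  expect_equal(per_cycle_exit_prob(rip_os, 1, 1), 1 - exp(-0.013971806),
               tolerance = 1e-9)
  # increasing hazard for shape > 1 gives a strictly increasing sequence
  p2 <- per_cycle_exit_prob(rip_os, 1:60, 1)
  expect_true(all(diff(p2) > 0))
})

test_that("hybrid curves are continuous and proportional beyond the junction", {
  km <- data.frame(time = c(0, 1, 2, 4), survival = c(1, 0.9, 0.75, 0.6))
  tail <- weibull_curve(1.4, 0.07)
  hyb <- hybrid_curve(km, tail, junction = 4)
  expect_equal(surv_prob(hyb, 4), 0.6)
  # tail segment ratio equals pure-Weibull conditional survival
  expect_equal(surv_prob(hyb, 8) / surv_prob(hyb, 4),
               surv_prob(tail, 8) / surv_prob(tail, 4), tolerance = 1e-12)
  # empty KM table with junction 0 degenerates to the pure Weibull
  pure <- hybrid_curve(data.frame(time = numeric(), survival = numeric()),
                       tail, junction = 0)
  tt <- c(0, 1, 5, 20)
  expect_equal(surv_prob(pure, tt), surv_prob(tail, tt))
  expect_error(hybrid_curve(km, tail, junction = 10), "junction")
  expect_error(hybrid_curve(data.frame(time = c(0, 1), survival = c(0.5, 0.9)),
                            tail, junction = 1), "nonincreasing")
})
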