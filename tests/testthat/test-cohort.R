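test_that("traces conserve occupancy and death is monotone in both structures", {
  inp <- gist_inputs()
  for (structure in c("partitioned", "markov_competing")) {
    cfg <- model_config(structure = structure)
    for (arm in c("ripretinib", "placebo")) {
      tr <- suppressWarnings(
        build_trace(inp$curves[[arm]]$os, inp$curves[[arm]]$pfs, cfg))
      expect_true(all(abs(tr$pf + tr$pd + tr$dead - 1) < 1e-9))
      expect_true(all(diff(tr$dead) >= -1e-12))
      expect_true(all(tr$pf >= -1e-12 & tr$pd >= -1e-12))
      expect_true(all(diff(tr$pf) <= 1e-12))
    }
  }
})

test_that("competing-hazard occupancy never exceeds the partitioned trace", {
  inp <- gist_inputs()
  tr_p <- suppressWarnings(build_trace(inp$curves$ripretinib$os,
                                       inp$curves$ripretinib$pfs,
                                       model_config(structure = "partitioned")))
  tr_m <- build_trace(inp$curves$ripretinib$os, inp$curves$ripretinib$pfs,
                      model_config(structure = "markov_competing"))
  expect_true(all(tr_m$pf <= tr_p$pf + 1e-9))
})

test_that("PFS above OS is clamped with a warning", {
  # the intervention PFS tail decays slower than OS, so the independent fits
  # cross late in the horizon
  inp <- gist_inputs()
  expect_warning(
    tr <- build_trace(inp$curves$ripretinib$os, inp$curves$ripretinib$pfs,
                      model_config()),
    "clamped")
  expect_true(all(tr$pd >= 0))
  expect_true(all(tr$pf <= surv_prob(inp$curves$ripretinib$os, tr$time) + 1e-12))
})

test_that("state_time reduces to the plain occupancy sum and shrinks under discounting", {
  cfg0 <- model_config(annual_discount = 0, half_cycle = FALSE)
  cv_os <- weibull_curve(1.2, 0.05)
  cv_pfs <- weibull_curve(1.3, 0.1)
  tr <- build_trace(cv_os, cv_pfs, cfg0)
  expect_equal(state_time(tr, "pf"), sum(tr$pf[-1]) * cfg0$cycle_length)
  cfg_d <- model_config(annual_discount = 0.05, half_cycle = FALSE)
  tr_d <- build_trace(cv_os, cv_pfs, cfg_d)
  expect_lt(state_time(tr_d, "pf", discounted = TRUE),
            state_time(tr_d, "pf", discounted = FALSE))
})

test_that("half-cycle correction at zero discount equals the trapezoid integral", {
  cfg <- model_config(annual_discount = 0, half_cycle = TRUE)
  cv_os <- weibull_curve(1.535033646, 0.013971806)
  cv_pfs <- weibull_curve(1.096622663, 0.102752314)
  tr <- suppressWarnings(build_trace(cv_os, cv_pfs, cfg))
  trap <- sum((tr$pf[-1] + tr$pf[-nrow(tr)]) / 2) * cfg$cycle_length
  expect_equal(state_time(tr, "pf"), trap, tolerance = 1e-12)
})

test_that("PF-only collapse recovers the exponential mean on a fine grid", {
  rate <- 0.1
  expo <- weibull_curve(1, rate)
  cfg <- model_config(cycle_length = 0.1, horizon = 240, annual_discount = 0,
                      half_cycle = TRUE)
  tr <- build_trace(expo, expo, cfg)
  expect_equal(state_time(tr, "pf"), 1 / rate, tolerance = 1e-3)
})

test_that("halving the cycle length changes state times by less than 1%", {
  inp <- gist_inputs()
  for (arm in c("ripretinib", "placebo")) {
    t1 <- state_times(suppressWarnings(
      build_trace(inp$curves[[arm]]$os, inp$curves[[arm]]$pfs,
                  model_config(cycle_length = 1))))
    t2 <- state_times(suppressWarnings(
      build_trace(inp$curves[[arm]]$os, inp$curves[[arm]]$pfs,
                  model_config(cycle_length = 0.5))))
    expect_lt(rel_err(t2$pf_months, t1$pf_months), 0.01)
    expect_lt(rel_err(t2$pd_months, t1$pd_months), 0.01)
  }
})

test_that("placebo partitioned trace reproduces the published effectiveness", {
  inp <- gist_inputs()
  tr <- suppressWarnings(
    build_trace(inp$curves$placebo$os, inp$curves$placebo$pfs, inp$config))
  q <- accrue_qalys(state_times(tr), inp$config)
  expect_equal(round(q$qaly_pf, 2), 0.13)
  expect_equal(round(q$qaly_pd, 2), 0.39)
})
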