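test_that("cost accrual follows the state-time recipe", {
  inp <- gist_inputs()
  zero <- tibble::tibble(pf_months = 0, pd_months = 0)
  c0 <- accrue_costs(zero, inp$arms$ripretinib, inp$config)
  expect_equal(c0$cost_pf, inp$arms$ripretinib$ae_onetime_cost)
  expect_equal(c0$cost_pd, 0)
  # one PF month accrues drug + BSC + one CT cycle
  one <- tibble::tibble(pf_months = 1, pd_months = 0)
  c1 <- accrue_costs(one, inp$arms$ripretinib, inp$config)
  expect_equal(c1$cost_pf, 32000 + 3382.47 + 1365.39 + 421.2)
  # comparator PD months accrue BSC plus crossover-weighted drug cost
  pd1 <- tibble::tibble(pf_months = 0, pd_months = 1)
  c2 <- accrue_costs(pd1, inp$arms$placebo, inp$config)
  expect_equal(c2$cost_pd, 3382.47 + 29 / 44 * 32000)
  expect_equal(c2$cost_total, c2$cost_pf + c2$cost_pd)
})

test_that("QALY accrual weights person-years by state utilities", {
  cfg <- model_config()
  st <- tibble::tibble(pf_months = 6, pd_months = 3)
  q <- accrue_qalys(st, cfg)
  expect_equal(q$qaly_pf, 6 / 12 * 0.767)
  expect_equal(q$qaly_pd, 3 / 12 * 0.647)
  cfg0 <- model_config(utility_pf = 0, utility_pd = 0)
  q0 <- accrue_qalys(st, cfg0)
  expect_equal(c(q0$qaly_pf, q0$qaly_pd), c(0, 0))
})

test_that("ce_compare computes incrementals, ICER and dominance flags", {
  mk <- function(arm, cost, qaly) {
    tibble::tibble(arm = arm, pf_months = 1, pd_months = 1,
                   cost_pf = cost, cost_pd = 0, cost_total = cost,
                   qaly_pf = qaly, qaly_pd = 0, qaly_total = qaly)
  }
  d_e <- 70251 / 244010
  cmp <- ce_compare(mk("a", 70251, d_e), mk("b", 0, 0))
  expect_equal(cmp$icer, 244010)
  expect_equal(cmp$status, "ok")
  dom <- ce_compare(mk("a", -1, 0.1), mk("b", 0, 0))
  expect_equal(dom$status, "dominant")
  expect_true(is.na(dom$icer))
  ded <- ce_compare(mk("a", 1, -0.1), mk("b", 0, 0))
  expect_equal(ded$status, "dominated")
  und <- ce_compare(mk("a", 1, 0.5), mk("b", 0, 0.5))
  expect_equal(und$status, "undefined")
  g <- glance(cmp)
  expect_equal(g$incremental_cost, 70251)
})

test_that("calibrated fixture reproduces the published base case", {
  fx <- calibrate_fixture()
  expect_equal(fx$incremental_qaly, 70251 / 244010, tolerance = 1e-12)
  # drug-month differential implied by the printed price sweep
  expect_equal(fx$drug_month_diff, (70251 - 46115) / 16000, tolerance = 1e-3)
  expect_true(all(fx$times$pf_months > 0 & fx$times$pd_months > 0))
  bc <- base_case()
  expect_equal(bc$arms$cost_total, c(260105, 189854), tolerance = 1e-6)
  expect_equal(bc$incremental_cost, 70251, tolerance = 1e-6)
  expect_equal(bc$icer, 244010, tolerance = 1e-6)
  # spec'd example cells within 0.5%
  expect_lt(rel_err(bc$arms$cost_pf[1], 234808), 0.005)
  expect_lt(rel_err(bc$arms$cost_pd[2], 180349), 0.005)
  # totals are exact sums of their state components
  expect_equal(bc$arms$cost_total, bc$arms$cost_pf + bc$arms$cost_pd)
  expect_equal(bc$arms$qaly_total, bc$arms$qaly_pf + bc$arms$qaly_pd)
})

test_that("pure-Weibull placebo arm reproduces published totals without the fixture", {
  bc <- suppressWarnings(base_case(fixture = NULL))
  placebo <- bc$arms[bc$arms$arm == "placebo", ]
  expect_lt(rel_err(placebo$cost_total, 189854), 0.02)
  expect_equal(round(placebo$qaly_total, 2), 0.52)
})

test_that("infeasible printed cells are flagged as a recipe mismatch", {
  cells <- published_base_case()
  cells$placebo[cells$quantity == "cost_pf"] <- 100  # below the AE charge
  expect_error(calibrate_fixture(base_case_cells = cells), "infeasible")
})

test_that("scaling both utilities scales effectiveness and divides the ICER", {
  m <- ce_model()
  base <- m(list())
  half <- m(list(utility_pf = 0.767 / 2, utility_pd = 0.647 / 2))
  expect_equal(half$incremental_qaly, base$incremental_qaly / 2,
               tolerance = 1e-9)
  expect_equal(half$icer, base$icer * 2, tolerance = 1e-9)
})
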