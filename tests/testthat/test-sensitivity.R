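test_that("the one-way range convention reproduces the published perturbed shape", {
  params <- default_dsa_params()
  row <- params[params$parameter == "os_placebo_shape", ]
  expect_equal(round(row$low, 5), 0.89911)
  # degenerate range gives a zero-width row
  m <- ce_model()
  tor <- one_way_sweep(tibble::tibble(parameter = "utility_pf", base = 0.767,
                                      low = 0.767, high = 0.767), m)
  expect_equal(tor$width, 0)
  expect_equal(tor$icer_low, tor$icer_high)
})

test_that("lowering placebo OS shape makes the intervention strictly more favorable", {
  inp <- gist_inputs()
  for (anchor in c("fixture", "weibull")) {
    m <- ce_model(inp, anchor = anchor)
    base <- m(list())
    low <- m(list(os_placebo_shape = 0.9 * inp$curves$placebo$os$shape))
    # dominance (negative incremental cost) counts as an ICER decrease
    expect_true(low$status == "dominant" ||
                  (low$status == "ok" && low$icer < base$icer))
  }
})

test_that("tornado rows are ordered by width and flagged rows excluded", {
  m <- ce_model()
  params <- default_dsa_params()[c(1, 2, 5), ]  # drug, BSC, utility_pf
  tor <- one_way_sweep(params, m)
  w <- tor$width[!is.na(tor$width)]
  expect_true(all(diff(w) <= 0))
  expect_s3_class(tor, "tornado_table")
  expect_true(is.finite(attr(tor, "icer_base")))
})

test_that("price sweep matches all published rows within 0.5%", {
  sweep <- price_sweep()
  pub <- published_price_sweep()
  expect_equal(sweep$price, pub$price)
  expect_true(all(rel_err(sweep$incremental_cost, pub$incremental_cost) < 0.005))
  expect_true(all(rel_err(sweep$icer, pub$icer) < 0.005))
  expect_true(all(rel_err(sweep$total_cost, pub$total_cost) < 0.005))
  # spot targets
  expect_lt(rel_err(sweep$icer[sweep$price == 16000], 160178), 0.005)
  expect_lt(rel_err(sweep$icer[sweep$price == 3200], 93113), 0.005)
  # identity row: list price reproduces the base case
  expect_equal(sweep$icer[sweep$price == 32000], base_case()$icer,
               tolerance = 1e-9)
  # effectiveness constant across rows
  expect_equal(length(unique(round(sweep$incremental_qaly, 12))), 1L)
  # affine price response with slope D / dE
  fx <- calibrate_fixture()
  pred <- sweep$icer[10] - (32000 - sweep$price) * fx$drug_month_diff / fx$incremental_qaly
  expect_equal(sweep$icer, pred, tolerance = 1e-9)
})

test_that("threshold price inverts the ICER within tolerance", {
  inp <- gist_inputs()
  fx <- calibrate_fixture(inputs = inp)
  p150 <- threshold_price(150000, inp, fx)
  expect_lt(abs(p150 - 14057), 25)
  # fixed point at the base-case ICER
  expect_equal(threshold_price(base_case()$icer, inp, fx), 32000,
               tolerance = 1e-3)
  # closed-form linear inversion oracle at another willingness-to-pay
  bc <- base_case(inp, fx)
  p200_oracle <- 32000 -
    (bc$incremental_cost - 200000 * fx$incremental_qaly) / fx$drug_month_diff
  expect_equal(threshold_price(200000, inp, fx), p200_oracle, tolerance = 1e-3)
  expect_equal(round(p200_oracle), 23600, tolerance = 1)
  # re-running the model at the threshold price returns the target ICER
  for (w in c(100000, 150000, 244010)) {
    p <- threshold_price(w, inp, fx)
    expect_lt(abs(base_case(inp, fx, price = p)$icer - w), 1)
  }
  expect_error(threshold_price(1, inp, fx), "unreachable")
})

test_that("PSA draws are seeded, reproducible and moment-matched", {
  m <- ce_model()
  a <- psa_run(n = 50, seed = 9, model = m)
  b <- psa_run(n = 50, seed = 9, model = m)
  expect_identical(a, b)
  # zero dispersion collapses every draw to the base case
  specs0 <- default_psa_specs()
  specs0$dispersion <- 0
  s0 <- psa_run(n = 5, seed = 1, specs = specs0, model = m)
  base <- m(list())
  expect_true(all(abs(s0$incremental_cost - base$incremental_cost) < 1e-9))
  expect_true(all(abs(s0$incremental_qaly - base$incremental_qaly) < 1e-9))
  # adding a parameter must not reshuffle the streams of the others
  specs_drop <- default_psa_specs()[-1, ]
  s_full <- psa_run(n = 20, seed = 4, model = m)
  s_drop <- psa_run(n = 20, seed = 4, specs = specs_drop, model = m)
  expect_equal(s_full$bsc_cost_monthly, s_drop$bsc_cost_monthly)
  # tiny dispersions converge to the deterministic base case
  specs_eps <- default_psa_specs(cv_cost = 1e-6, cv_utility = 1e-6,
                                 se_survival = 1e-6)
  s_eps <- psa_run(n = 10, seed = 2, specs = specs_eps, model = m)
  expect_true(all(rel_err(s_eps$incremental_cost, base$incremental_cost) < 1e-3))
})

test_that("infeasible beta moment matching is rejected", {
  specs <- default_psa_specs()
  specs$dispersion[specs$parameter == "utility_pf"] <- 2
  expect_error(psa_run(n = 2, seed = 1, specs = specs, model = ce_model()),
               "moment matching infeasible")
})

test_that("the acceptability curve behaves as a distribution function", {
  m <- ce_model()
  s <- psa_run(n = 300, seed = 12, model = m)
  grid <- seq(0, 500000, by = 25000)
  curve <- ceac(s, grid)
  expect_true(all(curve$prob_cost_effective >= 0 &
                    curve$prob_cost_effective <= 1))
  # at w = 0 the curve equals the fraction of cost-saving draws
  expect_equal(curve$prob_cost_effective[1], mean(s$incremental_cost <= 0))
  # monotone over draws with positive incremental effectiveness
  pos <- s[s$incremental_qaly > 0, ]
  curve_pos <- ceac(pos, grid)
  expect_true(all(diff(curve_pos$prob_cost_effective) >= 0))
  # large willingness-to-pay accepts every positive-effect draw
  expect_equal(ceac(pos, 1e9)$prob_cost_effective, 1)
  # degenerate PSA: step from 0 to 1 at the base ICER
  specs0 <- default_psa_specs()
  specs0$dispersion <- 0
  s0 <- psa_run(n = 3, seed = 1, specs = specs0, model = m)
  base_icer <- m(list())$icer
  step <- ceac(s0, c(base_icer - 1, base_icer + 1))
  expect_equal(step$prob_cost_effective, c(0, 1))
})
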