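# Base-case configuration: ripretinib vs placebo, fourth-line advanced GIST.
# Costs in 2021 USD; time in months; Weibull curves in AFT form.
seed: 1
output_dir: results
model:
  cycle_length: 1          # months (30.4375 days)
  horizon: 240             # lifetime: cohort survival << 0.1% by then
  annual_discount: 0.03
  half_cycle: true
  utility_pf: 0.767
  utility_pd: 0.647
  structure: partitioned
arms:
  ripretinib:
    drug_cost_monthly: 32000
    bsc_cost_monthly: 3382.47
    ae_onetime_cost: 421.2
    ct_cost_per_cycle: 1365.39
    crossover_fraction: 0
    crossover_drug_cost: 0
  placebo:
    drug_cost_monthly: 0
    bsc_cost_monthly: 3382.47
    ae_onetime_cost: 421.2
    ct_cost_per_cycle: 1365.39
    crossover_fraction: 0.659090909090909   # 29 of 44 crossed over
    crossover_drug_cost: 32000
curves:
  ripretinib:
    os:  {type: weibull, intercept: 2.782163, log_scale: -0.4285523}
    pfs: {type: weibull, intercept: 2.074947, log_scale: -0.09223515}
  placebo:
    os:  {type: weibull, intercept: 2.250612, log_scale: 0.00098579}
    pfs: {type: weibull, intercept: 0.830945, log_scale: -0.6655104}
sensitivity:
  one_way_range: 0.1
  psa:
    draws: 10000
    cv_cost: 0.2
    cv_utility: 0.1
    se_survival: 0.1
  price_grid: [3200, 6400, 9600, 12800, 16000, 19200, 22400, 25600, 28800, 32000]
  wtp_grid: {from: 0, to: 300000, by: 5000}
  threshold_wtp: 150000
simulate:
  n_per_arm: {ripretinib: 85, placebo: 44}
  admin_censor_time: 30
  accrual: 0
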