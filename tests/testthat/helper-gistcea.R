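# closed-form (discount-free) Weibull mean: lambda^(-1/gamma) * Gamma(1 + 1/gamma)
weibull_mean_closed_form <- function(shape, rate) {
  rate^(-1 / shape) * gamma(1 + 1 / shape)
}

# published Weibull parameter table, used across tests
table1_weibulls <- function() {
  tibble::tribble(
    ~arm,         ~endpoint, ~intercept,  ~log_scale,  ~shape,      ~rate,
    "ripretinib", "os",      2.782163,    -0.4285523,  1.535033646, 0.013971806,
    "placebo",    "os",      2.250612,    0.00098579,  0.999014696, 0.105568583,
    "ripretinib", "pfs",     2.074947,    -0.09223515, 1.096622663, 0.102752314,
    "placebo",    "pfs",     0.830945,    -0.6655104,  1.945483243, 0.19857477
  )
}

rel_err <- function(x, ref) abs(x - ref) / abs(ref)
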