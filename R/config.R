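# schema helpers ---------------------------------------------------------

check_known_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown)) {
    stop(sprintf("unknown key(s) in %s: %s", where,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
}

need_number <- function(x, field, lo = -Inf, hi = Inf) {
  if (is.null(x) || !is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    stop(sprintf("field '%s' must be a single finite number", field),
         call. = FALSE)
  }
  if (x < lo || x > hi) {
    stop(sprintf("field '%s' = %g outside [%g, %g]", field, x, lo, hi),
         call. = FALSE)
  }
  x
}

parse_curve <- function(spec, where, base_dir) {
  check_known_keys(spec, c("type", "intercept", "log_scale", "shape", "rate",
                           "km_file", "junction"), where)
  type <- spec$type %||% "weibull"
  make_weibull <- function(sp, wh) {
    if (!is.null(sp$intercept) || !is.null(sp$log_scale)) {
      weibull_curve_aft(need_number(sp$intercept, paste0(wh, ".intercept")),
                        need_number(sp$log_scale, paste0(wh, ".log_scale")))
    } else {
      weibull_curve(need_number(sp$shape, paste0(wh, ".shape"), lo = 1e-12),
                    need_number(sp$rate, paste0(wh, ".rate"), lo = 1e-12))
    }
  }
  if (type == "weibull") {
    make_weibull(spec, where)
  } else if (type == "hybrid") {
    km_path <- file.path(base_dir, spec$km_file %||%
                           stop(sprintf("field '%s.km_file' required", where),
                                call. = FALSE))
    if (!file.exists(km_path)) {
      stop(sprintf("KM file '%s' does not exist", km_path), call. = FALSE)
    }
    km <- utils::read.csv(km_path)
    hybrid_curve(km, make_weibull(spec, where),
                 need_number(spec$junction, paste0(where, ".junction"), lo = 0))
  } else {
    stop(sprintf("field '%s.type' must be 'weibull' or 'hybrid'", where),
         call. = FALSE)
  }
}

#' Load and validate an analysis configuration
#'
#' Reads a YAML configuration describing the full analysis — arms, model
#' settings, survival curves, sensitivity settings, seed — validates it
#' (unknown keys are rejected, domains are checked with field-level
#' messages), applies defaults, and assembles the model inputs. The shipped
#' default configuration (`system.file("extdata", "default_config.yaml",
#' package = "gistcea")`) reproduces the published base case.
#'
#' @param path Path to a YAML configuration file.
#' @return A list of class `analysis_config` with elements `inputs` (as
#'   from [gist_inputs()]), `sensitivity`, `simulate`, `seed`,
#'   `output_dir`, and `raw` (the parsed YAML).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw) || !is.list(raw) || length(raw) == 0) {
    stop("config is empty or not a YAML mapping", call. = FALSE)
  }
  base_dir <- dirname(normalizePath(path))
  check_known_keys(raw, c("seed", "output_dir", "model", "arms", "curves",
                          "sensitivity", "simulate"), "top level")

  m <- raw$model %||% list()
  check_known_keys(m, c("cycle_length", "horizon", "annual_discount",
                        "half_cycle", "utility_pf", "utility_pd", "structure"),
                   "model")
  config <- model_config(
    cycle_length = need_number(m$cycle_length %||% 1, "model.cycle_length", lo = 1e-6),
    horizon = need_number(m$horizon %||% 240, "model.horizon", lo = 1e-6),
    annual_discount = need_number(m$annual_discount %||% 0.03,
                                  "model.annual_discount", lo = 0, hi = 1 - 1e-9),
    half_cycle = isTRUE(m$half_cycle %||% TRUE),
    utility_pf = need_number(m$utility_pf %||% 0.767, "model.utility_pf", 0, 1),
    utility_pd = need_number(m$utility_pd %||% 0.647, "model.utility_pd", 0, 1),
    structure = m$structure %||% "partitioned"
  )

  default_arms <- gist_inputs()$arms
  arms <- list()
  arm_fields <- c("drug_cost_monthly", "bsc_cost_monthly", "ae_onetime_cost",
                  "ct_cost_per_cycle", "crossover_fraction",
                  "crossover_drug_cost", "include_ae")
  arm_names <- names(raw$arms %||% default_arms)
  if (length(arm_names) != 2) stop("exactly two arms required", call. = FALSE)
  for (a in arm_names) {
    spec <- (raw$arms %||% list())[[a]] %||% list()
    check_known_keys(spec, arm_fields, paste0("arms.", a))
    dft <- default_arms[[a]] %||% default_arms$placebo
    arms[[a]] <- arm_spec(
      name = a,
      drug_cost_monthly = need_number(spec$drug_cost_monthly %||% dft$drug_cost_monthly,
                                      paste0("arms.", a, ".drug_cost_monthly"), lo = 0),
      bsc_cost_monthly = need_number(spec$bsc_cost_monthly %||% dft$bsc_cost_monthly,
                                     paste0("arms.", a, ".bsc_cost_monthly"), lo = 0),
      ae_onetime_cost = need_number(spec$ae_onetime_cost %||% dft$ae_onetime_cost,
                                    paste0("arms.", a, ".ae_onetime_cost"), lo = 0),
      ct_cost_per_cycle = need_number(spec$ct_cost_per_cycle %||% dft$ct_cost_per_cycle,
                                      paste0("arms.", a, ".ct_cost_per_cycle"), lo = 0),
      crossover_fraction = need_number(spec$crossover_fraction %||% dft$crossover_fraction,
                                       paste0("arms.", a, ".crossover_fraction"), 0, 1),
      crossover_drug_cost = need_number(spec$crossover_drug_cost %||% dft$crossover_drug_cost,
                                        paste0("arms.", a, ".crossover_drug_cost"), lo = 0),
      include_ae = isTRUE(spec$include_ae %||% dft$include_ae)
    )
  }

  default_curves <- gist_inputs()$curves
  curves <- list()
  for (a in arm_names) {
    cs <- (raw$curves %||% list())[[a]]
    check_known_keys(cs %||% list(), c("os", "pfs"), paste0("curves.", a))
    curves[[a]] <- list(
      os = if (is.null(cs$os)) default_curves[[a]]$os else
        parse_curve(cs$os, paste0("curves.", a, ".os"), base_dir),
      pfs = if (is.null(cs$pfs)) default_curves[[a]]$pfs else
        parse_curve(cs$pfs, paste0("curves.", a, ".pfs"), base_dir)
    )
  }

  aft_or_na <- function(cv, f) cv[[f]] %||% NA_real_
  survival_params <- tibble::tibble(
    arm = rep(arm_names, each = 2),
    endpoint = rep(c("os", "pfs"), 2),
    intercept = unlist(lapply(arm_names, function(a)
      c(aft_or_na(curves[[a]]$os, "intercept"), aft_or_na(curves[[a]]$pfs, "intercept")))),
    log_scale = unlist(lapply(arm_names, function(a)
      c(aft_or_na(curves[[a]]$os, "log_scale"), aft_or_na(curves[[a]]$pfs, "log_scale"))))
  )

  s <- raw$sensitivity %||% list()
  check_known_keys(s, c("one_way_range", "psa", "price_grid", "wtp_grid",
                        "threshold_wtp"), "sensitivity")
  psa <- s$psa %||% list()
  check_known_keys(psa, c("draws", "cv_cost", "cv_utility", "se_survival"),
                   "sensitivity.psa")
  wg <- s$wtp_grid %||% list()
  check_known_keys(wg, c("from", "to", "by"), "sensitivity.wtp_grid")
  sensitivity <- list(
    one_way_range = need_number(s$one_way_range %||% 0.1, "sensitivity.one_way_range", 0, 1),
    psa_n = need_number(psa$draws %||% 10000, "sensitivity.psa.draws", lo = 1),
    cv_cost = need_number(psa$cv_cost %||% 0.2, "sensitivity.psa.cv_cost", lo = 0),
    cv_utility = need_number(psa$cv_utility %||% 0.1, "sensitivity.psa.cv_utility", lo = 0),
    se_survival = need_number(psa$se_survival %||% 0.1, "sensitivity.psa.se_survival", lo = 0),
    price_grid = as.numeric(s$price_grid %||% seq(3200, 32000, by = 3200)),
    wtp_grid = seq(need_number(wg$from %||% 0, "sensitivity.wtp_grid.from", lo = 0),
                   need_number(wg$to %||% 300000, "sensitivity.wtp_grid.to", lo = 0),
                   by = need_number(wg$by %||% 5000, "sensitivity.wtp_grid.by", lo = 1)),
    threshold_wtp = need_number(s$threshold_wtp %||% 150000,
                                "sensitivity.threshold_wtp", lo = 0)
  )
  if (any(sensitivity$price_grid < 0)) {
    stop("field 'sensitivity.price_grid' must be nonnegative", call. = FALSE)
  }

  sim <- raw$simulate %||% list()
  check_known_keys(sim, c("n_per_arm", "admin_censor_time", "accrual"), "simulate")
  n_per_arm <- sim$n_per_arm %||% list(ripretinib = 85, placebo = 44)
  simulate <- list(
    n_per_arm = lapply(n_per_arm, need_number, field = "simulate.n_per_arm", lo = 1),
    admin_censor_time = need_number(sim$admin_censor_time %||% 30,
                                    "simulate.admin_censor_time", lo = 0),
    accrual = need_number(sim$accrual %||% 0, "simulate.accrual", lo = 0)
  )

  structure(list(
    inputs = list(curves = curves, arms = arms, config = config,
                  survival_params = survival_params),
    sensitivity = sensitivity,
    simulate = simulate,
    seed = as.integer(need_number(raw$seed %||% 1, "seed")),
    output_dir = raw$output_dir %||% "results",
    raw = raw
  ), class = "analysis_config")
}
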