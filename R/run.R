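# tiny deterministic content hash for run logs (FNV-1a over the YAML text)
config_hash <- function(raw) {
  txt <- yaml::as.yaml(raw)
  h <- 2166136261
  for (b in utf8ToInt(txt)) h <- ((bitwXor(as.integer(h %% 2^31), b)) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Serialise a comparison result
#'
#' Writes a `ce_result` to JSON at full precision; [read_ce_result()]
#' round-trips it back to an identical object.
#'
#' @param x A [ce_compare()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ce_result <- function(x, path) {
  stopifnot(inherits(x, "ce_result"))
  jsonlite::write_json(
    list(arms = x$arms, intervention = x$intervention,
         comparator = x$comparator,
         incremental_cost = x$incremental_cost,
         incremental_qaly = x$incremental_qaly,
         icer = x$icer, status = x$status),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_ce_result
#' @export
read_ce_result <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(arms = tibble::as_tibble(j$arms),
                 intervention = j$intervention, comparator = j$comparator,
                 incremental_cost = j$incremental_cost,
                 incremental_qaly = j$incremental_qaly,
                 icer = j$icer %||% NA_real_, status = j$status),
            class = "ce_result")
}

#' Run an analysis stage and write its outputs
#'
#' Executes one stage of the analysis described by a configuration and
#' writes its tabular outputs plus a log (seed, configuration hash, package
#' version) under the output directory:
#'
#' * `run` — base-case comparison: `results.csv` (per-arm per-state costs
#'   and QALYs with incrementals and the ICER, mirroring the published
#'   layout) and `results.json` (full precision).
#' * `dsa` — `tornado.csv` and `price_sweep.csv`.
#' * `psa` — `psa_samples.csv` and `ceac.csv`.
#' * `threshold` — `threshold.json`.
#' * `simulate` — `ipd.csv` (pseudo individual-patient data per arm and
#'   endpoint) and one KM table per arm/endpoint.
#' * `fit` — Weibull AFT fits of the simulated data, `fits.csv`.
#'
#' @param config An [load_config()] result (or the shipped default when
#'   omitted).
#' @param command Stage to run.
#' @param out_dir Output directory, created if needed; defaults to the
#'   configuration's `output_dir`.
#' @param n Override for the number of PSA draws.
#' @param wtp Override for the threshold willingness-to-pay.
#' @param seed Override for the configuration seed.
#' @return A list of the objects written (invisibly for file side-effects).
#' @export
run_analysis <- function(config = load_config(system.file("extdata", "default_config.yaml",
                                                          package = "gistcea")),
                         command = c("run", "dsa", "psa", "threshold",
                                     "simulate", "fit"),
                         out_dir = NULL, n = NULL, wtp = NULL, seed = NULL) {
  command <- match.arg(command)
  stopifnot(inherits(config, "analysis_config"))
  out_dir <- out_dir %||% config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed %||% config$seed)
  inputs <- config$inputs

  log_lines <- c(
    sprintf("stage: %s", command),
    sprintf("seed: %d", seed),
    sprintf("config_hash: %s", config_hash(config$raw)),
    sprintf("gistcea_version: %s", as.character(utils::packageVersion("gistcea"))),
    sprintf("time: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  )

  out <- switch(command,
    run = {
      res <- base_case(inputs)
      utils::write.csv(dplyr::bind_rows(
        tidy(res),
        tibble::tibble(arm = "incremental",
                       cost_total = res$incremental_cost,
                       qaly_total = res$incremental_qaly),
        tibble::tibble(arm = "icer", cost_total = res$icer)
      ), file.path(out_dir, "results.csv"), row.names = FALSE, na = "")
      write_ce_result(res, file.path(out_dir, "results.json"))
      list(result = res)
    },
    dsa = {
      fixture <- calibrate_fixture(inputs = inputs)
      model <- ce_model(inputs, fixture = fixture)
      tor <- one_way_sweep(default_dsa_params(inputs, config$sensitivity$one_way_range),
                           model)
      sw <- price_sweep(config$sensitivity$price_grid, inputs, fixture)
      utils::write.csv(tor, file.path(out_dir, "tornado.csv"), row.names = FALSE, na = "")
      utils::write.csv(sw, file.path(out_dir, "price_sweep.csv"), row.names = FALSE, na = "")
      list(tornado = tor, price_sweep = sw)
    },
    psa = {
      n_draws <- as.integer(n %||% config$sensitivity$psa_n)
      specs <- default_psa_specs(inputs,
                                 cv_cost = config$sensitivity$cv_cost,
                                 cv_utility = config$sensitivity$cv_utility,
                                 se_survival = config$sensitivity$se_survival)
      samples <- psa_run(n = n_draws, seed = seed, specs = specs,
                         model = ce_model(inputs))
      curve <- ceac(samples, config$sensitivity$wtp_grid)
      utils::write.csv(samples, file.path(out_dir, "psa_samples.csv"),
                       row.names = FALSE, na = "")
      utils::write.csv(curve, file.path(out_dir, "ceac.csv"), row.names = FALSE)
      log_lines <- c(log_lines, sprintf("psa_n: %d", n_draws))
      list(samples = samples, ceac = curve)
    },
    threshold = {
      w <- wtp %||% config$sensitivity$threshold_wtp
      p <- threshold_price(w, inputs)
      jsonlite::write_json(list(wtp = w, price_per_month = p),
                           file.path(out_dir, "threshold.json"),
                           auto_unbox = TRUE, digits = NA)
      list(wtp = w, price_per_month = p)
    },
    simulate = {
      ipd <- purrr::imap_dfr(inputs$curves, function(eps, a) {
        purrr::imap_dfr(eps, function(cv, e) {
          if (!inherits(cv, "weibull_curve")) {
            stop("simulate requires Weibull curves for arm ", a, call. = FALSE)
          }
          dplyr::mutate(
            simulate_ipd(config$simulate$n_per_arm[[a]] %||% 44, cv,
                         admin_censor_time = config$simulate$admin_censor_time,
                         seed = param_seed(seed, paste(a, e)),
                         arm = a, accrual = config$simulate$accrual),
            endpoint = e)
        })
      })
      utils::write.csv(
        dplyr::transmute(ipd, time_months = .data$time,
                         event = as.integer(.data$event),
                         arm = .data$arm, endpoint = .data$endpoint),
        file.path(out_dir, "ipd.csv"), row.names = FALSE)
      for (a in unique(ipd$arm)) {
        for (e in unique(ipd$endpoint)) {
          km <- km_estimate(ipd[ipd$arm == a & ipd$endpoint == e, ])
          utils::write.csv(km, file.path(out_dir, sprintf("km_%s_%s.csv", a, e)),
                           row.names = FALSE)
        }
      }
      list(ipd = ipd)
    },
    fit = {
      ipd_path <- file.path(out_dir, "ipd.csv")
      if (!file.exists(ipd_path)) {
        run_analysis(config, "simulate", out_dir = out_dir, seed = seed)
      }
      ipd <- utils::read.csv(ipd_path)
      fits <- purrr::map_dfr(split(ipd, paste(ipd$arm, ipd$endpoint, sep = ".")),
        function(d) {
          f <- fit_weibull_aft(tibble::tibble(time = d$time_months,
                                              event = d$event == 1))
          tibble::tibble(arm = d$arm[1], endpoint = d$endpoint[1],
                         intercept = f$intercept, log_scale = f$log_scale,
                         se_intercept = f$se_intercept,
                         se_log_scale = f$se_log_scale,
                         shape = f$shape, rate = f$rate,
                         n = f$n, n_events = f$n_events)
        })
      utils::write.csv(fits, file.path(out_dir, "fits.csv"), row.names = FALSE)
      list(fits = fits)
    }
  )

  writeLines(log_lines, file.path(out_dir, paste0(command, ".log")))
  message(paste(log_lines, collapse = "; "))
  invisible(out)
}
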