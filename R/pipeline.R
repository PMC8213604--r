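#' Full-pipeline configuration
#'
#' Bundles every stage's parameters: input (CSV path or synthetic config),
#' decomposition (window, cutoff, filter order), AR settings, the
#' trajectory-method grid, dynamics settings and UTCI scenarios.  The
#' config is fully serializable; [run_pipeline()] writes a snapshot next to
#' its outputs.
#'
#' @param input CSV path (canonical dialect) or a [synthetic_config()].
#' @param out_dir Output directory for stage artifacts (`NULL`: no files).
#' @param window_months,cutoff,filter_order Decomposition parameters.
#' @param ar_max_lag,ar_cap Correlogram depth and order-selection cap.
#' @param tm_grid List of [tm_config()]s (`NULL`: [tm_search()] default).
#' @param dynamics_steps,dynamics_dt,transient_frac Long-run settings.
#' @param scenarios Numeric wind speeds (m/s) for the UTCI scenarios.
#' @param rh_proxy,latitude,irc Bioclimate conventions (see [utci_series()]).
#' @param seed Master seed.
#' @param log_level `"info"` or `"quiet"`.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(input = synthetic_config(), out_dir = NULL,
                            window_months = 120L, cutoff = 0.0038,
                            filter_order = 4L, ar_max_lag = 20L,
                            ar_cap = 12L, tm_grid = NULL,
                            dynamics_steps = 7000L, dynamics_dt = 1,
                            transient_frac = 0.3,
                            scenarios = c(0.5, 1, 5), rh_proxy = 0.7,
                            latitude = 51.1, irc = 1.15, seed = 1L,
                            log_level = c("info", "quiet")) {
  structure(list(input = input, out_dir = out_dir,
                 window_months = window_months, cutoff = cutoff,
                 filter_order = filter_order, ar_max_lag = ar_max_lag,
                 ar_cap = ar_cap, tm_grid = tm_grid,
                 dynamics_steps = dynamics_steps, dynamics_dt = dynamics_dt,
                 transient_frac = transient_frac, scenarios = scenarios,
                 rh_proxy = rh_proxy, latitude = latitude, irc = irc,
                 seed = as.integer(seed),
                 log_level = match.arg(log_level)),
            class = "pipeline_config")
}

pipeline_log <- function(config, ...) {
  if (identical(config$log_level, "quiet")) return(invisible())
  message(format(Sys.time(), "%H:%M:%S "), ...)
}

config_snapshot <- function(config) {
  snap <- unclass(config)
  if (inherits(snap$input, "synthetic_config")) {
    sc <- unclass(snap$input)
    sc$trend_model <- if (identical(sc$trend_model, "benchmark"))
      "benchmark" else "custom poly_ode_model"
    sc$ar_models <- lapply(sc$ar_models, unclass)
    snap$input <- sc
  }
  snap$tm_grid <- lapply(snap$tm_grid, unclass)
  snap
}

#' Run the full analysis pipeline
#'
#' Stages, in order: load or synthesize the dataset; decompose each
#' variable into slow/seasonal/residual; select and fit an AR model per
#' residual with a whiteness check; reconstruct the slow components as a
#' cubic ODE system (trajectory-method search); analyse its equilibria and
#' long-term behaviour (only when a stable candidate exists -- the search
#' failing to find one is reported, not fatal, matching how rarely the
#' reconstruction succeeds); compute UTCI series per wind scenario from
#' the full data and from the slow components, data-based vs model-based.
#' Each stage's artifacts are written to `out_dir` (CSV/JSON) when set.
#'
#' @param config A [pipeline_config()].
#' @return A `run_report` list with per-stage summaries.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  od <- config$out_dir
  if (!is.null(od) && !dir.exists(od)) dir.create(od, recursive = TRUE)
  art <- function(name) if (is.null(od)) NULL else file.path(od, name)
  if (!is.null(od))
    jsonlite::write_json(config_snapshot(config), art("config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)

  # -- stage 1: data
  if (inherits(config$input, "synthetic_config")) {
    cfgin <- config$input
    cfgin$seed <- config$seed
    pipeline_log(config, "generating synthetic dataset (seed ", config$seed, ")")
    dataset <- generate_dataset(cfgin)
  } else {
    pipeline_log(config, "reading ", config$input)
    dataset <- read_monthly_csv(config$input)
  }
  n <- length(dataset$temperature$values)
  if (n < 2L * config$window_months)
    stop("input has ", n, " months; need at least ", 2L * config$window_months)
  for (cfg in config$tm_grid) tm_check_feasible(n - config$window_months, cfg)
  if (!is.null(od)) write_monthly_csv(dataset, art("dataset.csv"))

  vars <- c("sunshine", "precipitation", "temperature")

  # -- stage 2: decomposition
  pipeline_log(config, "decomposing ", n, " months per variable")
  dec <- lapply(vars, function(v)
    decompose_series(dataset[[v]], config$window_months, config$cutoff,
                     config$filter_order))
  names(dec) <- vars
  if (!is.null(od))
    for (v in vars) write_decomposition_json(dec[[v]],
                                             art(paste0("decomposition_", v, ".json")))

  # -- stage 3: AR models of the standardized residuals
  ar_fits <- list()
  for (v in vars) {
    resid <- dec[[v]]$residual_standardized
    if (dec[[v]]$degenerate) {
      ar_fits[[v]] <- list(order = NA_integer_, model = NULL, white = NULL)
      next
    }
    cg <- correlogram(resid, max_lag = config$ar_max_lag)
    p <- select_order(cg, cap = config$ar_cap)
    m <- fit_ar(resid, p)
    ar_fits[[v]] <- list(order = p, model = m,
                         white = residual_whiteness(m, resid,
                                                    max_lag = config$ar_max_lag))
    if (!is.null(od)) write_ar_json(m, art(paste0("ar_", v, ".json")))
  }
  pipeline_log(config, "AR orders: ",
               paste(vars, vapply(ar_fits, function(f) f$order, 1L),
                     sep = "=", collapse = ", "))

  # -- stage 4: trajectory-method reconstruction of the slow system
  slow <- lapply(dec, function(d) d$slow)
  pipeline_log(config, "trajectory-method search over the slow components")
  search <- tm_search(slow, config_grid = config$tm_grid, seed = config$seed)
  if (!is.null(od))
    utils::write.csv(search$log, art("tm_trials.csv"), row.names = FALSE)
  best <- if (length(search$candidates) > 0L) search$candidates[[1]] else NULL
  if (!is.null(best) && !is.null(od))
    write_model_json(best$model, art("ode_model.json"))

  # -- stage 5: dynamics of the fitted system
  dyn <- NULL
  if (!is.null(best)) {
    X <- slow_data_matrix(slow)
    width <- apply(X, 2, function(v) max(v) - min(v))
    box <- list(lo = apply(X, 2, min) - pmax(width, 1e-8),
                hi = apply(X, 2, max) + pmax(width, 1e-8))
    eq <- equilibrium_analysis(best$model, box)
    run <- long_term(best$model, X[1, ], steps = config$dynamics_steps,
                     dt = config$dynamics_dt,
                     transient_frac = config$transient_frac)
    per <- estimate_period(run)
    dyn <- list(equilibria = eq, years = run$years,
                period_months = per$period_months, run_completed = run$completed)
    if (!is.null(od) && length(eq) > 0)
      write_equilibria_csv(eq, art("equilibria.csv"))
    pipeline_log(config, "dynamics: ", length(eq), " equilibria, ",
                 run$years, " simulated years, period ",
                 signif(per$period_months, 5), " months")
  } else {
    pipeline_log(config, "no stable ODE candidate found; dynamics skipped")
  }

  # -- stage 6: UTCI scenarios
  utci_stage <- list()
  slow_ds <- list(sunshine = slow$sunshine, precipitation = slow$precipitation,
                  temperature = slow$temperature)
  for (w in config$scenarios) {
    sc <- utci_scenario(w)
    u_data <- utci_series(dataset, sc, config$rh_proxy, config$latitude,
                          config$irc)
    u_slow <- utci_series(slow_ds, sc, config$rh_proxy, config$latitude,
                          config$irc)
    entry <- list(wind = sc$wind_speed,
                  mean_utci = mean(u_data$values, na.rm = TRUE),
                  mean_utci_slow = mean(u_slow$values, na.rm = TRUE),
                  n_invalid = sum(!attr(u_data, "valid")))
    if (!is.null(best)) {
      # slow components integrated from the fitted model, same span
      Xs <- slow_data_matrix(slow)
      tr <- rk4_trajectory(best$model, Xs[1, ], n_steps = nrow(Xs) - 1L,
                           dt = 1)
      if (tr$completed) {
        mod_ds <- slow_ds
        for (i in seq_along(vars))
          mod_ds[[vars[i]]]$values <- tr$states[, i]
        u_mod <- utci_series(mod_ds, sc, config$rh_proxy, config$latitude,
                             config$irc)
        entry$mse_slow_vs_model <- compare_series(u_slow, u_mod)$mse
      }
    }
    utci_stage[[sc$label]] <- entry
    if (!is.null(od)) {
      lbl <- gsub("[^0-9.]", "", sc$label)
      df <- data.frame(year = series_years(u_data),
                       month = series_months(u_data),
                       utci = u_data$values, valid = attr(u_data, "valid"))
      utils::write.csv(df, art(paste0("utci_", lbl, "ms.csv")),
                       row.names = FALSE)
    }
  }

  report <- structure(list(
    seed = config$seed, n_months = n,
    decomposition = lapply(dec, function(d)
      list(slow_mean = mean(d$slow$values), seasonal = d$seasonal,
           residual_sd = d$residual_sd, degenerate = d$degenerate)),
    ar = lapply(ar_fits, function(f)
      list(order = f$order,
           phi = if (!is.null(f$model)) f$model$phi else NULL,
           sigma2 = if (!is.null(f$model)) f$model$sigma2 else NULL,
           whiteness_pass = if (!is.null(f$white)) f$white$pass else NA)),
    trajectory = list(n_trials = nrow(search$log),
                      n_stable = sum(search$log$stable, na.rm = TRUE),
                      best_Q = if (!is.null(best)) best$report$total else NA_real_,
                      stable_found = !is.null(best)),
    dynamics = dyn,
    utci = utci_stage,
    versions = list(package = as.character(utils::packageVersion("bioclimdyn")),
                    r = R.version.string)),
    class = "run_report")
  if (!is.null(od))
    jsonlite::write_json(report_to_json(report), art("report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report
}

report_to_json <- function(report) {
  r <- unclass(report)
  if (!is.null(r$dynamics) && length(r$dynamics$equilibria) > 0)
    r$dynamics$equilibria <- lapply(r$dynamics$equilibria, function(e)
      list(state = unname(e$state),
           eigenvalues_re = Re(e$eigenvalues),
           eigenvalues_im = Im(e$eigenvalues),
           characteristic = e$classification$label,
           hyperbolic = e$classification$hyperbolic))
  r
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat("  months:", x$n_months, " seed:", x$seed, "\n")
  cat("  AR orders:", paste(names(x$ar),
                            vapply(x$ar, function(a) a$order, 1L),
                            sep = "=", collapse = ", "), "\n")
  cat(sprintf("  ODE search: %d trials, %d stable, best Q %s\n",
              x$trajectory$n_trials, x$trajectory$n_stable,
              if (is.na(x$trajectory$best_Q)) "-" else
                signif(x$trajectory$best_Q, 5)))
  if (!is.null(x$dynamics))
    cat(sprintf("  dynamics: %d equilibria, %d years, period %s months\n",
                length(x$dynamics$equilibria), x$dynamics$years,
                if (is.na(x$dynamics$period_months)) "undefined" else
                  signif(x$dynamics$period_months, 5)))
  for (nm in names(x$utci))
    cat(sprintf("  UTCI %s: mean %.2f degC (slow %.2f)\n", nm,
                x$utci[[nm]]$mean_utci, x$utci[[nm]]$mean_utci_slow))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Command-line interface

cli_usage <- "usage: bioclimdyn <command> [--seed N] [--out DIR] [--in FILE]
                  [--wind W] [--log-level info|quiet]
commands:
  simulate    generate a synthetic dataset CSV (--out directory)
  decompose   decompose a dataset CSV (--in) into components (--out)
  fit-ar      fit AR models to the decomposed residuals of --in
  fit-ode     trajectory-method search on the slow components of --in
  analyze     equilibria + long-term run of a fitted model (--in model JSON,
              --data dataset CSV)
  utci        UTCI series for --in dataset at --wind m/s (--out)
  run-all     full pipeline on --in (or synthetic when absent)"

cli_parse <- function(args) {
  out <- list(command = NULL, opts = list())
  if (length(args) == 0L) return(out)
  out$command <- args[[1]]
  args <- args[-1]
  i <- 1L
  while (i <= length(args)) {
    key <- args[[i]]
    if (!startsWith(key, "--")) stop("unexpected argument: ", key)
    if (i + 1L > length(args)) stop("missing value for ", key)
    out$opts[[substring(key, 3)]] <- args[[i + 1L]]
    i <- i + 2L
  }
  out
}

#' Command-line entry point
#'
#' Subcommands `simulate`, `decompose`, `fit-ar`, `fit-ode`, `analyze`,
#' `utci` and `run-all`; each accepts `--seed`, `--out`, `--in` and
#' `--log-level`.  Returns (and, under `Rscript`, exits with) status 0 on
#' success and 1 with a one-line cause on failure.
#'
#' @param args Character vector of CLI arguments (default:
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit status, invisibly.
#' @export
bioclim_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    p <- cli_parse(args)
    if (is.null(p$command) || p$command %in% c("help", "--help")) {
      cat(cli_usage, "\n")
      return(invisible(0L))
    }
    o <- p$opts
    seed <- as.integer(o$seed %||% 1L)
    lvl <- o[["log-level"]] %||% "info"
    need_out <- function() {
      if (is.null(o$out)) stop("--out is required for ", p$command)
      if (!dir.exists(o$out)) dir.create(o$out, recursive = TRUE)
      o$out
    }
    switch(p$command,
      simulate = {
        od <- need_out()
        cfg <- synthetic_config(seed = seed)
        ds <- generate_dataset(cfg)
        write_monthly_csv(ds, file.path(od, "dataset.csv"),
                          wind_ms = cfg$wind_speed)
        message("wrote ", file.path(od, "dataset.csv"))
      },
      decompose = {
        od <- need_out()
        if (is.null(o[["in"]])) stop("--in dataset CSV is required")
        ds <- read_monthly_csv(o[["in"]])
        for (v in c("sunshine", "precipitation", "temperature"))
          write_decomposition_json(decompose_series(ds[[v]]),
                                   file.path(od, paste0("decomposition_", v, ".json")))
        message("wrote decompositions to ", od)
      },
      `fit-ar` = {
        od <- need_out()
        if (is.null(o[["in"]])) stop("--in dataset CSV is required")
        ds <- read_monthly_csv(o[["in"]])
        for (v in c("sunshine", "precipitation", "temperature")) {
          d <- decompose_series(ds[[v]])
          cg <- correlogram(d$residual_standardized)
          m <- fit_ar(d$residual_standardized, select_order(cg))
          write_ar_json(m, file.path(od, paste0("ar_", v, ".json")))
        }
        message("wrote AR models to ", od)
      },
      `fit-ode` = {
        od <- need_out()
        if (is.null(o[["in"]])) stop("--in dataset CSV is required")
        ds <- read_monthly_csv(o[["in"]])
        slow <- lapply(ds[c("sunshine", "precipitation", "temperature")],
                       extract_slow)
        sr <- tm_search(slow, seed = seed)
        utils::write.csv(sr$log, file.path(od, "tm_trials.csv"),
                         row.names = FALSE)
        if (length(sr$candidates) == 0L)
          stop("no stable model found (trial log written to ", od, ")")
        write_model_json(sr$candidates[[1]]$model,
                         file.path(od, "ode_model.json"))
        message("wrote best model to ", od)
      },
      analyze = {
        od <- need_out()
        if (is.null(o[["in"]])) stop("--in model JSON is required")
        if (is.null(o$data)) stop("--data dataset CSV is required")
        model <- read_model_json(o[["in"]])
        ds <- read_monthly_csv(o$data)
        X <- slow_data_matrix(lapply(
          ds[c("sunshine", "precipitation", "temperature")], extract_slow))
        width <- apply(X, 2, function(v) max(v) - min(v))
        box <- list(lo = apply(X, 2, min) - width, hi = apply(X, 2, max) + width)
        eq <- equilibrium_analysis(model, box)
        if (length(eq) > 0)
          write_equilibria_csv(eq, file.path(od, "equilibria.csv"))
        run <- long_term(model, X[1, ])
        per <- estimate_period(run)
        jsonlite::write_json(list(n_equilibria = length(eq),
                                  years = run$years,
                                  period_months = per$period_months),
                             file.path(od, "dynamics.json"),
                             auto_unbox = TRUE, digits = NA)
        message("wrote dynamics to ", od)
      },
      utci = {
        od <- need_out()
        if (is.null(o[["in"]])) stop("--in dataset CSV is required")
        ds <- read_monthly_csv(o[["in"]])
        w <- as.numeric(o$wind %||% 0.5)
        u <- utci_series(ds, w)
        df <- data.frame(year = series_years(u), month = series_months(u),
                         utci = u$values, valid = attr(u, "valid"),
                         scenario = attr(u, "scenario"))
        f <- file.path(od, sprintf("utci_%gms.csv", w))
        utils::write.csv(df, f, row.names = FALSE)
        message("wrote ", f)
      },
      `run-all` = {
        od <- need_out()
        input <- if (is.null(o[["in"]])) synthetic_config(seed = seed)
                 else o[["in"]]
        cfg <- pipeline_config(input = input, out_dir = od, seed = seed,
                               log_level = lvl)
        print(run_pipeline(cfg))
      },
      stop("unknown command: ", p$command, "\n", cli_usage)
    )
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
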