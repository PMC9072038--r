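#' Run one pipeline command
#'
#' Programmatic core of the command-line surface. Supported commands:
#' \describe{
#'   \item{simulate}{draw a panel from a scenario; writes `panel.csv`,
#'     `proximity.csv`, `truth.csv` and a `scenario.json` echo.}
#'   \item{fit}{REML fit; writes `fit_<model>.json` (beta, tau, loglik,
#'     information criteria, convergence).}
#'   \item{predict}{fit + EBLUP + MSE (analytic for FH, bootstrap
#'     otherwise); writes `predictions_<model>.csv`.}
#'   \item{diagnose}{fit + diagnostic battery; writes `diagnostics.csv` and
#'     a plain-text `diagnostics.txt` summary block.}
#'   \item{compare}{fit FH/SFH/STFH to the identical stacked panel; writes
#'     an information-criteria block (`compare.csv`, `compare.txt`).}
#' }
#' Every output file carries a header with package version, seed, model tag
#' and fitted tau where applicable. Errors from inner modules propagate as
#' typed `stfh_error` conditions; nothing is written until the
#' configuration has validated.
#'
#' @param config named list: `command`, `out` (output directory), and the
#'   command's inputs — `panel`, `proximity` (paths), `model`, `seed`,
#'   `bootstrap_B`, `refit`, plus scenario fields (`m`, `T`, `p`, `tau`,
#'   `beta`, `graph`) for `simulate`. May be built from a JSON file via
#'   [read_run_config()].
#' @return (invisibly) a named list of the written file paths.
#' @export
run_pipeline <- function(config) {
  cmd <- config$command %||%
    stfh_stop("config$command is required", "stfh_config_error")
  if (!cmd %in% c("simulate", "fit", "predict", "diagnose", "compare")) {
    stfh_stop(paste0("unknown command: ", cmd), "stfh_config_error")
  }
  out_dir <- config$out %||%
    stfh_stop("config$out (output directory) is required", "stfh_config_error")
  seed <- as.integer(config$seed %||% 1L)
  for (f in c("panel", "proximity")) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]])) {
      stfh_stop(paste0(f, " file not found: ", config[[f]]), "stfh_config_error")
    }
  }
  B <- as.integer(config$bootstrap_B %||% 200L)
  if (B < 1) stfh_stop("bootstrap_B must be >= 1", "stfh_config_error")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- list()
  w <- function(name, path) written[[name]] <<- path

  if (cmd == "simulate") {
    tau <- if (is.null(config$tau)) variance_components(0.001, 0.95, 0.01, -0.6)
      else do.call(variance_components, as.list(config$tau))
    sc <- simulation_scenario(
      m = config$m %||% 83, T = config$T %||% 4, p = config$p %||% 6,
      graph = config$graph %||% list(kind = "random_planar", k = 4),
      beta = config$beta, tau = tau, seed = seed)
    sim <- simulate_panel(sc)
    w("panel", write_panel(sim$panel, file.path(out_dir, "panel.csv"), seed))
    w("proximity", write_proximity(sim$W, file.path(out_dir, "proximity.csv")))
    w("truth", write_truth(sim$truth, file.path(out_dir, "truth.csv"),
                           sim$panel$area_ids, sim$panel$time_ids, seed))
    echo <- sc[c("m", "T", "p", "graph", "beta", "D_spec", "X_spec", "seed")]
    echo$tau <- unclass(sc$tau)
    jsonlite::write_json(echo, file.path(out_dir, "scenario.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    w("scenario", file.path(out_dir, "scenario.json"))
    return(invisible(written))
  }

  if (is.null(config$panel)) {
    stfh_stop("config$panel is required", "stfh_config_error")
  }
  panel <- read_panel(config$panel)
  model <- tolower(config$model %||% "stfh")
  W <- if (!is.null(config$proximity)) {
    read_proximity(config$proximity, panel$area_ids)
  }
  if (cmd == "compare") {
    fits <- list(FH = fit_model(panel, model = "fh"),
                 SFH = fit_model(panel, W, "sfh"),
                 STFH = if (panel$T >= 2) fit_model(panel, W, "stfh"))
    fits <- Filter(Negate(is.null), fits)
    rep_ <- diagnostics_report(fits, panel, W)
    w("csv", {
      write_delim_with_header(rep_$ic, file.path(out_dir, "compare.csv"),
                              output_header(seed = seed))
      file.path(out_dir, "compare.csv")
    })
    txt <- file.path(out_dir, "compare.txt")
    sink(txt); print(rep_); sink()
    w("txt", txt)
    return(invisible(written))
  }

  fit <- fit_model(panel, W, model)
  if (cmd == "fit") {
    ic <- information_criteria(fit)
    obj <- list(model = fit$model, beta_hat = as.list(fit$beta_hat),
                tau_hat = unclass(fit$tau_hat), loglik = fit$loglik,
                n_params = fit$n_params, converged = fit$converged,
                n_iter = fit$n_iter, boundary = fit$boundary,
                minus2LL = ic$minus2LL, AIC = ic$AIC, BIC = ic$BIC,
                seed = seed, version = as.character(utils::packageVersion("stfh")),
                created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
    path <- file.path(out_dir, paste0("fit_", tolower(fit$model), ".json"))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    w("fit", path)
    return(invisible(written))
  }
  if (cmd == "predict") {
    pred <- if (fit$model == "FH") {
      mse_analytic_fh(fit, panel)
    } else {
      mse_bootstrap(fit, panel, W, B = B, seed = seed,
                    refit = !isFALSE(config$refit))
    }
    path <- file.path(out_dir, paste0("predictions_", tolower(fit$model), ".csv"))
    write_predictions(pred, path, fit = fit, seed = seed)
    w("predictions", path)
    return(invisible(written))
  }
  # diagnose
  rep_ <- diagnostics_report(stats::setNames(list(fit), fit$model), panel, W)
  df <- rep_$ic
  df$ks_statistic <- rep_$ks[[1]]$statistic
  df$ks_p <- rep_$ks[[1]]$p_value
  df$bias_slope <- rep_$bias[[1]]$slope
  df$bias_intercept <- rep_$bias[[1]]$intercept
  df$bias_r2 <- rep_$bias[[1]]$r_squared
  w("csv", {
    write_delim_with_header(df, file.path(out_dir, "diagnostics.csv"),
                            output_header(seed = seed, model = fit$model,
                                          tau = fit$tau_hat))
    file.path(out_dir, "diagnostics.csv")
  })
  txt <- file.path(out_dir, "diagnostics.txt")
  sink(txt); print(rep_); sink()
  w("txt", txt)
  invisible(written)
}

#' Read a JSON run configuration
#'
#' @param path JSON file whose fields mirror the `config` argument of
#'   [run_pipeline()].
#' @return named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stfh_stop(paste0("config file not found: ", path), "stfh_config_error")
  }
  jsonlite::read_json(path, simplifyVector = TRUE)
}
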