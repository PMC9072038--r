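#' Simulation experiment: estimator recovery and calibration
#'
#' Repeatedly simulates panels from a scenario (holding the survey-design
#' quantities W, X and D fixed at their scenario draw, redrawing the random
#' effects and sampling errors), fits the requested models, and summarizes
#' estimator performance: bias and RMSE of the covariance parameters and
#' fixed effects, empirical MSE of each EBLUP against the simulated truth
#' versus the direct estimator, mean CV%, and (optionally) the
#' bootstrap-MSE calibration ratio. `"stfh"` is fitted to the full panel;
#' `"fh"` and `"sfh"` to the final-period slice, which is how those models
#' are used when the spatio-temporal model is the headline. Deterministic
#' given `seed`.
#'
#' @param scenario a [simulation_scenario()]; its own seed fixes W, X, D.
#' @param n_reps number of replicates, >= 1.
#' @param seed root seed for the replicate draws.
#' @param models subset of `c("fh", "sfh", "stfh")`.
#' @param boot_B bootstrap size for the calibration ratio (0 = skip).
#' @param boot_reps number of leading replicates on which the bootstrap MSE
#'   is computed and averaged.
#' @param control optimizer settings passed to [fit_model()].
#' @return list of class `stfh_recovery`: `summary` (long data frame of
#'   quantities), `tau_hat` (per replicate and model), `emp_mse` (per-cell
#'   empirical MSE by model), `direct_mse`, `boot_mse` (or NULL),
#'   `n_fit_failures`.
#' @export
recovery_experiment <- function(scenario, n_reps, seed,
                                models = c("fh", "sfh", "stfh"),
                                boot_B = 0, boot_reps = 1,
                                control = fit_control()) {
  stopifnot(inherits(scenario, "simulation_scenario"), n_reps >= 1)
  models <- match.arg(models, c("fh", "sfh", "stfh"), several.ok = TRUE)
  base <- tryCatch(simulate_panel(scenario), stfh_error = function(e) {
    stfh_stop(paste0("scenario inadmissible: ", conditionMessage(e),
                     sprintf(" [m=%d T=%d p=%d seed=%d]", scenario$m,
                             scenario$T, scenario$p, scenario$seed)),
              "stfh_validation_error")
  })
  W <- base$W
  frame <- scenario
  frame$graph <- list(kind = "supplied"); frame$W <- W
  frame$X_spec <- list(kind = "supplied"); frame$X <- base$panel$X
  frame$D_spec <- list(kind = "supplied"); frame$D <- base$panel$D
  m <- scenario$m; Tn <- scenario$T
  tau_true <- unlist(scenario$tau)

  sq <- lapply(models, function(mod)
    matrix(0, m, if (mod == "stfh") Tn else 1))
  names(sq) <- models
  nrep_ok <- stats::setNames(numeric(length(models)), models)
  direct_sq <- matrix(0, m, Tn)
  tau_rows <- list(); beta_rows <- list()
  boot_mse <- NULL; n_boot <- 0L; n_fail <- 0L

  for (r in seq_len(n_reps)) {
    frame$seed <- mix_seed(seed, r)
    sim <- simulate_panel(frame)
    panel <- sim$panel; theta <- sim$truth$theta
    direct_sq <- direct_sq + (panel$y - theta)^2
    pfin <- if (any(models != "stfh")) panel_slice(panel, Tn, index = TRUE)
    for (mod in models) {
      fit <- tryCatch(
        if (mod == "stfh") fit_model(panel, W, "stfh", control = control)
        else fit_model(pfin, if (mod == "sfh") W, mod, control = control),
        stfh_error = function(e) NULL)
      if (is.null(fit) || !isTRUE(fit$converged)) {
        n_fail <- n_fail + 1L
        next
      }
      tau_rows[[length(tau_rows) + 1L]] <-
        data.frame(rep = r, model = toupper(mod),
                   t(unlist(fit$tau_hat)), loglik = fit$loglik)
      if (mod == "stfh") {
        beta_rows[[length(beta_rows) + 1L]] <-
          data.frame(rep = r, t(fit$beta_hat))
        pr <- eblup(fit, panel, W)
        sq[[mod]] <- sq[[mod]] +
          matrix((pr$eblup - as.vector(t(theta)))^2, m, Tn, byrow = TRUE)
        if (boot_B > 0 && n_boot < boot_reps) {
          bp <- mse_bootstrap(fit, panel, W, B = boot_B,
                              seed = mix_seed(seed, r, "boot"))
          bm <- matrix(bp$mse, m, Tn, byrow = TRUE)
          boot_mse <- if (is.null(boot_mse)) bm else boot_mse + bm
          n_boot <- n_boot + 1L
        }
      } else {
        pr <- eblup(fit, pfin, if (mod == "sfh") W)
        sq[[mod]] <- sq[[mod]] + (pr$eblup - theta[, Tn])^2
      }
      nrep_ok[mod] <- nrep_ok[mod] + 1
    }
  }
  emp_mse <- lapply(models, function(mod) sq[[mod]] / max(nrep_ok[mod], 1))
  names(emp_mse) <- models
  direct_mse <- direct_sq / n_reps
  if (!is.null(boot_mse)) boot_mse <- boot_mse / n_boot

  tau_hat <- do.call(rbind, tau_rows)
  beta_hat <- do.call(rbind, beta_rows)
  rows <- list()
  add <- function(quantity, model, value)
    rows[[length(rows) + 1L]] <<- data.frame(quantity = quantity,
                                             model = model, value = value)
  if ("stfh" %in% models && !is.null(tau_hat)) {
    sub <- tau_hat[tau_hat$model == "STFH", ]
    for (nm in c("sigma1_sq", "rho1", "sigma2_sq", "rho2")) {
      add(paste0("bias_", nm), "STFH", mean(sub[[nm]]) - tau_true[nm])
      add(paste0("rmse_", nm), "STFH",
          sqrt(mean((sub[[nm]] - tau_true[nm])^2)))
      add(paste0("median_", nm), "STFH", stats::median(sub[[nm]]))
    }
    if (!is.null(beta_hat)) {
      bh <- as.matrix(beta_hat[, -1, drop = FALSE])
      add("rmse_beta", "STFH",
          sqrt(mean(sweep(bh, 2, scenario$beta)^2)))
    }
  }
  add("emp_mse_final", "direct", mean(direct_mse[, Tn]))
  for (mod in models) {
    add("emp_mse_final", toupper(mod),
        mean(emp_mse[[mod]][, if (mod == "stfh") Tn else 1]))
  }
  add("mean_cv_direct_final", "direct",
      mean(cv_percent(base$panel$y[, Tn], base$panel$D[, Tn]), na.rm = TRUE))
  if (!is.null(boot_mse) && "stfh" %in% models) {
    ratio <- rowMeans(boot_mse) / rowMeans(emp_mse[["stfh"]])
    add("boot_calibration_ratio", "STFH", mean(ratio))
  }
  structure(list(summary = do.call(rbind, rows), tau_hat = tau_hat,
                 beta_hat = beta_hat, emp_mse = emp_mse,
                 direct_mse = direct_mse, boot_mse = boot_mse,
                 n_fit_failures = n_fail, n_reps = n_reps, seed = seed,
                 models = models),
            class = "stfh_recovery")
}

#' @export
print.stfh_recovery <- function(x, ...) {
  cat(sprintf("recovery experiment: %d replicate(s), models: %s, %d fit failure(s)\n",
              x$n_reps, paste(toupper(x$models), collapse = "/"),
              x$n_fit_failures))
  print(transform(x$summary, value = signif(value, 5)), row.names = FALSE)
  invisible(x)
}
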