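#' Empirical best linear unbiased prediction
#'
#' Computes the EBLUP theta_hat = X beta_hat + V_nu Z' V^-1 (y - X beta_hat)
#' for every (area, period) cell, which simplifies to
#' y - D o (V^-1 (y - X beta_hat)) since Z V_nu Z' = V - diag(D). The
#' prediction is a matrix-weighted compromise between the direct estimate
#' and the synthetic part X beta_hat: as a cell's sampling variance goes to
#' 0 it reproduces the direct estimate, and with zero variance components it
#' collapses to the synthetic estimator.
#'
#' @param fit a converged [fit_model()] result.
#' @param panel the [area_panel()] the model was fitted to.
#' @param W proximity matrix (needed whenever the fit has a spatial
#'   component).
#' @return a `stfh_predictions` data frame, one row per cell in area-major
#'   order, with columns `area_id`, `time`, `direct`, `var_direct`, `eblup`,
#'   `mse`, `root_mse`, `cv_direct`, `cv_model`, `model_tag`, `mse_method`.
#'   MSE columns are NA until filled by [mse_analytic_fh()] or
#'   [mse_bootstrap()]. The final period (the "current" survey the model
#'   enhances) is recorded in attribute `headline_time`.
#' @export
eblup <- function(fit, panel, W = NULL) {
  stopifnot(inherits(fit, "stfh_fit"), inherits(panel, "area_panel"))
  if (!isTRUE(fit$converged)) {
    stfh_stop("refusing to predict from a non-converged fit",
              "stfh_model_error")
  }
  if (!is.null(W)) W <- align_proximity(W, panel$area_ids)
  check_tau(fit$tau_hat, W)
  y <- panel_yvec(panel)
  d <- panel_dvec(panel)
  r <- y - drop(panel$X %*% fit$beta_hat)
  V <- build_full_covariance(fit$tau_hat, W, panel$D)$V
  R <- chol(V)
  u <- backsolve(R, backsolve(R, r, transpose = TRUE))  # V^-1 r
  theta <- y - d * u
  new_prediction_set(panel, theta, fit$model)
}

new_prediction_set <- function(panel, eblup_vec, model_tag,
                               mse = NA_real_, mse_method = NA_character_) {
  y <- panel_yvec(panel)
  d <- panel_dvec(panel)
  out <- data.frame(
    area_id = rep(panel$area_ids, each = panel$T),
    time = rep(as.character(panel$time_ids), panel$m),
    direct = y,
    var_direct = d,
    eblup = eblup_vec,
    mse = mse,
    root_mse = sqrt(mse),
    cv_direct = cv_percent(y, d),
    cv_model = if (all(is.na(mse))) NA_real_ else cv_percent(eblup_vec, mse),
    model_tag = model_tag,
    mse_method = mse_method,
    stringsAsFactors = FALSE)
  structure(out,
            class = c("stfh_predictions", "data.frame"),
            headline_time = as.character(panel$time_ids[panel$T]))
}

fill_mse <- function(pred, mse, mse_method) {
  pred$mse <- mse
  pred$root_mse <- sqrt(mse)
  pred$cv_model <- cv_percent(pred$eblup, mse)
  pred$mse_method <- mse_method
  pred
}

#' @export
print.stfh_predictions <- function(x, ...) {
  cat(sprintf("EBLUP predictions (%s), %d cells; headline period: %s\n",
              x$model_tag[1], nrow(x), attr(x, "headline_time")))
  print.data.frame(utils::head(as.data.frame(x), 8), row.names = FALSE)
  if (nrow(x) > 8) cat("...\n")
  invisible(x)
}
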