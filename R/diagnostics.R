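#' Information criteria of a REML fit
#'
#' -2LL, AIC = -2LL + 2k and BIC = -2LL + k log(n), with k the number of
#' estimated parameters (fixed effects plus free covariance parameters:
#' FH p+1, SFH p+2, STFH p+4) and n = m*T. Lower values indicate the
#' preferred model. Because the criteria are built on the restricted
#' likelihood, they are comparable only across models fitted to the same
#' stacked data with identical X.
#'
#' @param fit a converged [fit_model()] result.
#' @return named list `minus2LL`, `AIC`, `BIC`, `k`, `n`.
#' @export
information_criteria <- function(fit) {
  stopifnot(inherits(fit, "stfh_fit"))
  if (!isTRUE(fit$converged)) {
    stfh_stop("information criteria require a converged fit",
              "stfh_model_error")
  }
  m2 <- -2 * fit$loglik
  k <- fit$n_params
  list(minus2LL = m2, AIC = m2 + 2 * k, BIC = m2 + k * log(fit$n),
       k = k, n = fit$n)
}

#' Kolmogorov-Smirnov normality check of model residuals
#'
#' Standardized marginal residuals diag(V_hat)^{-1/2} (y - X beta_hat) are
#' compared with the standard normal using the asymptotic KS distribution.
#' Parameters were estimated from the same data (the Lilliefors caveat), so
#' the p-value is mildly conservative toward normality; it is reported
#' uncorrected, as is usual in applied model checking for this model family.
#'
#' @inheritParams eblup
#' @return list `statistic`, `p_value`, `residuals`.
#' @export
ks_normality <- function(fit, panel, W = NULL) {
  stopifnot(inherits(fit, "stfh_fit"), inherits(panel, "area_panel"))
  if (!isTRUE(fit$converged)) {
    stfh_stop("normality check requires a converged fit", "stfh_model_error")
  }
  if (!is.null(W)) W <- align_proximity(W, panel$area_ids)
  r <- panel_yvec(panel) - drop(panel$X %*% fit$beta_hat)
  V <- build_full_covariance(fit$tau_hat, W, panel$D)$V
  r <- r / sqrt(diag(V))
  if (length(r) < 5) {
    stfh_stop("need at least 5 residuals for the KS test",
              "stfh_samplesize_error")
  }
  kt <- suppressWarnings(stats::ks.test(r, "pnorm", exact = FALSE))
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       residuals = r)
}

#' Bias-diagnostic regression
#'
#' Ordinary least-squares regression of the direct estimates (y-axis) on the
#' model-based estimates (x-axis). Under a valid model the model-based
#' estimates are close to the truth and the fitted line is close to the
#' identity, so (slope, intercept) near (1, 0) is the reported evidence of
#' validity.
#'
#' @param direct vector of direct estimates.
#' @param model_est vector of model-based estimates, same length >= 3.
#' @return list `slope`, `intercept`, `r_squared`.
#' @export
bias_diagnostic <- function(direct, model_est) {
  if (length(direct) != length(model_est) || length(direct) < 3) {
    stfh_stop("need two aligned vectors of length >= 3",
              "stfh_validation_error")
  }
  if (stats::sd(model_est) < 1e-12) {
    stfh_stop("model estimates are constant; regression is degenerate",
              "stfh_degenerate_error")
  }
  f <- stats::lm(direct ~ model_est)
  tss <- sum((direct - mean(direct))^2)
  r2 <- if (tss < 1e-30) 1 else 1 - sum(stats::residuals(f)^2) / tss
  list(slope = unname(stats::coef(f)[2]),
       intercept = unname(stats::coef(f)[1]),
       r_squared = r2)
}

#' Percent coefficient of variation
#'
#' CV% = 100 * sqrt(mse) / |estimate|. Estimates are z-score means and may
#' legitimately be negative, hence the absolute value. Cells with
#' |estimate| < 1e-8 are flagged unstable and their CV is omitted (NA);
#' the flags are returned in attribute `unstable`.
#'
#' @param estimate estimate vector (or scalar).
#' @param mse nonnegative MSE (or sampling variance for direct estimates).
#' @return numeric vector of CV percentages with attribute `unstable`.
#' @export
cv_percent <- function(estimate, mse) {
  if (any(mse < 0, na.rm = TRUE)) {
    stfh_stop("mse must be >= 0", "stfh_validation_error")
  }
  unstable <- abs(estimate) < 1e-8
  out <- ifelse(unstable, NA_real_, 100 * sqrt(mse) / abs(estimate))
  attr(out, "unstable") <- unstable
  out
}

#' Efficiency gain in CV of one estimator over a reference
#'
#' gain_i = 100 * (cv_ref_i - cv_model_i) / cv_ref_i: the percentage
#' reduction in CV relative to the reference (bounded above by 100,
#' unbounded below; negative values are efficiency losses and are
#' reported as such). The summary follows the six-number layout
#' (Min, Q1, Mean, Median, Q3, Max).
#'
#' @param cv_ref reference CVs (e.g. direct estimates), strictly positive.
#' @param cv_model model-based CVs, aligned with `cv_ref`.
#' @return list `gain` (per area) and `summary` (named six-number vector).
#' @export
efficiency_gain <- function(cv_ref, cv_model) {
  if (length(cv_ref) != length(cv_model)) {
    stfh_stop("cv_ref and cv_model must be aligned", "stfh_validation_error")
  }
  if (any(!is.finite(cv_ref)) || any(cv_ref <= 0)) {
    stfh_stop("reference CV must be positive and finite",
              "stfh_validation_error")
  }
  gain <- 100 * (cv_ref - cv_model) / cv_ref
  list(gain = gain, summary = six_number(gain))
}

six_number <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
  c(Min = min(x, na.rm = TRUE), Q1 = q[1], Mean = mean(x, na.rm = TRUE),
    Median = q[2], Q3 = q[3], Max = max(x, na.rm = TRUE))
}

#' Model-assessment report
#'
#' Bundles the diagnostic battery for one or more fits on common data:
#' information criteria per model, KS normality of the standardized
#' residuals, the bias-diagnostic regression of direct on model-based
#' estimates, and (when predictions with MSE are supplied) CV% and
#' efficiency-gain summaries against the direct estimator.
#'
#' @param fits named list of converged `stfh_fit` objects (identical panel).
#' @param panel,W the common data.
#' @param predictions optional named list of `stfh_predictions` (aligned
#'   with `fits`) whose MSE columns are filled.
#' @return list of class `stfh_diagnostics`: `ic` (data frame), `ks`,
#'   `bias`, `cv_summary`, `gain` (per model with MSE available).
#' @export
diagnostics_report <- function(fits, panel, W = NULL, predictions = NULL) {
  if (inherits(fits, "stfh_fit")) fits <- list(fits)
  if (is.null(names(fits))) {
    names(fits) <- vapply(fits, function(f) f$model, "")
  }
  ic <- do.call(rbind, lapply(names(fits), function(nm) {
    v <- information_criteria(fits[[nm]])
    data.frame(model = nm, minus2LL = v$minus2LL, AIC = v$AIC,
               BIC = v$BIC, k = v$k, n = v$n)
  }))
  ks <- lapply(fits, function(f) {
    v <- ks_normality(f, panel, if (f$tau_hat$sigma1_sq > 0) W else NULL)
    v[c("statistic", "p_value")]
  })
  bias <- lapply(fits, function(f) {
    pr <- eblup(f, panel, if (f$tau_hat$sigma1_sq > 0) W else NULL)
    bias_diagnostic(pr$direct, pr$eblup)
  })
  cv_summary <- NULL; gain <- NULL
  if (!is.null(predictions)) {
    cv_summary <- lapply(predictions, function(pr)
      six_number(pr$cv_model))
    gain <- lapply(predictions, function(pr) {
      ok <- is.finite(pr$cv_direct) & pr$cv_direct > 0
      efficiency_gain(pr$cv_direct[ok], pr$cv_model[ok])
    })
  }
  structure(list(ic = ic, ks = ks, bias = bias,
                 cv_summary = cv_summary, gain = gain),
            class = "stfh_diagnostics")
}

#' @export
print.stfh_diagnostics <- function(x, ...) {
  cat("Model comparison based on information criteria\n")
  tab <- t(as.matrix(x$ic[, c("minus2LL", "AIC", "BIC")]))
  rownames(tab) <- c("-2LL", "AIC", "BIC")
  colnames(tab) <- x$ic$model
  print(round(tab, 2))
  cat("\nKolmogorov-Smirnov normality of standardized residuals\n")
  for (nm in names(x$ks)) {
    cat(sprintf("  %-5s D = %.4f, p = %.4f\n", nm,
                x$ks[[nm]]$statistic, x$ks[[nm]]$p_value))
  }
  cat("\nBias diagnostic (direct ~ model estimates)\n")
  for (nm in names(x$bias)) {
    cat(sprintf("  %-5s slope = %.3f, intercept = %.3f, R^2 = %.3f\n", nm,
                x$bias[[nm]]$slope, x$bias[[nm]]$intercept,
                x$bias[[nm]]$r_squared))
  }
  if (!is.null(x$gain)) {
    cat("\nEfficiency gain in CV (%) over the direct estimator\n")
    tab <- do.call(cbind, lapply(x$gain, function(g) g$summary))
    print(round(tab, 2))
  }
  invisible(x)
}
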