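# REML fitting of the FH / SFH / STFH family.
#
# All three model tags are constrained versions of one stacked covariance
#   var(y) = sigma1^2 (Omega1(rho1) (x) J_T) + sigma2^2 (I (x) Omega2(rho2))
#            + diag(D):
#   FH   - independent cell effect:   free (sigma2_sq)           k = p + 1
#   SFH  - SAR(1) area effect:        free (sigma1_sq, rho1)     k = p + 2
#   STFH - both, AR(1) over time:     free all four              k = p + 4
# Optimization is over transformed parameters (log variances; tanh-mapped
# autocorrelations restricted to their admissible intervals) with bounded
# quasi-Newton and a derivative-free simplex fallback.

model_free_params <- function(model) {
  switch(model,
         fh = "sigma2_sq",
         sfh = c("sigma1_sq", "rho1"),
         stfh = c("sigma1_sq", "rho1", "sigma2_sq", "rho2"),
         stfh_stop(paste0("unknown model tag: ", model), "stfh_model_error"))
}

#' Optimizer settings for [fit_model()]
#'
#' @param maxit iteration cap for the quasi-Newton optimizer.
#' @param factr,pgtol L-BFGS-B tolerances (relative objective change about
#'   `factr * .Machine$double.eps`, projected-gradient norm `pgtol`, both on
#'   the transformed scale).
#' @param ndeps finite-difference step for numerical gradients.
#' @param extra_start add the alternative start (rho1 = 0.5, rho2 = -0.3)
#'   guarding against multimodality in rho2; the best optimum is kept.
#' @param use_default_starts when FALSE and explicit `starts` are supplied
#'   to [fit_model()], skip the built-in starting values (used by the
#'   bootstrap, which warm-starts refits at tau_hat).
#' @return list of class `stfh_control`.
#' @export
fit_control <- function(maxit = 500, factr = 1e7, pgtol = 1e-5,
                        ndeps = 1e-5, extra_start = TRUE,
                        use_default_starts = TRUE) {
  structure(list(maxit = maxit, factr = factr, pgtol = pgtol,
                 ndeps = ndeps, extra_start = extra_start,
                 use_default_starts = use_default_starts),
            class = "stfh_control")
}

# psi <-> tau transforms. `iv` is the admissible rho1 interval.
psi_to_tau <- function(psi, free, fixed_tau, iv) {
  out <- fixed_tau
  for (j in seq_along(free)) {
    nm <- free[j]
    out[[nm]] <- switch(nm,
      sigma1_sq = , sigma2_sq = exp(psi[j]),
      rho2 = tanh(psi[j]),
      rho1 = (iv[1] + iv[2]) / 2 + (iv[2] - iv[1]) / 2 * tanh(psi[j]))
  }
  out
}

tau_to_psi <- function(tau, free, iv) {
  vapply(free, function(nm) switch(nm,
    sigma1_sq = log(max(tau[[nm]], 1e-12)),
    sigma2_sq = log(max(tau[[nm]], 1e-12)),
    rho2 = atanh(max(-0.999, min(0.999, tau[[nm]]))),
    rho1 = atanh(max(-0.999, min(0.999,
      (tau[[nm]] - (iv[1] + iv[2]) / 2) / ((iv[2] - iv[1]) / 2))))), 0)
}

#' Fit an area-level model by REML
#'
#' Maximizes the restricted likelihood of the Fay-Herriot (`"fh"`), spatial
#' Fay-Herriot (`"sfh"`) or spatio-temporal Fay-Herriot (`"stfh"`) model
#' over the admissible covariance-parameter box, then computes the GLS fixed
#' effects at the optimum. Variance estimates below 1e-10 are reported as 0
#' with a boundary flag.
#'
#' @param panel an [area_panel()]. `"stfh"` requires T >= 2; `"fh"` and
#'   `"sfh"` accept any T (a T > 1 panel is fitted as one stacked model with
#'   a single beta; use [panel_slice()] for per-period fits).
#' @param W proximity matrix; required for `"sfh"` and `"stfh"`.
#' @param model model tag.
#' @param fixed named list constraining covariance parameters to fixed
#'   values (e.g. `list(sigma1_sq = 0, rho1 = 0, rho2 = 0)` reduces STFH to
#'   the stacked FH model); constrained parameters are not counted in
#'   `n_params`.
#' @param starts optional list of [variance_components()] used as additional
#'   optimizer starts.
#' @param control a [fit_control()] list.
#' @return object of class `stfh_fit`: `model`, `beta_hat`, `beta_cov`,
#'   `tau_hat`, `loglik`, `n`, `p`, `n_params`, `converged`, `n_iter`,
#'   `boundary`, `trace` (one row per start), plus the free/fixed parameter
#'   bookkeeping needed to refit in the bootstrap.
#' @export
fit_model <- function(panel, W = NULL, model = c("stfh", "sfh", "fh"),
                      fixed = list(), starts = NULL,
                      control = fit_control()) {
  stopifnot(inherits(panel, "area_panel"))
  model <- match.arg(model)
  if (model == "stfh" && panel$T < 2) {
    stfh_stop("the spatio-temporal model needs T >= 2 periods; use model = 'fh' or 'sfh'",
              "stfh_model_error")
  }
  if (model %in% c("sfh", "stfh") && is.null(W)) {
    stfh_stop(sprintf("model '%s' requires a proximity matrix W", model),
              "stfh_model_error")
  }
  if (!is.null(W)) W <- align_proximity(W, panel$area_ids)
  free <- setdiff(model_free_params(model), names(fixed))
  fixed_tau <- list(sigma1_sq = 0, rho1 = 0, sigma2_sq = 0, rho2 = 0)
  for (nm in names(fixed)) fixed_tau[[nm]] <- fixed[[nm]]
  iv <- if (!is.null(W)) rho1_interval(W) else c(-0.999, 0.999)

  negll <- function(psi) {
    tl <- psi_to_tau(psi, free, fixed_tau, iv)
    tau <- variance_components(tl$sigma1_sq, tl$rho1, tl$sigma2_sq, tl$rho2)
    ll <- reml_loglik_internal(tau, panel, W)
    if (!is.finite(ll)) 1e10 else -ll
  }

  s0 <- stats::median(panel_dvec(panel)) / 2
  start_list <- list(variance_components(s0, 0, s0, 0))
  if (isTRUE(control$extra_start) && any(c("rho1", "rho2") %in% free)) {
    start_list <- c(start_list, list(variance_components(s0, 0.5, s0, -0.3)))
  }
  if (!is.null(starts)) {
    starts <- lapply(starts, function(st) {
      if (inherits(st, "variance_components")) st else
        do.call(variance_components, as.list(st))
    })
    start_list <- if (isTRUE(control$use_default_starts)) {
      c(start_list, starts)
    } else starts
  }

  k <- length(free)
  if (k == 0) stfh_stop("no free covariance parameters", "stfh_model_error")
  lower <- ifelse(grepl("sigma", free), -30, -6)
  upper <- ifelse(grepl("sigma", free), 10, 6)

  runs <- lapply(start_list, function(st) {
    psi0 <- tau_to_psi(st, free, iv)
    psi0 <- pmin(pmax(psi0, lower + 1e-6), upper - 1e-6)
    if (!is.finite(negll(psi0))) {
      return(list(value = Inf, par = psi0, convergence = 99L,
                  counts = c(0L, 0L), method = "none"))
    }
    res <- tryCatch(
      stats::optim(psi0, negll, method = if (k == 1) "Brent" else "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = if (k == 1) list(maxit = control$maxit) else
                     list(maxit = control$maxit, factr = control$factr,
                          pgtol = control$pgtol, ndeps = rep(control$ndeps, k))),
      error = function(e) NULL)
    if (is.null(res)) {  # line-search failure: derivative-free fallback
      res <- stats::optim(psi0, negll, method = "Nelder-Mead",
                          control = list(maxit = 4 * control$maxit,
                                         reltol = 1e-12))
      res$method <- "Nelder-Mead"
    } else {
      res$method <- if (k == 1) "Brent" else "L-BFGS-B"
    }
    res
  })
  values <- vapply(runs, function(r) r$value, 0)
  if (all(!is.finite(values) | values >= 1e10)) {
    stfh_stop("restricted likelihood non-finite at every start",
              "stfh_initialization_error")
  }
  best <- runs[[which.min(values)]]
  tl <- psi_to_tau(best$par, free, fixed_tau, iv)

  # boundary clamping: REML can land on sigma^2 = 0, in which case the
  # corresponding autocorrelation is unidentified and is reported as 0
  boundary <- character(0)
  rho_of <- c(sigma1_sq = "rho1", sigma2_sq = "rho2")
  for (nm in c("sigma1_sq", "sigma2_sq")) {
    if (nm %in% free && tl[[nm]] < 1e-10) {
      tl[[nm]] <- 0
      boundary <- c(boundary, nm)
      if (rho_of[[nm]] %in% free) tl[[rho_of[[nm]]]] <- 0
    }
  }
  tau_hat <- variance_components(tl$sigma1_sq, tl$rho1, tl$sigma2_sq, tl$rho2)
  loglik <- reml_loglik_internal(tau_hat, panel, W)
  g <- gls_beta(tau_hat, panel, W)
  conv <- is.finite(loglik) &&
    (best$convergence == 0 ||
       (identical(best$method, "Brent") && best$convergence %in% 0L))
  trace <- data.frame(
    start = seq_along(runs),
    method = vapply(runs, function(r) r$method %||% "none", ""),
    neg_loglik = values,
    convergence = vapply(runs, function(r) as.integer(r$convergence), 0L),
    n_eval = vapply(runs, function(r) as.integer(r$counts[1]), 0L))

  structure(list(model = toupper(model), beta_hat = g$beta_hat,
                 beta_cov = g$beta_cov, tau_hat = tau_hat, loglik = loglik,
                 n = panel$m * panel$T, m = panel$m, T = panel$T,
                 p = panel$p, n_params = panel$p + length(free),
                 converged = isTRUE(conv),
                 n_iter = as.integer(best$counts[1]),
                 boundary = boundary, free = free, fixed = fixed,
                 trace = trace, time_ids = panel$time_ids,
                 area_ids = panel$area_ids),
            class = "stfh_fit")
}

#' @export
print.stfh_fit <- function(x, ...) {
  cat(sprintf("%s model fit by REML (%d areas x %d periods)\n",
              x$model, x$m, x$T))
  cat(sprintf("  log-restricted-likelihood: %.4f  (converged: %s)\n",
              x$loglik, x$converged))
  est <- unlist(x$tau_hat)
  lab <- c("sigma1^2", "rho1", "sigma2^2", "rho2")
  shown <- c("sigma1_sq", "rho1", "sigma2_sq", "rho2") %in%
    c(x$free, names(x$fixed))
  for (j in which(shown)) {
    cat(sprintf("  %-9s %s%.6g\n", lab[j],
                if (names(est)[j] %in% x$boundary) "(boundary) " else "",
                est[j]))
  }
  cat("  fixed effects:\n")
  print(round(x$beta_hat, 5))
  invisible(x)
}
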