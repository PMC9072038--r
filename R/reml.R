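#' Restricted log-likelihood of the stacked model
#'
#' Evaluates the Gaussian restricted (REML) log-likelihood
#' \deqn{\ell_R(\tau) = -\tfrac12[(n-p)\log 2\pi + \log|V| +
#'   \log|X'V^{-1}X| + y'Py],}
#' with \eqn{P = V^{-1} - V^{-1}X(X'V^{-1}X)^{-1}X'V^{-1}} and n = m*T, at
#' the covariance parameters tau. V is factorized once (Cholesky); no
#' explicit inverses are formed. The value is invariant under y -> y + Xc.
#'
#' @param tau a [variance_components()] object.
#' @param panel an [area_panel()].
#' @param W proximity matrix (required when `tau$sigma1_sq > 0`).
#' @return scalar log-likelihood.
#' @export
reml_loglik <- function(tau, panel, W = NULL) {
  stopifnot(inherits(panel, "area_panel"))
  check_tau(tau, W)
  ll <- reml_loglik_internal(tau, panel, W)
  if (!is.finite(ll)) {
    stfh_stop(sprintf(
      "covariance numerically singular at tau = (%.3g, %.3g, %.3g, %.3g)",
      tau$sigma1_sq, tau$rho1, tau$sigma2_sq, tau$rho2),
      "stfh_conditioning_error")
  }
  ll
}

reml_loglik_internal <- function(tau, panel, W = NULL) {
  Wm <- if (is.null(W)) matrix(0, panel$m, panel$m) else unclass(as.matrix(W))
  if (tau$sigma1_sq > 0 && is.null(W)) return(NA_real_)
  reml_loglik_cpp(panel_yvec(panel), panel$X, panel_dvec(panel), Wm,
                  tau$sigma1_sq, tau$rho1, tau$sigma2_sq, tau$rho2,
                  as.integer(panel$T))
}

#' Generalized least squares fixed effects at given variance components
#'
#' beta_hat = (X'V^-1 X)^-1 X'V^-1 y with covariance (X'V^-1 X)^-1, the GLS
#' step implicit in both REML and the EBLUP.
#'
#' @inheritParams reml_loglik
#' @return list with `beta_hat` (named p-vector) and `beta_cov` (p x p).
#' @export
gls_beta <- function(tau, panel, W = NULL) {
  X <- panel$X
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    dep <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    stfh_stop(paste0("X is rank deficient; dependent column(s): ",
                     paste(dep, collapse = ", ")), "stfh_rank_error")
  }
  check_tau(tau, W)
  V <- build_full_covariance(tau, W, panel$D)$V
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) {
    stfh_stop("covariance matrix not positive definite",
              "stfh_conditioning_error")
  }
  Xw <- backsolve(R, X, transpose = TRUE)
  yw <- backsolve(R, panel_yvec(panel), transpose = TRUE)
  M <- crossprod(Xw)
  beta <- drop(solve(M, crossprod(Xw, yw)))
  cov <- solve(M)
  cov <- (cov + t(cov)) / 2
  names(beta) <- colnames(X)
  dimnames(cov) <- list(colnames(X), colnames(X))
  list(beta_hat = beta, beta_cov = cov)
}
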