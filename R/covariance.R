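#' Variance components of the spatio-temporal area-level model
#'
#' tau = (sigma1_sq, rho1, sigma2_sq, rho2): variance and autocorrelation of
#' the SAR(1) spatial area effect, and innovation variance and
#' autocorrelation of the stationary AR(1) area-by-time effect.
#'
#' @param sigma1_sq spatial effect variance, >= 0.
#' @param rho1 spatial autocorrelation; must lie in the SAR-admissible
#'   interval of the proximity matrix in use (checked where W is available).
#' @param sigma2_sq temporal innovation variance, >= 0.
#' @param rho2 temporal autocorrelation, |rho2| < 1.
#' @return object of class `variance_components` (a named list).
#' @export
variance_components <- function(sigma1_sq = 0, rho1 = 0,
                                sigma2_sq = 0, rho2 = 0) {
  sigma1_sq <- unname(sigma1_sq); rho1 <- unname(rho1)
  sigma2_sq <- unname(sigma2_sq); rho2 <- unname(rho2)
  if (!is.finite(sigma1_sq) || sigma1_sq < 0) {
    stfh_stop("sigma1_sq must be finite and >= 0", "stfh_admissibility_error")
  }
  if (!is.finite(sigma2_sq) || sigma2_sq < 0) {
    stfh_stop("sigma2_sq must be finite and >= 0", "stfh_admissibility_error")
  }
  if (!is.finite(rho2) || abs(rho2) >= 1) {
    stfh_stop(sprintf("rho2 = %g is inadmissible (need |rho2| < 1)", rho2),
              "stfh_admissibility_error")
  }
  if (!is.finite(rho1)) {
    stfh_stop("rho1 must be finite", "stfh_admissibility_error")
  }
  structure(list(sigma1_sq = sigma1_sq, rho1 = rho1,
                 sigma2_sq = sigma2_sq, rho2 = rho2),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("tau: sigma1^2 = %.6g, rho1 = %.4f, sigma2^2 = %.6g, rho2 = %.4f\n",
              x$sigma1_sq, x$rho1, x$sigma2_sq, x$rho2))
  invisible(x)
}

check_tau <- function(tau, W = NULL) {
  stopifnot(inherits(tau, "variance_components"))
  if (!is.null(W) && tau$sigma1_sq > 0) {
    iv <- rho1_interval(W)
    if (tau$rho1 <= iv[1] || tau$rho1 >= iv[2]) {
      stfh_stop(sprintf(
        "rho1 = %g outside the SAR-admissible interval (%.4f, %.4f) for W",
        tau$rho1, iv[1], iv[2]), "stfh_admissibility_error")
    }
  }
  invisible(tau)
}

#' AR(1) temporal structure matrix
#'
#' T x T covariance structure of a stationary AR(1) process with unit
#' innovation variance: entries rho2^|t-s| / (1 - rho2^2). The constant
#' diagonal 1/(1 - rho2^2) is the stationary variance, so the area-by-time
#' effect has covariance sigma2_sq * build_omega2(rho2, T).
#'
#' @param rho2 autocorrelation, |rho2| < 1.
#' @param T number of periods, >= 1.
#' @return symmetric positive definite T x T Toeplitz matrix.
#' @export
build_omega2 <- function(rho2, T) {
  if (!is.finite(rho2) || abs(rho2) >= 1) {
    stfh_stop(sprintf("rho2 = %g is inadmissible (need |rho2| < 1)", rho2),
              "stfh_admissibility_error")
  }
  T <- as.integer(T)
  stopifnot(T >= 1)
  H <- abs(outer(seq_len(T), seq_len(T), "-"))
  (rho2^H) / (1 - rho2^2)
}

#' SAR(1) spatial structure matrix
#'
#' m x m covariance structure of the simultaneous autoregressive area
#' effect: Omega1 = ((I - rho1 W)' (I - rho1 W))^-1 for a row-standardized
#' proximity matrix W. The area effect has covariance sigma1_sq * Omega1.
#'
#' @param rho1 spatial autocorrelation inside the SAR-admissible interval
#'   for `W` (see [proximity_matrix()]).
#' @param W proximity matrix (row-standardized m x m).
#' @return symmetric positive definite m x m matrix.
#' @export
build_omega1 <- function(rho1, W) {
  Wm <- unclass(as.matrix(W))
  iv <- rho1_interval(W)
  if (!is.finite(rho1) || rho1 <= iv[1] || rho1 >= iv[2]) {
    stfh_stop(sprintf(
      "rho1 = %g outside the SAR-admissible interval (%.4f, %.4f)",
      rho1, iv[1], iv[2]), "stfh_admissibility_error")
  }
  A <- diag(nrow(Wm)) - rho1 * Wm
  P <- crossprod(A)
  O1 <- tryCatch(chol2inv(chol(P)), error = function(e) NULL)
  if (is.null(O1)) {
    stfh_stop(sprintf("I - rho1 W numerically singular at rho1 = %g", rho1),
              "stfh_admissibility_error")
  }
  (O1 + t(O1)) / 2
}

#' Full covariance of the stacked model
#'
#' Assembles every covariance object of the spatio-temporal model:
#' var(y) = Z V_nu Z' + V_eps with V_nu = diag(sigma1_sq Omega1,
#' sigma2_sq Omega2), Z = (Z1, I), Z1 repeating each area effect over its T
#' rows. Equivalently V = sigma1_sq (Omega1 (x) J_T) +
#' sigma2_sq (I_m (x) Omega2) + diag(D).
#'
#' @param tau a [variance_components()] object.
#' @param W proximity matrix, or NULL when sigma1_sq = 0 (no spatial term).
#' @param D m x T matrix of sampling variances.
#' @return list of class `covariance_bundle` with elements `Omega1` (m x m),
#'   `Omega2` (T x T block, identical across areas), `V_nu`, `V_eps`, `V`,
#'   `Z`.
#' @export
build_full_covariance <- function(tau, W = NULL, D) {
  check_tau(tau, W)
  D <- as.matrix(D)
  m <- nrow(D); Tn <- ncol(D)
  if (any(D <= 0)) stfh_stop("D must be > 0", "stfh_validation_error")
  if (!is.null(W) && nrow(as.matrix(W)) != m) {
    stfh_stop("W and D disagree on the number of areas",
              "stfh_validation_error")
  }
  O1 <- if (tau$sigma1_sq > 0) {
    if (is.null(W)) stfh_stop("sigma1_sq > 0 requires a proximity matrix W",
                              "stfh_validation_error")
    build_omega1(tau$rho1, W)
  } else diag(m)
  O2 <- build_omega2(tau$rho2, Tn)
  n <- m * Tn
  Z1 <- kronecker(diag(m), matrix(1, Tn, 1))
  Z <- cbind(Z1, diag(n))
  V_nu <- matrix(0, m + n, m + n)
  V_nu[seq_len(m), seq_len(m)] <- tau$sigma1_sq * O1
  V_nu[m + seq_len(n), m + seq_len(n)] <-
    tau$sigma2_sq * kronecker(diag(m), O2)
  V_eps <- diag(as.vector(t(D)), n)
  V <- tau$sigma1_sq * kronecker(O1, matrix(1, Tn, Tn)) +
    tau$sigma2_sq * kronecker(diag(m), O2)
  diag(V) <- diag(V) + as.vector(t(D))
  V <- (V + t(V)) / 2
  structure(list(Omega1 = O1, Omega2 = O2, V_nu = V_nu, V_eps = V_eps,
                 V = V, Z = Z),
            class = "covariance_bundle")
}
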