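#' Analytic MSE of the Fay-Herriot EBLUP
#'
#' Prasad-Rao-type decomposition MSE = g1 + g2 + 2*g3 for the classical
#' Fay-Herriot model (independent cell effects with variance sigma^2, known
#' sampling variances d), per cell:
#' \itemize{
#'   \item g1 = gamma * d, gamma = sigma^2 / (sigma^2 + d) — random-effect
#'     variability;
#'   \item g2 = (1 - gamma)^2 * x' (X'V^-1 X)^-1 x — fixed-effect
#'     estimation, O(1/m);
#'   \item g3 = d^2 (sigma^2 + d)^-3 * var(sigma_hat^2) — variance-component
#'     estimation, with var(sigma_hat^2) = 2 / sum_j (sigma^2 + d_j)^-2 from
#'     the REML information.
#' }
#' Closed forms exist only for this model; for the spatial and
#' spatio-temporal models use [mse_bootstrap()].
#'
#' @param fit a converged FH [fit_model()] result.
#' @param panel the fitted [area_panel()].
#' @return `stfh_predictions` with columns `g1`, `g2`, `g3` added and the
#'   MSE columns filled (`mse_method = "analytic"`).
#' @export
mse_analytic_fh <- function(fit, panel) {
  stopifnot(inherits(fit, "stfh_fit"))
  if (fit$model != "FH") {
    stfh_stop(paste0("analytic MSE components are available for the FH model only; ",
                     "use mse_bootstrap() for ", fit$model),
              "stfh_model_error")
  }
  if (!isTRUE(fit$converged)) {
    stfh_stop("refusing to compute MSE from a non-converged fit",
              "stfh_model_error")
  }
  d <- panel_dvec(panel)
  s2 <- fit$tau_hat$sigma2_sq
  gamma <- s2 / (s2 + d)
  g1 <- gamma * d
  M <- crossprod(panel$X / sqrt(s2 + d))      # X'V^-1 X, V diagonal
  Minv <- solve(M)
  g2 <- (1 - gamma)^2 * rowSums((panel$X %*% Minv) * panel$X)
  var_s2 <- 2 / sum(1 / (s2 + d)^2)
  g3 <- d^2 / (s2 + d)^3 * var_s2
  pred <- eblup(fit, panel)
  pred <- fill_mse(pred, g1 + g2 + 2 * g3, "analytic")
  pred$g1 <- g1
  pred$g2 <- g2
  pred$g3 <- g3
  pred
}

# One parametric draw of (theta*, y*) from the fitted model. Every normal
# deviate comes from a sub-stream keyed by (seed, replicate, component,
# area id), so draws are independent of area ordering and of which other
# components are active.
boot_draw <- function(b, seed, panel, Xb, sqrt1, s2, r2) {
  m <- panel$m; Tn <- panel$T
  ids <- panel$area_ids
  z1 <- vapply(ids, function(id)
    with_seed(mix_seed(seed, b, 1L, id), stats::rnorm(1)), 0)
  nu1 <- if (is.null(sqrt1)) numeric(m) else drop(sqrt1 %*% z1)
  nu2 <- matrix(0, m, Tn)
  if (s2 > 0) {
    sd_stat <- sqrt(s2 / (1 - r2^2))
    for (i in seq_len(m)) {
      e <- with_seed(mix_seed(seed, b, 2L, ids[i]), stats::rnorm(Tn))
      v <- numeric(Tn)
      v[1] <- sd_stat * e[1]
      if (Tn > 1) for (t in 2:Tn) v[t] <- r2 * v[t - 1] + sqrt(s2) * e[t]
      nu2[i, ] <- v
    }
  }
  eps <- matrix(0, m, Tn)
  for (i in seq_len(m)) {
    eps[i, ] <- with_seed(mix_seed(seed, b, 3L, ids[i]),
                          stats::rnorm(Tn)) * sqrt(panel$D[i, ])
  }
  theta <- Xb + as.vector(t(nu1 + nu2))    # stacked, area-major
  ystar <- theta + as.vector(t(eps))
  list(theta = theta, y = matrix(ystar, m, Tn, byrow = TRUE))
}

#' Parametric bootstrap MSE of the EBLUP
#'
#' For b = 1..B, draws nu1* ~ N(0, sigma1_hat^2 Omega1(rho1_hat)), nu2* from
#' the stationary AR(1) with (sigma2_hat^2, rho2_hat) and eps* ~ N(0,
#' diag(D)); forms y* = X beta_hat + nu1* + nu2* + eps* and the bootstrap
#' truth theta* = X beta_hat + nu1* + nu2*; re-estimates the model on y*
#' (variance components refitted when `refit = TRUE`, held at tau_hat with
#' beta re-estimated by GLS otherwise); and averages (eblup* - theta*)^2.
#'
#' Replicates whose refit fails to converge are dropped and redrawn; more
#' than `fail_cap * B` failures abort with a bootstrap error reporting the
#' fraction. Identical `seed` gives identical output, and because draws are
#' keyed per area id the result is equivariant under relabelling of areas.
#'
#' @param fit converged [fit_model()] result (any model tag; FH is accepted
#'   mainly to cross-validate against [mse_analytic_fh()]).
#' @param panel,W the fitted data.
#' @param B number of bootstrap replicates, >= 1.
#' @param seed integer seed (mandatory).
#' @param refit re-estimate the variance components per replicate (default,
#'   matching the parametric-bootstrap methodology the model family uses);
#'   `FALSE` holds tau_hat fixed and only re-estimates beta.
#' @param fail_cap maximum tolerated fraction of non-converged replicates.
#' @param control optimizer settings for the refits.
#' @return `stfh_predictions` with bootstrap MSE filled in;
#'   `mse_method` records B and the mode, attribute `n_failed` the number of
#'   redrawn replicates.
#' @export
mse_bootstrap <- function(fit, panel, W = NULL, B, seed, refit = TRUE,
                          fail_cap = 0.1,
                          control = fit_control(extra_start = FALSE,
                                                use_default_starts = FALSE)) {
  stopifnot(inherits(fit, "stfh_fit"), inherits(panel, "area_panel"))
  if (!isTRUE(fit$converged)) {
    stfh_stop("refusing to bootstrap a non-converged fit", "stfh_model_error")
  }
  B <- as.integer(B)
  if (is.na(B) || B < 1) stfh_stop("B must be >= 1", "stfh_bootstrap_error")
  if (missing(seed)) stfh_stop("seed is mandatory", "stfh_bootstrap_error")
  if (!is.null(W)) W <- align_proximity(W, panel$area_ids)
  tau <- fit$tau_hat
  check_tau(tau, W)
  Xb <- drop(panel$X %*% fit$beta_hat)
  sqrt1 <- if (tau$sigma1_sq > 0) {
    sym_sqrt(tau$sigma1_sq * build_omega1(tau$rho1, W))
  } else NULL

  # fixed-tau mode: factorize V once
  if (!refit) {
    V <- build_full_covariance(tau, W, panel$D)$V
    R <- chol(V)
    Xw <- backsolve(R, panel$X, transpose = TRUE)
    XtX <- crossprod(Xw)
  }
  d <- panel_dvec(panel)

  sq_sum <- numeric(panel$m * panel$T)
  done <- 0L; b_draw <- 0L; n_failed <- 0L
  max_fail <- ceiling(fail_cap * B)
  while (done < B) {
    b_draw <- b_draw + 1L
    dr <- boot_draw(b_draw, seed, panel, Xb, sqrt1,
                    tau$sigma2_sq, tau$rho2)
    pstar <- panel
    pstar$y <- dr$y
    if (refit) {
      fstar <- tryCatch(
        fit_model(pstar, W, model = tolower(fit$model), fixed = fit$fixed,
                  starts = list(tau), control = control),
        stfh_error = function(e) NULL)
      if (is.null(fstar) || !isTRUE(fstar$converged)) {
        n_failed <- n_failed + 1L
        if (n_failed > max_fail) {
          stfh_stop(sprintf(
            "bootstrap refit failure fraction %.2f exceeded cap %.2f (%d of %d draws)",
            n_failed / b_draw, fail_cap, n_failed, b_draw),
            "stfh_bootstrap_error")
        }
        next
      }
      theta_hat <- eblup(fstar, pstar, W)$eblup
    } else {
      ystar <- as.vector(t(dr$y))
      yw <- backsolve(R, ystar, transpose = TRUE)
      beta_star <- solve(XtX, crossprod(Xw, yw))
      r <- ystar - drop(panel$X %*% beta_star)
      u <- backsolve(R, backsolve(R, r, transpose = TRUE))
      theta_hat <- ystar - d * u
    }
    sq_sum <- sq_sum + (theta_hat - dr$theta)^2
    done <- done + 1L
  }
  pred <- eblup(fit, panel, W)
  pred <- fill_mse(pred, sq_sum / B,
                   sprintf("bootstrap B=%d (%s)", B,
                           if (refit) "refit" else "fixed-tau"))
  attr(pred, "n_failed") <- n_failed
  attr(pred, "seed") <- seed
  pred
}
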