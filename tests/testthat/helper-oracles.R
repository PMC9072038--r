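# Independent oracles and small fixture builders. Everything here
# deliberately uses the naive route (explicit inverses, determinants,
# element-by-element assembly) that the package itself avoids, so the two
# paths stay independent. Only used at dimensions m*T <= ~16.

# element-wise assembly of var(y) from first principles
naive_full_covariance <- function(tau, W, D) {
  m <- nrow(D); Tn <- ncol(D)
  O1 <- if (is.null(W)) diag(m) else {
    A <- diag(m) - tau$rho1 * unclass(as.matrix(W))
    solve(t(A) %*% A)
  }
  O2 <- matrix(0, Tn, Tn)
  for (t in 1:Tn) for (s in 1:Tn) {
    O2[t, s] <- tau$rho2^abs(t - s) / (1 - tau$rho2^2)
  }
  n <- m * Tn
  V <- matrix(0, n, n)
  for (i in 1:m) for (t in 1:Tn) for (j in 1:m) for (s in 1:Tn) {
    r <- (i - 1) * Tn + t; c <- (j - 1) * Tn + s
    V[r, c] <- tau$sigma1_sq * O1[i, j] +
      (i == j) * tau$sigma2_sq * O2[t, s] +
      (i == j && t == s) * D[i, t]
  }
  V
}

# dense-formula restricted likelihood with explicit inverses/determinants
reml_oracle <- function(tau, panel, W = NULL) {
  V <- naive_full_covariance(tau, W, panel$D)
  X <- panel$X
  y <- as.vector(t(panel$y))
  n <- length(y); p <- ncol(X)
  Vi <- solve(V)
  M <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(M) %*% t(X) %*% Vi
  ld_V <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
  ld_M <- as.numeric(determinant(M, logarithm = TRUE)$modulus)
  -0.5 * ((n - p) * log(2 * pi) + ld_V + ld_M +
            drop(t(y) %*% P %*% y))
}

# classical scalar Fay-Herriot shrinkage at known (sigma2, beta)
fh_shrink_oracle <- function(y, d, xb, sigma2) {
  g <- sigma2 / (sigma2 + d)
  g * y + (1 - g) * xb
}

# quick low-level panel with arbitrary (non-model) numbers
make_test_panel <- function(m, Tn, p = 2, seed = 1) {
  set.seed(seed)
  X <- cbind(1, matrix(rnorm(m * Tn * (p - 1)), m * Tn, p - 1))
  colnames(X) <- c("intercept", if (p > 1) paste0("x", seq_len(p - 1)))
  area_panel(sprintf("Z%02d", 1:m), seq_len(Tn),
             y = matrix(rnorm(m * Tn), m, Tn),
             D = matrix(runif(m * Tn, 0.3, 1.5), m, Tn),
             X = X)
}

chain_W <- function(m) make_proximity("chain", m = m)

# canonical simulation scenarios used across test files
scenario_recovery <- function(seed, m = 60) {
  simulation_scenario(m = m, T = 4, p = 2,
                      tau = variance_components(0.5, 0.8, 0.25, -0.6),
                      beta = c(3, 1), seed = seed)
}

scenario_weak_signal <- function(seed, m = 60) {
  simulation_scenario(m = m, T = 4, p = 2,
                      tau = variance_components(0.001, 0.95, 0.01, -0.6),
                      beta = c(3, 1), seed = seed)
}
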