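make_fh_fit <- function(panel, ...) fit_model(panel, model = "fh", ...)

test_that("EBLUP limiting behaviour: zero shrinkage and zero sampling variance", {
  sim <- simulate_panel(scenario_weak_signal(seed = 21, m = 20))
  panel <- sim$panel
  # all variance components zero -> pure synthetic estimator X beta_hat
  fit0 <- fit_model(panel, sim$W, "stfh",
                    fixed = list(sigma1_sq = 0, rho1 = 0, rho2 = 0))
  fit0$tau_hat$sigma2_sq <- 0
  pr0 <- eblup(fit0, panel, sim$W)
  xb <- drop(panel$X %*% fit0$beta_hat)
  expect_equal(pr0$eblup, xb, tolerance = 1e-10)
  # a near-zero sampling variance pins the EBLUP to the direct estimate
  fit <- fit_model(panel, sim$W, "stfh")
  panel2 <- panel
  panel2$D[3, 2] <- 1e-10
  pr <- eblup(fit, panel2, sim$W)
  cell <- (3 - 1) * panel$T + 2
  expect_equal(pr$eblup[cell], pr$direct[cell], tolerance = 1e-6)
})

test_that("FH EBLUP equals the classical closed form (independent oracle)", {
  sim <- simulate_panel(scenario_weak_signal(seed = 23, m = 30))
  p1 <- panel_slice(sim$panel, sim$panel$T, index = TRUE)
  fit <- make_fh_fit(p1)
  pr <- eblup(fit, p1)
  oracle <- fh_shrink_oracle(pr$direct, unname(p1$D[, 1]),
                             drop(p1$X %*% fit$beta_hat),
                             fit$tau_hat$sigma2_sq)
  expect_equal(pr$eblup, unname(oracle), tolerance = 1e-10)
})

test_that("analytic FH MSE components have the stated structure", {
  sim <- simulate_panel(scenario_weak_signal(seed = 29, m = 30))
  p1 <- panel_slice(sim$panel, sim$panel$T, index = TRUE)
  fit <- make_fh_fit(p1)
  pr <- mse_analytic_fh(fit, p1)
  s2 <- fit$tau_hat$sigma2_sq
  gamma <- s2 / (s2 + p1$D[, 1])
  expect_equal(pr$g1, unname(gamma * p1$D[, 1]), tolerance = 1e-12)
  expect_equal(pr$mse, pr$g1 + pr$g2 + 2 * pr$g3, tolerance = 1e-12)
  expect_true(all(pr$g1 >= 0 & pr$g2 >= 0 & pr$g3 >= 0))
  expect_equal(pr$root_mse, sqrt(pr$mse))
  # sigma^2 = 0 boundary: g1 vanishes
  fit0 <- fit
  fit0$tau_hat$sigma2_sq <- 0
  pr0 <- mse_analytic_fh(fit0, p1)
  expect_equal(pr0$g1, rep(0, p1$m))
  expect_equal(pr0$mse, pr0$g2 + 2 * pr0$g3, tolerance = 1e-12)
  # exchangeability: equal variances + intercept-only X -> identical g1
  m <- 12
  pan <- area_panel(paste0("A", 1:m), 1,
                    matrix(rnorm(m, 1), m, 1), matrix(0.5, m, 1),
                    matrix(1, m, 1, dimnames = list(NULL, "intercept")))
  fe <- make_fh_fit(pan)
  pe <- mse_analytic_fh(fe, pan)
  expect_equal(diff(range(pe$g1)), 0, tolerance = 1e-12)
  expect_equal(diff(range(pe$g2)), 0, tolerance = 1e-12)
  # wrong model tag is redirected to the bootstrap
  sfit <- fit_model(p1, sim$W, "sfh")
  expect_error(mse_analytic_fh(sfit, p1), regexp = "bootstrap",
               class = "stfh_model_error")
})

test_that("g2 shrinks as the number of areas grows", {
  mean_g2 <- vapply(c(20, 60, 140), function(m) {
    sim <- simulate_panel(scenario_weak_signal(seed = 101, m = m))
    p1 <- panel_slice(sim$panel, 4, index = TRUE)
    mean(mse_analytic_fh(make_fh_fit(p1), p1)$g2)
  }, 0)
  expect_true(all(diff(mean_g2) < 0))
})

test_that("analytic FH MSE tracks the empirical MSE of the EBLUP", {
  # Monte-Carlo oracle: repeated data from a known FH world, m = 40
  sc <- simulation_scenario(m = 40, T = 1, p = 2,
                            tau = variance_components(0, 0, 0.02, 0),
                            beta = c(3, 1), seed = 71)
  base <- simulate_panel(sc)
  frame <- sc
  frame$graph <- list(kind = "supplied"); frame$W <- base$W
  frame$X_spec <- list(kind = "supplied"); frame$X <- base$panel$X
  frame$D_spec <- list(kind = "supplied"); frame$D <- base$panel$D
  nrep <- 300
  sq <- 0; amse <- 0
  for (r in seq_len(nrep)) {
    frame$seed <- 71000 + r
    sim <- simulate_panel(frame)
    fit <- make_fh_fit(sim$panel)
    pr <- mse_analytic_fh(fit, sim$panel)
    sq <- sq + (pr$eblup - sim$truth$theta[, 1])^2
    amse <- amse + pr$mse
  }
  expect_lt(abs(mean(amse / nrep) / mean(sq / nrep) - 1), 0.15)
})

test_that("bootstrap MSE is deterministic in the seed", {
  sim <- simulate_panel(scenario_weak_signal(seed = 37, m = 15))
  p1 <- panel_slice(sim$panel, 4, index = TRUE)
  fit <- fit_model(p1, sim$W, "sfh")
  b1 <- mse_bootstrap(fit, p1, sim$W, B = 30, seed = 7)
  b2 <- mse_bootstrap(fit, p1, sim$W, B = 30, seed = 7)
  expect_identical(b1$mse, b2$mse)
  b3 <- mse_bootstrap(fit, p1, sim$W, B = 30, seed = 8)
  expect_false(identical(b1$mse, b3$mse))
  expect_error(mse_bootstrap(fit, p1, sim$W, B = 0, seed = 1),
               class = "stfh_bootstrap_error")
})

test_that("FH bootstrap (fixed tau) agrees with analytic g1 + g2", {
  sim <- simulate_panel(scenario_weak_signal(seed = 41, m = 30))
  p1 <- panel_slice(sim$panel, 4, index = TRUE)
  fit <- make_fh_fit(p1)
  pr_a <- mse_analytic_fh(fit, p1)
  pr_b <- mse_bootstrap(fit, p1, NULL, B = 500, seed = 99, refit = FALSE)
  # with tau held fixed the bootstrap targets g1 + g2 only
  rel <- pr_b$mse / (pr_a$g1 + pr_a$g2)
  expect_true(all(rel > 0.8 & rel < 1.2))
})

test_that("bootstrap output is equivariant under area relabelling", {
  sim <- simulate_panel(scenario_weak_signal(seed = 43, m = 12))
  panel <- sim$panel; W <- sim$W
  fit <- fit_model(panel, W, "stfh")
  b <- mse_bootstrap(fit, panel, W, B = 10, seed = 3, refit = FALSE)
  # permute areas everywhere, keeping ids attached
  set.seed(1); perm <- sample(panel$m)
  rows <- as.vector(t(outer((perm - 1) * panel$T, seq_len(panel$T), "+")))
  panel_p <- area_panel(panel$area_ids[perm], panel$time_ids,
                        panel$y[perm, ], panel$D[perm, ],
                        panel$X[rows, , drop = FALSE])
  W_p <- proximity_matrix(attr(W, "adjacency")[perm, perm],
                          attr(W, "area_ids")[perm])
  fit_p <- fit
  fit_p$beta_hat <- fit$beta_hat  # same fitted parameters, relabelled data
  b_p <- mse_bootstrap(fit_p, panel_p, W_p, B = 10, seed = 3, refit = FALSE)
  mse_mat <- matrix(b$mse, panel$m, panel$T, byrow = TRUE)
  mse_mat_p <- matrix(b_p$mse, panel$m, panel$T, byrow = TRUE)
  expect_equal(mse_mat_p, mse_mat[perm, ], tolerance = 1e-9)
})
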