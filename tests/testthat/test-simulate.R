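test_that("make_proximity: chain, grid, determinism, connectivity", {
  W3 <- make_proximity("chain", m = 3)
  expect_equal(unname(rowSums(unclass(as.matrix(W3)))), rep(1, 3))
  expect_equal(unclass(as.matrix(W3))[2, ], c(0.5, 0, 0.5),
               ignore_attr = TRUE)
  G <- make_proximity("grid", dims = c(2, 2))
  A <- attr(G, "adjacency")
  expect_equal(rowSums(A > 0), rep(2, 4))
  expect_true(all(unclass(as.matrix(G))[A > 0] == 0.5))
  Wa <- make_proximity("random_planar", m = 30, k = 3, seed = 1)
  Wb <- make_proximity("random_planar", m = 30, k = 3, seed = 1)
  expect_identical(unclass(as.matrix(Wa)), unclass(as.matrix(Wb)))
  for (s in 1:5) {
    Ws <- make_proximity("random_planar", m = 20, k = 2, seed = s)
    expect_equal(unname(rowSums(unclass(as.matrix(Ws)))), rep(1, 20))
    expect_equal(max(stfh:::graph_components(attr(Ws, "adjacency"))), 1)
  }
  expect_error(make_proximity("random_planar", m = 5, k = 6),
               class = "stfh_validation_error")
})

test_that("simulate_panel is a pure function of the scenario", {
  sc <- scenario_recovery(seed = 77, m = 12)
  a <- simulate_panel(sc)
  b <- simulate_panel(sc)
  expect_identical(a$panel$y, b$panel$y)
  expect_identical(a$truth$nu2, b$truth$nu2)
  sc2 <- sc; sc2$seed <- 78L
  expect_false(identical(simulate_panel(sc2)$panel$y, a$panel$y))
})

test_that("the simulated decomposition reconstructs y exactly and the AR recursion holds", {
  sim <- simulate_panel(scenario_recovery(seed = 79, m = 10))
  tr <- sim$truth
  expect_equal(sim$panel$y,
               matrix(drop(sim$panel$X %*% tr$beta), 10, 4, byrow = TRUE) +
                 tr$nu1 + tr$nu2 + tr$eps,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(tr$theta + tr$eps, sim$panel$y, ignore_attr = TRUE)
  # nu2 rows follow the AR(1) recursion given their innovations
  rho2 <- tr$tau$rho2
  innov <- tr$nu2[, -1] - rho2 * tr$nu2[, -4]
  expect_equal(sd(as.vector(innov)), sqrt(tr$tau$sigma2_sq),
               tolerance = 0.35)
})

test_that("component sub-streams are independent: toggling one leaves others unchanged", {
  sc <- scenario_recovery(seed = 81, m = 8)
  sim <- simulate_panel(sc)
  sc0 <- sc
  sc0$tau <- variance_components(0, 0, sc$tau$sigma2_sq, sc$tau$rho2)
  sim0 <- simulate_panel(sc0)
  expect_identical(sim0$truth$nu2, sim$truth$nu2)
  expect_identical(sim0$truth$eps, sim$truth$eps)
  expect_identical(sim0$truth$nu1, rep(0, 8))
})

test_that("nu2 Monte-Carlo covariance matches sigma2^2 * Omega2", {
  sc <- simulation_scenario(m = 4, T = 4, p = 2,
                            tau = variance_components(0, 0, 0.25, -0.6),
                            beta = c(0, 0), seed = 1)
  base <- simulate_panel(sc)
  frame <- sc
  frame$graph <- list(kind = "supplied"); frame$W <- base$W
  frame$X_spec <- list(kind = "supplied"); frame$X <- base$panel$X
  frame$D_spec <- list(kind = "supplied"); frame$D <- base$panel$D
  nrep <- 4000
  acc <- matrix(0, nrep * 4, 4)
  for (r in seq_len(nrep)) {
    frame$seed <- r
    acc[(r - 1) * 4 + 1:4, ] <- simulate_panel(frame)$truth$nu2
  }
  emp <- cov(acc)
  target <- 0.25 * build_omega2(-0.6, 4)
  se <- sqrt((outer(diag(target), diag(target)) + target^2) / nrow(acc))
  expect_lt(max(abs(emp - target) / se), 4)
})

test_that("generated panels satisfy var(y) = V(tau) empirically (m=4, T=3)", {
  sc <- simulation_scenario(m = 4, T = 3, p = 2,
                            tau = variance_components(0.4, 0.6, 0.3, -0.5),
                            beta = c(1, 0.5),
                            D_spec = list(kind = "constant", value = 0.3),
                            seed = 5)
  base <- simulate_panel(sc)
  frame <- sc
  frame$graph <- list(kind = "supplied"); frame$W <- base$W
  frame$X_spec <- list(kind = "supplied"); frame$X <- base$panel$X
  frame$D_spec <- list(kind = "supplied"); frame$D <- base$panel$D
  nrep <- 4000
  Y <- matrix(0, nrep, 12)
  for (r in seq_len(nrep)) {
    frame$seed <- 100000 + r
    Y[r, ] <- as.vector(t(simulate_panel(frame)$panel$y))
  }
  emp <- cov(Y)
  target <- build_full_covariance(sc$tau, base$W, base$panel$D)$V
  se <- sqrt((outer(diag(target), diag(target)) + target^2) / nrep)
  expect_lt(max(abs(emp - target) / se), 4.5)  # 78 distinct entries
})

test_that("zero-variance tau leaves only sampling noise", {
  sc <- simulation_scenario(m = 50, T = 2, p = 1,
                            tau = variance_components(),
                            beta = 0,
                            D_spec = list(kind = "constant", value = 0.04),
                            seed = 9)
  sim <- simulate_panel(sc)
  expect_equal(sim$truth$theta, matrix(0, 50, 2), ignore_attr = TRUE)
  expect_equal(var(as.vector(sim$panel$y)), 0.04, tolerance = 0.35)
})

test_that("recovery_experiment returns a one-replicate table without error", {
  sc <- scenario_weak_signal(seed = 91, m = 15)
  res <- recovery_experiment(sc, n_reps = 1, seed = 4, models = "stfh")
  expect_s3_class(res, "stfh_recovery")
  expect_true(all(c("quantity", "model", "value") %in% names(res$summary)))
  expect_true("emp_mse_final" %in% res$summary$quantity)
  expect_equal(nrow(res$tau_hat), 1)
})
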