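# A minimal hand-built fit object: intercept-only model with known tau, so
# ks_normality's standardized residuals are exactly the y draws.
fake_fit <- function(beta = 0) {
  structure(list(model = "FH", beta_hat = beta, converged = TRUE,
                 tau_hat = variance_components(), free = "sigma2_sq",
                 fixed = list()), class = "stfh_fit")
}
unit_panel <- function(y) {
  m <- length(y)
  area_panel(sprintf("A%03d", seq_len(m)), 1, matrix(y, m, 1),
             matrix(1, m, 1), matrix(1, m, 1,
                                     dimnames = list(NULL, "intercept")))
}

test_that("information criteria identities", {
  fit <- fake_fit()
  fit$loglik <- -50; fit$n_params <- 5; fit$n <- 100
  ic <- information_criteria(fit)
  expect_equal(ic$minus2LL, 100)
  expect_equal(ic$AIC, 110)
  expect_equal(ic$BIC, 100 + 5 * log(100), tolerance = 1e-10)
  fit$n_params <- 0
  ic0 <- information_criteria(fit)
  expect_equal(ic0$AIC, ic0$minus2LL)
  expect_equal(ic0$BIC, ic0$minus2LL)
})

test_that("information criteria hold exactly for fitted models", {
  sim <- simulate_panel(scenario_weak_signal(seed = 61, m = 25))
  for (spec in list(list("fh", NULL), list("sfh", sim$W),
                    list("stfh", sim$W))) {
    fit <- fit_model(sim$panel, spec[[2]], spec[[1]])
    ic <- information_criteria(fit)
    expect_equal(ic$minus2LL, -2 * fit$loglik)
    expect_equal(ic$AIC, ic$minus2LL + 2 * fit$n_params)
    expect_equal(ic$BIC, ic$minus2LL + fit$n_params * log(100))
  }
})

test_that("STFH is preferred by AIC over stacked SFH when rho2 != 0", {
  wins <- 0L; nrep <- 20L
  for (r in seq_len(nrep)) {
    sc <- scenario_recovery(seed = 6000 + r, m = 30)
    sim <- simulate_panel(sc)
    a_stfh <- information_criteria(fit_model(sim$panel, sim$W, "stfh"))$AIC
    a_sfh <- information_criteria(fit_model(sim$panel, sim$W, "sfh"))$AIC
    wins <- wins + (a_stfh < a_sfh)
  }
  expect_gt(wins, nrep / 2)
})

test_that("KS normality check: calibration, power, degenerate case", {
  n <- 332
  pvals_null <- pvals_shift <- numeric(100)
  for (r in 1:100) {
    set.seed(r)
    pvals_null[r] <- ks_normality(fake_fit(), unit_panel(rnorm(n)))$p_value
    pvals_shift[r] <- ks_normality(fake_fit(),
                                   unit_panel(rnorm(n, mean = 2)))$p_value
  }
  expect_gte(mean(pvals_null > 0.05), 0.90)
  expect_gte(mean(pvals_shift < 0.05), 0.99)
  # constant residuals: maximal sup-distance against the normal CDF
  kc <- ks_normality(fake_fit(), unit_panel(rep(1.5, 20)))
  expect_equal(kc$statistic, pnorm(1.5), tolerance = 1e-6)
  expect_error(ks_normality(fake_fit(), unit_panel(rnorm(4))),
               class = "stfh_samplesize_error")
})

test_that("bias diagnostic recovers exact linear relations", {
  x <- c(1, 2, 3.5, 4, 7)
  expect_equal(bias_diagnostic(x, x),
               list(slope = 1, intercept = 0, r_squared = 1),
               tolerance = 1e-12)
  expect_equal(bias_diagnostic(2 * x + 3, x),
               list(slope = 2, intercept = 3, r_squared = 1),
               tolerance = 1e-12)
  expect_error(bias_diagnostic(x, rep(1, 5)),
               class = "stfh_degenerate_error")
  expect_error(bias_diagnostic(x, x[1:3]), class = "stfh_validation_error")
})

test_that("cv_percent arithmetic and the unstable flag", {
  expect_equal(as.numeric(cv_percent(2, 0.04)), 10)
  expect_equal(as.numeric(cv_percent(-2, 0.04)), 10)
  expect_equal(as.numeric(cv_percent(5, 0)), 0)
  v <- cv_percent(c(2, 1e-12), c(0.04, 0.04))
  expect_true(is.na(v[2]))
  expect_identical(attr(v, "unstable"), c(FALSE, TRUE))
  expect_error(cv_percent(1, -0.1), class = "stfh_validation_error")
})

test_that("efficiency gain formula, antisymmetry at zero, order invariance", {
  expect_equal(efficiency_gain(20, 10)$gain, 50)
  expect_equal(efficiency_gain(20, 25)$gain, -25)
  z <- efficiency_gain(c(5, 10, 20), c(5, 10, 20))
  expect_equal(z$gain, c(0, 0, 0))
  expect_equal(unname(z$summary), rep(0, 6))
  set.seed(8)
  a <- runif(30, 5, 40); b <- runif(30, 2, 50)
  g <- efficiency_gain(a, b)
  expect_true(all(g$gain <= 100))
  expect_true(any(g$gain < 0))
  s1 <- g$summary
  perm <- sample(30)
  s2 <- efficiency_gain(a[perm], b[perm])$summary
  expect_equal(s1, s2)
  expect_true(all(diff(s1[c("Min", "Q1", "Median", "Q3", "Max")]) >= 0))
  expect_error(efficiency_gain(c(1, 0), c(1, 1)),
               class = "stfh_validation_error")
})

test_that("diagnostics_report assembles the battery for multiple models", {
  sim <- simulate_panel(scenario_weak_signal(seed = 67, m = 25))
  fits <- list(SFH = fit_model(sim$panel, sim$W, "sfh"),
               STFH = fit_model(sim$panel, sim$W, "stfh"))
  rep_ <- diagnostics_report(fits, sim$panel, sim$W)
  expect_equal(rep_$ic$model, c("SFH", "STFH"))
  expect_equal(rep_$ic$AIC, rep_$ic$minus2LL + 2 * rep_$ic$k)
  expect_true(all(vapply(rep_$ks, function(k) k$p_value, 0) >= 0))
  out <- capture.output(print(rep_))
  expect_true(any(grepl("information criteria", out)))
})
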