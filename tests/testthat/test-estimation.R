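test_that("design factor and variance imputation follow their formulas", {
  d <- meta_dataset(c("a", "b"), c(50, 100), c(50, 100),
                    y = c(0.2, 0.1), se = sqrt(c(0.04, 0.02)))
  expect_equal(design_factor(d), (25 + 50) / 300)
  single <- meta_dataset("a", 5, 5, 0.1, sqrt(0.5))
  expect_equal(design_factor(single), 2 / 10)
  # homogeneous design: k recovered exactly and imputation is consistent
  cc <- 0.7
  n_tot <- c(60, 100, 150)
  dh <- meta_dataset(letters[1:3], n_tot / 2, n_tot / 2,
                     y = c(0.1, 0.2, 0.3), se = sqrt(1 / (cc * n_tot)))
  expect_equal(design_factor(dh), cc)
  expect_equal(impute_variance(100, design_factor(dh)), 1 / (cc * 100))
  expect_equal(impute_variance(100, 0.25), 0.04)
  expect_equal(impute_variance(50, 2), 0.01)
  expect_error(impute_variance(0, 1), class = "orbsel_error_config")
  expect_error(design_factor(make_dataset(4, 4, 1)[FALSE, ]),
               class = "orbsel_error_config")
})

test_that("single-study fit with known variance reproduces the normal MLE and Wald CI", {
  d <- meta_dataset("a", 50, 50, 0.5, 0.2)
  fit <- orb_fit(d, "naive", tau2 = 0)
  expect_equal(fit$mu_hat, 0.5, tolerance = 1e-7)
  expect_equal(fit$ci_mu, 0.5 + c(-1, 1) * qnorm(0.975) * 0.2,
               tolerance = 1e-6)
  d0 <- meta_dataset("a", 50, 50, 0, 1)
  fit0 <- orb_fit(d0, "naive", tau2 = 0)
  expect_equal(fit0$ci_mu, c(-1, 1) * qnorm(0.975), tolerance = 1e-6)
})

test_that("naive ML estimates agree with metafor's", {
  skip_if_not_installed("metafor")
  for (seed in c(2, 9, 31)) {
    d <- make_dataset(K = 12, n_unrep = 0, seed = seed)
    fit <- orb_fit(d, "naive", ci = FALSE)
    mf <- metafor::rma(yi = d$y, sei = d$se, method = "ML")
    expect_equal(fit$mu_hat, as.numeric(mf$beta), tolerance = 1e-4)
    expect_equal(fit$tau2_hat, mf$tau2, tolerance = 1e-4)
    expect_equal(fit$loglik, as.numeric(stats::logLik(mf)), tolerance = 1e-6)
  }
})

test_that("location invariance: shifting all effects shifts mu_hat only", {
  d <- make_dataset(K = 9, n_unrep = 0, seed = 13)
  fit <- orb_fit(d, "naive", ci = FALSE)
  d_shift <- d
  d_shift$y <- d$y + 0.7
  fit_s <- orb_fit(d_shift, "naive", ci = FALSE)
  expect_equal(fit_s$mu_hat, fit$mu_hat + 0.7, tolerance = 1e-6)
  expect_equal(fit_s$tau2_hat, fit$tau2_hat, tolerance = 1e-6)
})

test_that("homogeneous data put tau2 on the boundary with a zero lower CI", {
  set.seed(5)
  K <- 10
  d <- meta_dataset(sprintf("s%d", 1:K), rep(50, K), rep(50, K),
                    y = rnorm(K, 0.2, 0.02), se = rep(0.3, K))
  fit <- orb_fit(d, "naive")
  expect_equal(fit$tau2_hat, 0)
  expect_true(fit$diagnostics$boundary)
  expect_equal(fit$ci_tau2[1], 0)
})

test_that("adjusted fit with no unreported studies equals the naive fit", {
  d <- make_dataset(K = 7, n_unrep = 0, seed = 21)
  w <- selection_function("wB", beta = 3)
  naive <- orb_fit(d, "naive", ci = FALSE)
  adj <- orb_fit(d, "adjusted", selection = w, ci = FALSE)
  expect_equal(adj$mu_hat, naive$mu_hat, tolerance = 1e-8)
  expect_equal(adj$tau2_hat, naive$tau2_hat, tolerance = 1e-8)
})

test_that("profile CI endpoints sit at the chi-square likelihood drop", {
  d <- make_dataset(K = 10, n_unrep = 0, seed = 17)
  fit <- orb_fit(d, "naive")
  drop_target <- qchisq(0.95, 1) / 2 # 1.9207294
  prof_mu <- function(m) {
    opt <- optimize(function(t2) fit$loglik_fn(m, t2), c(0, 10),
                    maximum = TRUE, tol = 1e-10)
    max(opt$objective, fit$loglik_fn(m, 0))
  }
  for (end in fit$ci_mu) {
    expect_equal(fit$loglik - prof_mu(end), drop_target, tolerance = 1e-6)
  }
  # tau2 upper endpoint (lower may be boundary-clamped at 0)
  prof_t2 <- function(t2) {
    optimize(function(m) fit$loglik_fn(m, t2),
             fit$mu_hat + c(-3, 3), maximum = TRUE, tol = 1e-10)$objective
  }
  expect_equal(fit$loglik - prof_t2(fit$ci_tau2[2]), drop_target,
               tolerance = 1e-6)
  expect_true(fit$ci_mu[1] <= fit$mu_hat && fit$mu_hat <= fit$ci_mu[2])
})

test_that("adjustment moves beneficial-outcome estimates towards the null", {
  d <- epilepsy_dataset("seizure_freedom")
  naive <- orb_fit(d, "naive", ci = FALSE)
  for (w in list(selection_function("wA"),
                 selection_function("wB", beta = 3),
                 selection_function("wDGM", gamma = 1.5))) {
    adj <- orb_fit(d, "adjusted", selection = w, ci = FALSE)
    expect_lte(adj$mu_hat, naive$mu_hat)
  }
  # and on simulated MNAR data
  set.seed(88)
  cfg <- scenario_config(K = 15, mu = 0.2, I2 = 0.5, n_sim = 1, seed = 88)
  obs <- apply_orb(simulate_complete(cfg), 1.5)
  while (sum(obs$reported) < 2 || all(obs$reported)) {
    obs <- apply_orb(simulate_complete(cfg), 1.5)
  }
  adj <- orb_fit(obs, "adjusted", selection_function("wDGM", gamma = 1.5),
                 ci = FALSE)
  naive_s <- orb_fit(obs, "naive", ci = FALSE)
  expect_lte(adj$mu_hat, naive_s$mu_hat)
})

test_that("fit interface guards its preconditions", {
  d <- make_dataset(K = 6, n_unrep = 2, seed = 3)
  expect_error(orb_fit(d, "adjusted"), class = "orbsel_error_config")
  expect_error(orb_fit(d, "complete"), class = "orbsel_error_config")
  one_rep <- make_dataset(K = 3, n_unrep = 2, seed = 4)
  one_rep$y[2] <- NA
  expect_error(
    orb_fit(meta_dataset("a", 50, 50, 0.1, 0.2), "naive"),
    class = "orbsel_error_validation"
  )
})

test_that("tidy and glance summarise fits in broom style", {
  d <- epilepsy_dataset("seizure_freedom")
  fit <- orb_fit(d, "adjusted", selection_function("wA"))
  td <- tidy(fit, exponentiate = TRUE)
  expect_identical(td$term, c("mu", "tau2", "rr"))
  expect_equal(td$estimate[td$term == "rr"], exp(fit$mu_hat))
  expect_true(all(td$conf.low <= td$estimate | is.na(td$conf.low)))
  gl <- glance(fit)
  expect_equal(gl$n_unreported, 6L)
  expect_identical(gl$selection, "wA")
  expect_true(gl$converged)
})
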