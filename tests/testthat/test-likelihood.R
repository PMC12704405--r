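test_that("marginal density is the N(mu, se^2 + tau2) law", {
  expect_equal(marginal_density(0, 0, 0, 1), dnorm(0))
  expect_equal(marginal_density(2, 0, 3, 1), dnorm(2, 0, 2))
  mu <- 0.4
  ys <- seq(-2, 2, by = 0.1)
  dens <- marginal_density(ys, mu, 0.3, 0.5)
  expect_equal(ys[which.max(dens)], mu) # mode at mu
  expect_error(marginal_density(0, 0, -0.1, 1), class = "orbsel_error_config")
})

test_that("naive log-likelihood includes the full normal constant and is additive", {
  one <- meta_dataset("a", 50, 50, 0, 1)
  expect_equal(naive_loglik(one, 0, 0), -0.5 * log(2 * pi))
  two <- meta_dataset(c("a", "b"), c(50, 50), c(50, 50), c(0, 0), c(1, 1))
  expect_equal(naive_loglik(two, 0, 0), 2 * naive_loglik(one, 0, 0))
  # maximised at the inverse-variance-weighted mean when tau2 = 0
  d <- make_dataset(K = 6, n_unrep = 0, seed = 3)
  w_iv <- 1 / d$se^2
  mu_ivw <- sum(w_iv * d$y) / sum(w_iv)
  expect_gt(naive_loglik(d, mu_ivw, 0), naive_loglik(d, mu_ivw + 0.01, 0))
  expect_gt(naive_loglik(d, mu_ivw, 0), naive_loglik(d, mu_ivw - 0.01, 0))
  expect_error(naive_loglik(d[0, ], 0, 0), class = "orbsel_error_config")
})

test_that("threshold-selection contributions match their closed forms", {
  wA <- selection_function("wA")
  expect_equal(
    unreported_contribution(1, 0, 0, wA),
    log(pnorm(qnorm(0.95))),
    tolerance = 1e-12
  )
  expect_equal(
    exp(reported_normalizer(1, 0, 0, wA)), 0.05,
    tolerance = 1e-9
  )
  # quadrature agrees with the closed form on a random grid, both p scales
  set.seed(101)
  for (i in 1:50) {
    mu <- runif(1, -1.5, 1.5)
    tau2 <- runif(1, 0, 0.5)
    se <- runif(1, 0.2, 2)
    for (ps in c("one_sided", "two_sided")) {
      cf <- unreported_contribution(se, mu, tau2, wA, p_scale = ps,
                                    method = "closed_form")
      qd <- unreported_contribution(se, mu, tau2, wA, p_scale = ps,
                                    method = "quadrature")
      expect_equal(exp(qd), exp(cf), tolerance = 1e-9)
    }
  }
  # two-sided closed form is the Copas expression
  mu <- 0.3; tau2 <- 0.2; se <- 0.8
  za <- qnorm(1 - 0.05 / 2)
  s <- sqrt(se^2 + tau2)
  expect_equal(
    exp(unreported_contribution(se, mu, tau2, wA, p_scale = "two_sided")),
    pnorm((za * se - mu) / s) - pnorm((-za * se - mu) / s),
    tolerance = 1e-12
  )
})

test_that("adaptive quadrature agrees with a dense trapezoid oracle", {
  set.seed(202)
  for (i in 1:25) {
    w <- random_selection(i + 500)
    mu <- runif(1, -1, 1)
    tau2 <- runif(1, 0, 0.4)
    se <- runif(1, 0.2, 1.5)
    qd <- exp(unreported_contribution(se, mu, tau2, w, method = "quadrature"))
    oracle <- oracle_weighted_integral(se, mu, tau2, w, side = "complement")
    expect_lt(abs(qd - oracle), 1e-6, label = paste("diff for", format(w)))
  }
})

test_that("reporting and non-reporting probabilities are complementary", {
  set.seed(303)
  for (i in 1:20) {
    w <- random_selection(i + 900)
    mu <- runif(1, -1, 1)
    tau2 <- runif(1, 0, 0.4)
    se <- runif(1, 0.2, 1.5)
    a <- exp(unreported_contribution(se, mu, tau2, w, method = "quadrature"))
    b <- exp(reported_normalizer(se, mu, tau2, w, method = "quadrature"))
    expect_equal(a + b, 1, tolerance = 1e-8, info = format(w))
  }
  # w identically 1: nothing can be unreported
  expect_equal(reported_normalizer(1, 0, 0.1, selection_function("none")), 0)
  u <- unreported_contribution(1, 0, 0.1, selection_function("none"))
  expect_identical(as.numeric(u), -Inf)
  expect_identical(attr(u, "orbsel_flag"), "zero_integral")
})

test_that("non-reporting becomes less likely as the true effect grows", {
  mus <- seq(-0.5, 1.5, by = 0.25)
  for (fam in list(
    selection_function("wA"),
    selection_function("wB", beta = 3),
    selection_function("wC", gamma = 3),
    selection_function("wD", beta = 2, gamma = 2),
    selection_function("wDGM", gamma = 1.5)
  )) {
    contribs <- vapply(
      mus, function(m) unreported_contribution(0.5, m, 0.1, fam), numeric(1)
    )
    expect_true(all(diff(contribs) < 0), info = format(fam))
  }
})

test_that("adjusted log-likelihood assembles the right terms", {
  # no unreported studies: identical to the naive log-likelihood
  d0 <- make_dataset(K = 6, n_unrep = 0, seed = 5)
  wA <- selection_function("wA")
  expect_identical(orb_loglik(d0, 0.3, 0.1, wA), naive_loglik(d0, 0.3, 0.1))

  # epilepsy seizure freedom: naive part plus one term per unreported study
  d <- epilepsy_dataset("seizure_freedom")
  parts <- partition_reported(d)
  k_hat <- design_factor(parts$reported)
  se_imp <- sqrt(impute_variance(
    parts$unreported$n_treat + parts$unreported$n_ctrl, k_hat
  ))
  manual <- naive_loglik(parts$reported, 0.5, 0.05) +
    sum(vapply(se_imp, unreported_contribution, numeric(1),
               mu = 0.5, tau2 = 0.05, w = wA))
  expect_equal(orb_loglik(d, 0.5, 0.05, wA), manual, tolerance = 1e-12)
  expect_equal(nrow(parts$unreported), 6)

  # explicit imputation map is honoured, missing entries are an error
  named <- setNames(se_imp, parts$unreported$study_id)
  expect_equal(orb_loglik(d, 0.5, 0.05, wA, se_imputed = named), manual)
  expect_error(
    orb_loglik(d, 0.5, 0.05, wA, se_imputed = named[-1]),
    class = "orbsel_error_config"
  )

  # generic variant subtracts the reported normalisers
  wB <- selection_function("wB", beta = 3)
  base <- orb_loglik(d, 0.5, 0.05, wB)
  generic <- orb_loglik(d, 0.5, 0.05, wB, reported_selection = TRUE)
  norms <- sum(vapply(parts$reported$se, reported_normalizer, numeric(1),
                      mu = 0.5, tau2 = 0.05, w = wB))
  expect_equal(generic, base - norms, tolerance = 1e-10)
  expect_gte(generic, base) # normalisers are log-probabilities (<= 0)
})

test_that("adjusted likelihood matches a dense-grid oracle on simulated data", {
  set.seed(77)
  cfg <- scenario_config(K = 5, mu = 0.4, I2 = 0.25, n_sim = 1, seed = 77)
  d <- apply_orb(simulate_complete(cfg), 1.5)
  while (sum(d$reported) < 2 || all(d$reported)) {
    d <- apply_orb(simulate_complete(cfg), 1.5)
  }
  w <- selection_function("wDGM", gamma = 1.5)
  parts <- partition_reported(d)
  k_hat <- design_factor(parts$reported)
  se_imp <- sqrt(impute_variance(
    parts$unreported$n_treat + parts$unreported$n_ctrl, k_hat
  ))
  oracle <- naive_loglik(parts$reported, 0.4, 0.02) +
    sum(vapply(
      se_imp,
      function(s) log(oracle_weighted_integral(s, 0.4, 0.02, w)),
      numeric(1)
    ))
  expect_equal(orb_loglik(d, 0.4, 0.02, w), oracle, tolerance = 1e-6)
})
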