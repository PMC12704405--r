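#' Heterogeneity variance implied by I-squared
#'
#' I2 is the share of total variance due to between-study heterogeneity
#' relative to a typical within-study variance: tau2 = I2 * sigma2 / (1 - I2).
#'
#' @param I2 Heterogeneity proportion in \[0, 1).
#' @param sigma2_typical Typical within-study variance (default 2/n with
#'   n = 50 per arm).
#' @return tau2 >= 0.
#' @export
tau2_from_I2 <- function(I2, sigma2_typical = 2 / 50) {
  if (any(I2 < 0 | I2 >= 1)) abort_config("I2 must lie in [0, 1)")
  if (sigma2_typical <= 0) abort_config("sigma2_typical must be positive")
  I2 * sigma2_typical / (1 - I2)
}

#' Define a simulation scenario
#'
#' One cell of the simulation grid: a random-effects meta-analysis of K
#' two-arm studies (n per arm), pooled effect mu and heterogeneity given by
#' I2, with selective reporting driven by the exponential selection law
#' exp(-4 p^gamma) (MNAR) or by random removal of the same number of studies
#' (MCAR benchmark).
#'
#' @param K Number of studies.
#' @param mu True pooled effect.
#' @param I2 Heterogeneity proportion in \[0, 1).
#' @param n_per_arm Per-arm sample size (default 50).
#' @param dgm_gamma Exponent of the reporting law (1.5 or 0.5 in the study
#'   grid; smaller is steeper).
#' @param mechanism `"mnar"` (selective reporting) or `"mcar"` (paired
#'   random removal).
#' @param n_sim Number of Monte-Carlo replicates.
#' @param seed Base seed; replicate seeds are derived deterministically.
#' @param alpha One-sided significance threshold used by the estimators.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(K, mu, I2, n_per_arm = 50, dgm_gamma = 1.5,
                            mechanism = c("mnar", "mcar"), n_sim = 100,
                            seed = 1, alpha = 0.05) {
  mechanism <- match.arg(mechanism)
  if (n_sim < 1) abort_config("n_sim must be >= 1")
  if (K < 2) abort_config("K must be >= 2")
  cfg <- list(
    K = as.integer(K), mu = mu, I2 = I2, n_per_arm = as.integer(n_per_arm),
    sigma2 = 2 / n_per_arm, tau2 = tau2_from_I2(I2, 2 / n_per_arm),
    dgm_gamma = dgm_gamma, mechanism = mechanism,
    n_sim = as.integer(n_sim), seed = as.integer(seed), alpha = alpha
  )
  class(cfg) <- "scenario_config"
  cfg
}

# deterministic, parallelisation-friendly per-replicate seed below 2^31
replicate_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 1009) %% 2147483647)
}

#' Simulate a complete (fully reported) meta-analysis
#'
#' Study-specific true effects theta_i ~ N(mu, tau2); observed effects
#' y_i ~ N(theta_i, 2/n); reported squared standard errors drawn from the
#' scaled chi-square law sigma_i^2 ~ \[2 / ((n - 1) n)\] chi2_(n - 2), whose
#' mean 2 (n - 2) / ((n - 1) n) is approximately the true sampling variance
#' 2/n.
#'
#' @param config A [scenario_config()]. Uses the current RNG state; seed
#'   management is done by [run_scenario()].
#' @return A fully reported `meta_dataset`.
#' @export
simulate_complete <- function(config) {
  K <- config$K
  n <- config$n_per_arm
  theta <- stats::rnorm(K, config$mu, sqrt(config$tau2))
  y <- stats::rnorm(K, theta, sqrt(config$sigma2))
  sigma2_i <- 2 / ((n - 1) * n) * stats::rchisq(K, df = n - 2)
  meta_dataset(
    study_id = sprintf("study_%02d", seq_len(K)),
    n_treat = rep(n, K), n_ctrl = rep(n, K),
    y = y, se = sqrt(sigma2_i)
  )
}

#' Remove outcomes by selective (MNAR) reporting
#'
#' Each study's outcome is kept with probability exp(-4 p_i^gamma), where
#' p_i is the one-sided p-value of its observed effect; removed outcomes
#' keep only their sample sizes. The caller is responsible for re-simulating
#' replicates that end up with fewer than two reported outcomes
#' ([run_scenario()] does this).
#'
#' @param data A fully reported `meta_dataset`.
#' @param dgm_gamma Exponent of the reporting law (> 0).
#' @return A `meta_dataset` with some outcomes unreported.
#' @export
apply_orb <- function(data, dgm_gamma) {
  p <- one_sided_p(data$y, data$se)
  keep <- stats::runif(nrow(data)) < exp(-4 * p^dgm_gamma)
  out <- data
  out$y[!keep] <- NA_real_
  out$se[!keep] <- NA_real_
  out$reported <- keep
  out
}

#' Remove outcomes completely at random (MCAR benchmark)
#'
#' @param data A fully reported `meta_dataset`.
#' @param n_remove Number of outcomes to mark unreported (<= K - 2).
#' @return A `meta_dataset` with `n_remove` outcomes unreported.
#' @export
apply_mcar <- function(data, n_remove) {
  K <- nrow(data)
  if (n_remove > K - 2) abort_config("n_remove must leave >= 2 reported studies")
  if (n_remove == 0) return(data)
  drop_idx <- sample.int(K, n_remove)
  out <- data
  out$y[drop_idx] <- NA_real_
  out$se[drop_idx] <- NA_real_
  out$reported[drop_idx] <- FALSE
  out
}

#' The study's default estimator set
#'
#' Naive (reported studies only), complete-data benchmark, and
#' ORB-adjustment under each selection function examined: wA, wB(beta = 3),
#' wC(gamma = 3), wD(beta = 1.5, gamma = 7), wD(beta = 7, gamma = 1.5), and
#' the correctly specified wDGM matching the data-generating law.
#'
#' @param dgm_gamma Exponent used for the wDGM estimator.
#' @param alpha Significance threshold of the selection functions.
#' @return A named list of `list(method =, selection =)` entries suitable
#'   for [run_scenario()].
#' @export
default_estimators <- function(dgm_gamma = 1.5, alpha = 0.05) {
  list(
    naive = list(method = "naive", selection = NULL),
    complete = list(method = "complete", selection = NULL),
    wA = list(method = "adjusted",
              selection = selection_function("wA", alpha = alpha)),
    wB = list(method = "adjusted",
              selection = selection_function("wB", alpha = alpha, beta = 3)),
    wC = list(method = "adjusted",
              selection = selection_function("wC", alpha = alpha, gamma = 3)),
    wD_b1.5_g7 = list(method = "adjusted",
                      selection = selection_function("wD", alpha = alpha,
                                                     beta = 1.5, gamma = 7)),
    wD_b7_g1.5 = list(method = "adjusted",
                      selection = selection_function("wD", alpha = alpha,
                                                     beta = 7, gamma = 1.5)),
    wDGM = list(method = "adjusted",
                selection = selection_function("wDGM", gamma = dgm_gamma,
                                               alpha = alpha))
  )
}

#' Run one simulation scenario
#'
#' For each replicate: simulate a complete meta-analysis; under MNAR apply
#' selective reporting (re-simulating the whole replicate until at least two
#' outcomes are reported); under MCAR remove, at random, exactly the number
#' of outcomes the MNAR mechanism would have removed on the same draws. Then
#' fit every estimator, and summarise bias / ESE / MSE (and coverage / power
#' when `ci = TRUE`) with Monte-Carlo standard errors.
#'
#' The complete-data estimator is fitted on the pre-removal data. A
#' replicate's estimator failure (error or non-convergence) is dropped from
#' that estimator's summaries and counted in `n_failed`.
#'
#' @param config A [scenario_config()].
#' @param estimators Named list of `list(method =, selection =)` entries;
#'   default [default_estimators()] matched to the scenario's `dgm_gamma`.
#' @param ci Compute profile CIs per replicate (needed for coverage and
#'   power)? Default `TRUE`; set `FALSE` to speed up bias-only runs.
#' @return A tibble of class `orb_performance`: one row per
#'   (estimator, parameter, measure), with attribute `"replicates"` holding
#'   the per-replicate estimates.
#' @export
run_scenario <- function(config, estimators = NULL, ci = TRUE) {
  stopifnot(inherits(config, "scenario_config"))
  if (is.null(estimators)) {
    estimators <- default_estimators(config$dgm_gamma, config$alpha)
  }
  if (length(estimators) == 0) abort_config("estimators must be nonempty")

  one_replicate <- function(j) {
    set.seed(replicate_seed(config$seed, j))
    repeat {
      complete <- simulate_complete(config)
      observed <- apply_orb(complete, config$dgm_gamma)
      if (sum(observed$reported) >= 2) break
    }
    if (config$mechanism == "mcar") {
      n_removed <- sum(!observed$reported)
      observed <- apply_mcar(complete, n_removed)
    }
    purrr::imap_dfr(estimators, function(est, name) {
      dat <- if (est$method == "complete") complete else observed
      fit <- tryCatch(
        orb_fit(dat, method = est$method, selection = est$selection, ci = ci),
        error = function(e) NULL
      )
      if (is.null(fit) || !fit$converged) {
        return(tibble::tibble(
          replicate = j, estimator = name, failed = TRUE,
          mu_hat = NA_real_, tau2_hat = NA_real_,
          mu_lo = NA_real_, mu_hi = NA_real_,
          tau2_lo = NA_real_, tau2_hi = NA_real_,
          reject = NA, n_reported = NA_integer_
        ))
      }
      tibble::tibble(
        replicate = j, estimator = name, failed = FALSE,
        mu_hat = fit$mu_hat, tau2_hat = fit$tau2_hat,
        mu_lo = fit$ci_mu[1], mu_hi = fit$ci_mu[2],
        tau2_lo = fit$ci_tau2[1], tau2_hi = fit$ci_tau2[2],
        reject = if (ci) !is.na(fit$ci_mu[1]) && !is.na(fit$ci_mu[2]) &&
          (fit$ci_mu[1] > 0 || fit$ci_mu[2] < 0) else NA,
        n_reported = sum(dat$reported)
      )
    })
  }

  replicates <- purrr::map_dfr(seq_len(config$n_sim), one_replicate)
  out <- summarise_performance(replicates, truth_mu = config$mu,
                               truth_tau2 = config$tau2)
  attr(out, "replicates") <- replicates
  attr(out, "config") <- config
  class(out) <- c("orb_performance", class(out))
  out
}
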