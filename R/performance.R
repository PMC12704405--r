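#' Monte-Carlo performance measures with their standard errors
#'
#' Standard simulation-study summaries (Morris, White & Crowther
#' definitions): bias, empirical standard error, mean squared error,
#' CI coverage, and power, each paired with its Monte-Carlo standard error
#' (MCSE).
#'
#' @param estimates Numeric vector of point estimates across replicates.
#' @param truth True parameter value.
#' @return A one-row tibble with columns `value` and `mcse`.
#' @name mc_measures
NULL

#' @rdname mc_measures
#' @export
mc_bias <- function(estimates, truth) {
  n <- length(estimates)
  if (n < 2) abort_config("need >= 2 estimates")
  tibble::tibble(
    value = mean(estimates) - truth,
    mcse = stats::sd(estimates) / sqrt(n)
  )
}

#' @rdname mc_measures
#' @export
mc_ese <- function(estimates) {
  n <- length(estimates)
  if (n < 2) abort_config("need >= 2 estimates")
  ese <- stats::sd(estimates)
  tibble::tibble(value = ese, mcse = ese / sqrt(2 * (n - 1)))
}

#' @rdname mc_measures
#' @export
mc_mse <- function(estimates, truth) {
  n <- length(estimates)
  if (n < 2) abort_config("need >= 2 estimates")
  sq <- (estimates - truth)^2
  tibble::tibble(value = mean(sq), mcse = stats::sd(sq) / sqrt(n))
}

#' @rdname mc_measures
#' @param lower,upper CI endpoints across replicates.
#' @export
mc_coverage <- function(lower, upper, truth) {
  n <- length(lower)
  if (n < 1) abort_config("need >= 1 interval")
  cov <- mean(lower <= truth & truth <= upper)
  tibble::tibble(value = cov, mcse = sqrt(cov * (1 - cov) / n))
}

#' @rdname mc_measures
#' @param reject Logical rejection indicators across replicates.
#' @export
mc_power <- function(reject) {
  n <- length(reject)
  if (n < 1) abort_config("need >= 1 replicate")
  pw <- mean(reject)
  tibble::tibble(value = pw, mcse = sqrt(pw * (1 - pw) / n))
}

#' Summarise per-replicate fits into a performance table
#'
#' @param replicates Tibble of per-replicate results as produced inside
#'   [run_scenario()] (columns `estimator`, `failed`, `mu_hat`, `tau2_hat`,
#'   CI endpoints and `reject`).
#' @param truth_mu,truth_tau2 True parameter values of the scenario.
#' @return A tidy tibble: one row per (estimator, parameter, measure) with
#'   `value`, `mcse` and `n_effective` (converged replicates); coverage and
#'   power rows appear only when CIs were computed. Failures per estimator
#'   are reported in `n_failed`.
#' @export
summarise_performance <- function(replicates, truth_mu, truth_tau2) {
  per_estimator <- function(df) {
    ok <- df[!df$failed, , drop = FALSE]
    n_eff <- nrow(ok)
    n_failed <- sum(df$failed)
    if (n_eff < 2) {
      return(tibble::tibble(
        parameter = "mu", measure = "bias", value = NA_real_, mcse = NA_real_,
        n_effective = n_eff, n_failed = n_failed
      ))
    }
    has_ci <- !all(is.na(ok$mu_lo))
    rows <- list(
      dplyr::bind_cols(tibble::tibble(parameter = "mu", measure = "bias"),
                       mc_bias(ok$mu_hat, truth_mu)),
      dplyr::bind_cols(tibble::tibble(parameter = "mu", measure = "ese"),
                       mc_ese(ok$mu_hat)),
      dplyr::bind_cols(tibble::tibble(parameter = "mu", measure = "mse"),
                       mc_mse(ok$mu_hat, truth_mu)),
      dplyr::bind_cols(tibble::tibble(parameter = "tau2", measure = "bias"),
                       mc_bias(ok$tau2_hat, truth_tau2)),
      dplyr::bind_cols(tibble::tibble(parameter = "tau2", measure = "ese"),
                       mc_ese(ok$tau2_hat)),
      dplyr::bind_cols(tibble::tibble(parameter = "tau2", measure = "mse"),
                       mc_mse(ok$tau2_hat, truth_tau2))
    )
    if (has_ci) {
      rows <- c(rows, list(
        dplyr::bind_cols(tibble::tibble(parameter = "mu", measure = "coverage"),
                         mc_coverage(ok$mu_lo, ok$mu_hi, truth_mu)),
        dplyr::bind_cols(tibble::tibble(parameter = "mu", measure = "power"),
                         mc_power(ok$reject)),
        dplyr::bind_cols(tibble::tibble(parameter = "tau2", measure = "coverage"),
                         mc_coverage(ok$tau2_lo, ok$tau2_hi, truth_tau2))
      ))
    }
    dplyr::mutate(dplyr::bind_rows(rows),
                  n_effective = n_eff, n_failed = n_failed)
  }
  replicates |>
    dplyr::group_by(.data$estimator) |>
    dplyr::group_modify(~ per_estimator(.x)) |>
    dplyr::ungroup()
}

#' Look up one performance value
#'
#' Convenience accessor for a single (estimator, parameter, measure) cell of
#' a performance table.
#'
#' @param perf A table from [run_scenario()] / [summarise_performance()].
#' @param estimator,parameter,measure Row key.
#' @return A list with `value` and `mcse`.
#' @export
perf_value <- function(perf, estimator, parameter, measure) {
  row <- dplyr::filter(
    perf, .data$estimator == !!estimator,
    .data$parameter == !!parameter, .data$measure == !!measure
  )
  if (nrow(row) != 1) abort_config("no unique matching performance row")
  list(value = row$value, mcse = row$mcse)
}
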