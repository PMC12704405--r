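#' Marginal density of an observed effect under the random-effects model
#'
#' Under the hierarchical model y_i ~ N(theta_i, se_i^2) with
#' theta_i ~ N(mu, tau2), the marginal law of y_i is
#' N(mu, se_i^2 + tau2).
#'
#' @param y Observed effect(s).
#' @param mu Overall treatment effect.
#' @param tau2 Between-study heterogeneity variance (>= 0).
#' @param se Within-study standard error(s) (> 0).
#' @param log Return the log density?
#' @return Density values, vectorised.
#' @export
marginal_density <- function(y, mu, tau2, se, log = FALSE) {
  check_params(mu, tau2)
  if (any(se <= 0)) abort_config("se must be positive")
  stats::dnorm(y, mean = mu, sd = sqrt(se^2 + tau2), log = log)
}

check_params <- function(mu, tau2) {
  if (!is.finite(mu)) abort_config("mu must be finite")
  if (!is.finite(tau2) || tau2 < 0) abort_config("tau2 must be finite and >= 0")
  invisible(TRUE)
}

#' Naive random-effects log-likelihood (reported studies only)
#'
#' The standard meta-analytic log-likelihood that ignores unreported
#' outcomes, i.e. the sum of log marginal densities over reported studies.
#' The full normal constant (-log(2 pi sigma^2)/2 per study) is included, so
#' values are comparable across estimation methods.
#'
#' @param data A `meta_dataset` (or data frame) whose rows are all reported.
#' @inheritParams marginal_density
#' @return The log-likelihood value.
#' @export
naive_loglik <- function(data, mu, tau2) {
  if (nrow(data) == 0) abort_config("no reported studies: likelihood undefined")
  if (any(is.na(data$y) | is.na(data$se))) {
    abort_config("naive_loglik expects reported studies only (no missing y/se)")
  }
  sum(marginal_density(data$y, mu, tau2, data$se, log = TRUE))
}

# ---- weighted-density integrals -------------------------------------------

# Map a p-value on the chosen scale to the effect value(s) where it is
# attained, given the within-study standard error.
p_to_y <- function(p, se, p_scale) {
  if (p_scale == "one_sided") {
    -se * stats::qnorm(p)
  } else {
    c(-1, 1) * (-se * stats::qnorm(p / 2))
  }
}

p_of_y <- function(y, se, p_scale) {
  if (p_scale == "one_sided") {
    stats::pnorm(-y / se)
  } else {
    2 * stats::pnorm(-abs(y) / se)
  }
}

# log of integral over y of N(y; mu, se^2 + tau2) * g(w(p(y))) where
# g = identity (side = "w") or 1 - w (side = "complement").
# Standardised to z = (y - mu)/s and integrated adaptively on [-10, 10],
# split at the images of the selection function's breakpoints so every piece
# is smooth. Returns -Inf (with attribute "orbsel_flag") when the integral
# underflows to zero.
log_weighted_integral <- function(se, mu, tau2, w, p_scale, side,
                                  method = "quadrature") {
  s <- sqrt(se^2 + tau2)
  if (method == "closed_form") {
    return(closed_form_piecewise_constant(se, mu, s, w, p_scale, side))
  }
  complement <- side == "complement"
  if (w$family == "always_one") {
    if (!complement) return(0)
    res <- -Inf
    attr(res, "orbsel_flag") <- "zero_integral"
    return(res)
  }
  integrand <- function(z) {
    wt <- sel_weight(w, p_of_y(mu + s * z, se, p_scale))
    stats::dnorm(z) * (if (complement) 1 - wt else wt)
  }
  pb <- sel_breakpoints(w)
  zb <- numeric(0)
  if (length(pb) > 0) {
    yb <- unlist(lapply(pb, p_to_y, se = se, p_scale = p_scale))
    zb <- (yb - mu) / s
  }
  knots <- sort(unique(c(-10, 10, zb[zb > -10 & zb < 10])))
  total <- 0
  for (i in seq_len(length(knots) - 1)) {
    total <- total + stats::integrate(
      integrand, knots[i], knots[i + 1],
      rel.tol = 1e-10, abs.tol = 1e-10, subdivisions = 200L
    )$value
  }
  if (total <= 0) {
    res <- -Inf
    attr(res, "orbsel_flag") <- "zero_integral"
    return(res)
  }
  log(min(total, 1))
}

# Phi-based closed forms for the piecewise-constant (threshold) selection
# function. One-sided: the non-significant region is y < se * z_{1-alpha};
# two-sided (Copas form): |y| < se * z_{1-alpha/2}.
closed_form_piecewise_constant <- function(se, mu, s, w, p_scale, side) {
  if (w$family != "piecewise_constant") {
    abort_config("closed form available only for the piecewise_constant family")
  }
  if (p_scale == "one_sided") {
    zc <- (se * stats::qnorm(1 - w$alpha) - mu) / s
    if (side == "complement") {
      return(stats::pnorm(zc, log.p = TRUE))
    }
    return(stats::pnorm(zc, lower.tail = FALSE, log.p = TRUE))
  }
  cc <- se * stats::qnorm(1 - w$alpha / 2)
  inner <- stats::pnorm((cc - mu) / s) - stats::pnorm((-cc - mu) / s)
  val <- if (side == "complement") inner else 1 - inner
  if (val <= 0) {
    res <- -Inf
    attr(res, "orbsel_flag") <- "zero_integral"
    return(res)
  }
  log(val)
}

#' Likelihood contribution of an unreported study
#'
#' The log of the probability, under the marginal model N(mu, se^2 + tau2),
#' that a study outcome goes unreported: log of the integral of
#' f(y) (1 - w(p(y))) over the real line. For the piecewise-constant family
#' this reduces to a normal-CDF closed form (used when `method = "auto"`);
#' otherwise adaptive quadrature is used, split at the selection function's
#' breakpoints.
#'
#' @param se_imp Imputed standard error of the unreported study (> 0).
#' @inheritParams marginal_density
#' @param w A [selection_function()].
#' @param p_scale `"one_sided"` (default) or `"two_sided"`.
#' @param method `"auto"`, `"quadrature"`, or `"closed_form"` (the latter is
#'   only available for `piecewise_constant`).
#' @return A log-probability (<= 0); `-Inf` with attribute `orbsel_flag` when
#'   the integral underflows (essentially all mass in the reported region).
#' @export
unreported_contribution <- function(se_imp, mu, tau2, w,
                                    p_scale = c("one_sided", "two_sided"),
                                    method = c("auto", "quadrature", "closed_form")) {
  p_scale <- match.arg(p_scale)
  method <- match.arg(method)
  check_params(mu, tau2)
  if (se_imp <= 0) abort_config("se_imp must be positive")
  if (method == "auto") {
    method <- if (w$family %in% c("piecewise_constant", "always_one")) {
      "closed_form"
    } else {
      "quadrature"
    }
    if (w$family == "always_one") method <- "quadrature" # handled analytically inside
  }
  log_weighted_integral(se_imp, mu, tau2, w, p_scale, side = "complement",
                        method = method)
}

#' Normalising term for a reported study under explicit selection
#'
#' The log of the probability that a study outcome is reported,
#' log integral of f(y) w(p(y)) dy. Only needed when the selection process is
#' modelled for reported studies too (the generic adjusted likelihood); under
#' the default simplification w(y_i) = 1 for reported studies this term is 0
#' and is skipped.
#'
#' @inheritParams unreported_contribution
#' @param se Standard error of the reported study.
#' @return A log-probability (<= 0).
#' @export
reported_normalizer <- function(se, mu, tau2, w,
                                p_scale = c("one_sided", "two_sided"),
                                method = c("auto", "quadrature", "closed_form")) {
  p_scale <- match.arg(p_scale)
  method <- match.arg(method)
  check_params(mu, tau2)
  if (se <= 0) abort_config("se must be positive")
  if (method == "auto") {
    method <- if (w$family == "piecewise_constant") "closed_form" else "quadrature"
  }
  log_weighted_integral(se, mu, tau2, w, p_scale, side = "w", method = method)
}

#' ORB-adjusted log-likelihood
#'
#' Reported studies contribute their log marginal density; each unreported
#' study contributes the log probability of non-reporting under the selection
#' function ([unreported_contribution()]). When `reported_selection = TRUE`
#' the generic weighted-likelihood form is used instead, subtracting the
#' reporting-probability normaliser for every reported study.
#'
#' @param data A `meta_dataset`; unreported rows need imputed standard errors.
#' @inheritParams marginal_density
#' @param w A [selection_function()].
#' @param se_imputed Named numeric vector mapping unreported `study_id`s to
#'   imputed standard errors. `NULL` (default) imputes from the reported
#'   studies' design factor ([design_factor()]).
#' @param p_scale `"one_sided"` (default) or `"two_sided"`.
#' @param reported_selection Model the selection process for reported studies
#'   too? Default `FALSE` (no selection on reported outcomes).
#' @param method Integral evaluation passed to the contribution terms.
#' @return The log-likelihood; `-Inf` if any contribution underflows.
#' @export
orb_loglik <- function(data, mu, tau2, w, se_imputed = NULL,
                       p_scale = c("one_sided", "two_sided"),
                       reported_selection = FALSE,
                       method = c("auto", "quadrature", "closed_form")) {
  p_scale <- match.arg(p_scale)
  method <- match.arg(method)
  parts <- partition_reported(data)
  rep_d <- parts$reported
  unrep_d <- parts$unreported
  if (nrow(rep_d) == 0) abort_config("no reported studies: likelihood undefined")
  if (nrow(unrep_d) > 0) {
    if (is.null(se_imputed)) {
      k_hat <- design_factor(rep_d)
      se_imputed <- stats::setNames(
        sqrt(impute_variance(unrep_d$n_treat + unrep_d$n_ctrl, k_hat)),
        unrep_d$study_id
      )
    }
    missing_ids <- setdiff(unrep_d$study_id, names(se_imputed))
    if (length(missing_ids) > 0) {
      abort_config(paste0(
        "se_imputed lacks entries for unreported studies: ",
        paste(missing_ids, collapse = ", ")
      ))
    }
    se_u <- unname(se_imputed[unrep_d$study_id])
  } else {
    se_u <- numeric(0)
  }
  orb_loglik_core(rep_d$y, rep_d$se, se_u, mu, tau2, w, p_scale,
                  reported_selection, method)
}

# lean kernel used by the optimiser: no validation or data-frame handling.
# y, se: reported effects; se_u: imputed SEs of unreported studies.
orb_loglik_core <- function(y, se, se_u, mu, tau2, w, p_scale,
                            reported_selection, method = "auto") {
  ll <- sum(stats::dnorm(y, mu, sqrt(se^2 + tau2), log = TRUE))
  if (length(se_u) > 0) {
    # studies with equal imputed SE share one integral
    for (s_val in unique(se_u)) {
      contrib <- unreported_contribution(s_val, mu, tau2, w, p_scale, method)
      if (!is.finite(contrib)) return(structure(-Inf, orbsel_flag = "zero_integral"))
      ll <- ll + sum(se_u == s_val) * as.numeric(contrib)
    }
  }
  if (isTRUE(reported_selection)) {
    for (s_val in unique(se)) {
      norm <- reported_normalizer(s_val, mu, tau2, w, p_scale, method)
      if (!is.finite(norm)) return(structure(-Inf, orbsel_flag = "zero_integral"))
      ll <- ll - sum(se == s_val) * as.numeric(norm)
    }
  }
  ll
}
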