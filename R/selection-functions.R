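#' Parametric selection functions of the p-value
#'
#' A selection function w(p) gives the probability that a study outcome is
#' reported as a non-increasing function of its (one-sided) p-value p. These
#' are the missing-data mechanisms assumed for ORB adjustment, plus the
#' exponential law used to generate ORB in the simulation engine.
#'
#' Families (aliases in parentheses):
#' \describe{
#'   \item{`piecewise_constant` (`wA`)}{1 if p <= alpha, else 0.}
#'   \item{`constant_decreasing` (`wB`)}{1 if p <= alpha, else
#'     (p - beta) / (alpha - beta); requires beta > 1 so the weight stays in
#'     \[0, 1\] up to p = 1.}
#'   \item{`decreasing_constant` (`wC`)}{1 - p^gamma / alpha^gamma if
#'     p <= alpha, else 0.}
#'   \item{`piecewise_decreasing` (`wD`)}{1 - (1 - omega_alpha)
#'     p^gamma / alpha^gamma if p <= alpha, else
#'     omega_alpha (p - beta) / (alpha - beta); omega_alpha is the reporting
#'     probability at the significance threshold.}
#'   \item{`dgm_exponential` (`wDGM`)}{exp(-4 p^gamma); the law used to
#'     simulate selective reporting, with the constant -4 fixed.}
#'   \item{`always_one` (`none`)}{identically 1 (no selection).}
#' }
#'
#' @param family Family name or alias (see Details).
#' @param alpha One-sided significance threshold in (0, 1); default 0.05.
#' @param beta Slope parameter (> 1) for `constant_decreasing` /
#'   `piecewise_decreasing`.
#' @param gamma Shape parameter (> 0) for `decreasing_constant`,
#'   `piecewise_decreasing` and `dgm_exponential`.
#' @param omega_alpha Reporting probability at p = alpha, in \[0, 1\]
#'   (`piecewise_decreasing` only; default 0.5).
#'
#' @return An object of class `selection_function`.
#' @export
#' @examples
#' w <- selection_function("wB", beta = 3)
#' sel_weight(w, c(0.01, 0.05, 0.5, 1))
selection_function <- function(family, alpha = 0.05, beta = NULL,
                               gamma = NULL, omega_alpha = NULL) {
  aliases <- c(
    wA = "piecewise_constant", wB = "constant_decreasing",
    wC = "decreasing_constant", wD = "piecewise_decreasing",
    wDGM = "dgm_exponential", none = "always_one"
  )
  if (family %in% names(aliases)) family <- aliases[[family]]
  families <- unname(aliases)
  if (!family %in% families) {
    abort_config(paste0(
      "unknown selection family '", family, "'; use one of: ",
      paste(c(families, names(aliases)), collapse = ", ")
    ))
  }
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    abort_config("alpha must be a single number in (0, 1)")
  }
  needs_beta <- family %in% c("constant_decreasing", "piecewise_decreasing")
  needs_gamma <- family %in% c("decreasing_constant", "piecewise_decreasing",
                               "dgm_exponential")
  if (needs_beta) {
    if (is.null(beta) || !is.numeric(beta) || length(beta) != 1) {
      abort_config(paste0("family '", family, "' requires a numeric beta"))
    }
    if (beta <= 1) {
      abort_config(paste0(
        "beta must exceed 1 (got ", format(beta), "): for beta <= 1 the weight ",
        "(p - beta)/(alpha - beta) falls outside [0, 1] before p reaches 1"
      ))
    }
  } else if (!is.null(beta)) {
    abort_config(paste0("family '", family, "' does not take a beta parameter"))
  }
  if (needs_gamma) {
    if (is.null(gamma) || !is.numeric(gamma) || length(gamma) != 1 || gamma <= 0) {
      abort_config(paste0("family '", family, "' requires gamma > 0"))
    }
  } else if (!is.null(gamma)) {
    abort_config(paste0("family '", family, "' does not take a gamma parameter"))
  }
  if (family == "piecewise_decreasing") {
    if (is.null(omega_alpha)) omega_alpha <- 0.5
    if (!is.numeric(omega_alpha) || length(omega_alpha) != 1 ||
        omega_alpha < 0 || omega_alpha > 1) {
      abort_config("omega_alpha must be a single number in [0, 1]")
    }
  } else if (!is.null(omega_alpha)) {
    abort_config(paste0("family '", family, "' does not take omega_alpha"))
  }
  structure(
    list(family = family, alpha = alpha, beta = beta, gamma = gamma,
         omega_alpha = omega_alpha),
    class = "selection_function"
  )
}

#' @export
print.selection_function <- function(x, ...) {
  pars <- c(
    alpha = x$alpha,
    if (!is.null(x$beta)) c(beta = x$beta),
    if (!is.null(x$gamma)) c(gamma = x$gamma),
    if (!is.null(x$omega_alpha)) c(omega_alpha = x$omega_alpha)
  )
  cat("<selection_function> ", x$family, " (",
      paste(names(pars), unname(pars), sep = " = ", collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' @export
format.selection_function <- function(x, ...) {
  short <- c(
    piecewise_constant = "wA", constant_decreasing = "wB",
    decreasing_constant = "wC", piecewise_decreasing = "wD",
    dgm_exponential = "wDGM", always_one = "none"
  )[[x$family]]
  pars <- c(
    if (!is.null(x$beta)) paste0("beta=", format(x$beta)),
    if (!is.null(x$gamma)) paste0("gamma=", format(x$gamma))
  )
  if (length(pars) == 0) short else paste0(short, "(", paste(pars, collapse = ","), ")")
}

#' One- and two-sided p-values for a normal effect estimate
#'
#' `one_sided_p()` returns p = pnorm(-y / se), the p-value against the null
#' of no benefit for a beneficial outcome (small p = evidence of benefit).
#' `two_sided_p()` returns p = 2 pnorm(-|y| / se), the two-tail version used
#' by the Copas-style closed form.
#'
#' @param y Effect estimate(s).
#' @param se Positive standard error(s).
#' @return p-values in (0, 1); vectorised over `y` and `se`.
#' @export
one_sided_p <- function(y, se) {
  if (any(se <= 0)) abort_config("se must be positive")
  stats::pnorm(-y / se)
}

#' @rdname one_sided_p
#' @export
two_sided_p <- function(y, se) {
  if (any(se <= 0)) abort_config("se must be positive")
  2 * stats::pnorm(-abs(y) / se)
}

#' Evaluate a selection function
#'
#' @param w A [selection_function()].
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Reporting probabilities in \[0, 1\], non-increasing in `p`.
#' @export
sel_weight <- function(w, p) {
  stopifnot(inherits(w, "selection_function"))
  if (any(p < -1e-12 | p > 1 + 1e-12)) {
    abort_config("p-values must lie in [0, 1]")
  }
  p <- pmin(pmax(p, 0), 1)
  a <- w$alpha
  sig <- p <= a
  out <- switch(
    w$family,
    piecewise_constant = as.numeric(sig),
    constant_decreasing = ifelse(sig, 1, (p - w$beta) / (a - w$beta)),
    decreasing_constant = ifelse(sig, 1 - p^w$gamma / a^w$gamma, 0),
    piecewise_decreasing = ifelse(
      sig,
      1 - (1 - w$omega_alpha) * p^w$gamma / a^w$gamma,
      w$omega_alpha * (p - w$beta) / (a - w$beta)
    ),
    dgm_exponential = exp(-4 * p^w$gamma),
    always_one = rep(1, length(p))
  )
  pmin(pmax(out, 0), 1)
}

# internal: points of non-smoothness of w as a function of p, in (0, 1)
sel_breakpoints <- function(w) {
  switch(
    w$family,
    piecewise_constant = w$alpha,
    constant_decreasing = w$alpha,
    decreasing_constant = w$alpha,
    piecewise_decreasing = w$alpha,
    dgm_exponential = numeric(0),
    always_one = numeric(0)
  )
}
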