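# Independent numerical oracles and fixture builders used across tests.

# Composite-trapezoid evaluation of integral f(y) * g(w(p(y))) dy on the
# standardised scale, with nodes laid per smooth piece (split at the
# selection function's breakpoints) so the rule keeps its O(h^2) accuracy
# at discontinuities. Independent of the package's adaptive quadrature.
oracle_weighted_integral <- function(se, mu, tau2, w, p_scale = "one_sided",
                                     side = "complement", n_nodes = 1e4) {
  s <- sqrt(se^2 + tau2)
  p_of <- function(y) {
    if (p_scale == "one_sided") pnorm(-y / se) else 2 * pnorm(-abs(y) / se)
  }
  zb <- numeric(0)
  if (w$family %in% c("piecewise_constant", "constant_decreasing",
                      "decreasing_constant", "piecewise_decreasing")) {
    yb <- if (p_scale == "one_sided") {
      -se * qnorm(w$alpha)
    } else {
      c(-1, 1) * (-se * qnorm(w$alpha / 2))
    }
    zb <- (yb - mu) / s
  }
  knots <- sort(unique(c(-10, 10, zb[zb > -10 & zb < 10])))
  total <- 0
  for (i in seq_len(length(knots) - 1)) {
    z <- seq(knots[i], knots[i + 1], length.out = n_nodes)
    # evaluate the weight a hair inside the piece so endpoint values are the
    # one-sided limits, not the other branch of a discontinuous w
    z_eval <- z
    z_eval[1] <- z[1] + 1e-9
    z_eval[n_nodes] <- z[n_nodes] - 1e-9
    wt <- sel_weight(w, pmin(pmax(p_of(mu + s * z_eval), 0), 1))
    fz <- dnorm(z) * (if (side == "complement") 1 - wt else wt)
    h <- z[2] - z[1]
    total <- total + h * (sum(fz) - (fz[1] + fz[length(fz)]) / 2)
  }
  total
}

# random valid dataset with a chosen number of unreported rows
make_dataset <- function(K = 8, n_unrep = 2, seed = 1) {
  set.seed(seed)
  y <- rnorm(K, 0.3, 0.4)
  se <- sqrt(2 / 50) * sqrt(rchisq(K, 20) / 20)
  unrep <- sample.int(K, n_unrep)
  y[unrep] <- NA
  se[unrep] <- NA
  meta_dataset(
    study_id = sprintf("s%02d", seq_len(K)),
    n_treat = sample(30:120, K, replace = TRUE),
    n_ctrl = sample(30:120, K, replace = TRUE),
    y = y, se = se
  )
}

# a pool of valid selection functions for property tests
random_selection <- function(seed) {
  set.seed(seed)
  fam <- sample(c("wA", "wB", "wC", "wD", "wDGM"), 1)
  alpha <- runif(1, 0.01, 0.2)
  switch(fam,
    wA = selection_function("wA", alpha = alpha),
    wB = selection_function("wB", alpha = alpha, beta = runif(1, 1.2, 8)),
    wC = selection_function("wC", alpha = alpha, gamma = runif(1, 0.3, 6)),
    wD = selection_function("wD", alpha = alpha, beta = runif(1, 1.2, 8),
                            gamma = runif(1, 0.3, 6),
                            omega_alpha = runif(1)),
    wDGM = selection_function("wDGM", gamma = runif(1, 0.3, 3), alpha = alpha)
  )
}
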