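#' Build or read a grid of simulation scenarios
#'
#' `scenario_grid()` crosses the supplied factor levels into one
#' [scenario_config()] per cell. `read_scenario_grid()` does the same from a
#' YAML file whose top-level `scenarios` mapping carries the fields of
#' `scenario_grid()` (scalars or lists).
#'
#' @param K,mu,I2,dgm_gamma Vectors of levels to cross.
#' @param mechanism `"mnar"`, `"mcar"`, or both.
#' @param n_per_arm,n_sim,seed,alpha Scalars shared by all cells.
#' @return A tibble with one row per scenario and a list-column `config`.
#' @export
#' @examples
#' g <- scenario_grid(K = c(5, 15, 30), mu = c(0, 0.4), I2 = 0, n_sim = 10)
#' nrow(g)
scenario_grid <- function(K = c(5, 15, 30),
                          mu = c(0, 0.2, 0.4, 0.6, 0.8),
                          I2 = c(0, 0.25, 0.5, 0.75, 0.9),
                          dgm_gamma = c(1.5, 0.5),
                          mechanism = "mnar",
                          n_per_arm = 50, n_sim = 3200, seed = 1,
                          alpha = 0.05) {
  grid <- tidyr::crossing(K = K, mu = mu, I2 = I2, dgm_gamma = dgm_gamma,
                          mechanism = mechanism)
  grid$scenario <- seq_len(nrow(grid))
  grid$config <- purrr::pmap(
    grid[c("K", "mu", "I2", "dgm_gamma", "mechanism")],
    function(K, mu, I2, dgm_gamma, mechanism) {
      scenario_config(K = K, mu = mu, I2 = I2, n_per_arm = n_per_arm,
                      dgm_gamma = dgm_gamma, mechanism = mechanism,
                      n_sim = n_sim, seed = seed, alpha = alpha)
    }
  )
  grid
}

#' @rdname scenario_grid
#' @param path Path to a YAML scenario file.
#' @export
read_scenario_grid <- function(path) {
  spec <- yaml::read_yaml(path)
  sc <- spec$scenarios
  if (is.null(sc)) abort_config("scenario file needs a top-level 'scenarios' map")
  take <- function(name, default) {
    if (is.null(sc[[name]])) default else unlist(sc[[name]])
  }
  scenario_grid(
    K = take("K", c(5, 15, 30)),
    mu = take("mu", c(0, 0.2, 0.4, 0.6, 0.8)),
    I2 = take("I2", c(0, 0.25, 0.5, 0.75, 0.9)),
    dgm_gamma = take("dgm_gamma", c(1.5, 0.5)),
    mechanism = take("mechanism", "mnar"),
    n_per_arm = take("n_per_arm", 50),
    n_sim = take("n_sim", 3200),
    seed = take("seed", 1),
    alpha = take("alpha", 0.05)
  )
}

#' Run a grid of scenarios into one tidy performance table
#'
#' @param grid A tibble from [scenario_grid()] / [read_scenario_grid()].
#' @param estimators Passed to [run_scenario()]; default per-scenario
#'   [default_estimators()].
#' @param ci Compute CIs per replicate (coverage/power)?
#' @return A tibble with one row per
#'   (scenario, estimator, parameter, measure).
#' @export
run_scenario_grid <- function(grid, estimators = NULL, ci = TRUE) {
  purrr::map2_dfr(grid$scenario, grid$config, function(id, cfg) {
    perf <- run_scenario(cfg, estimators = estimators, ci = ci)
    dplyr::mutate(
      tibble::as_tibble(perf),
      scenario = id, K = cfg$K, mu = cfg$mu, I2 = cfg$I2,
      dgm_gamma = cfg$dgm_gamma, mechanism = cfg$mechanism,
      .before = 1
    )
  })
}
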