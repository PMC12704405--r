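#' Plot a sensitivity analysis
#'
#' Adjusted pooled risk-ratio estimates against the varied selection-function
#' parameter, one panel per family, with the naive estimate as a dashed
#' reference line. The null (RR = 1) is drawn dotted.
#'
#' @param object An `orb_sensitivity` tibble from [run_sensitivity()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.orb_sensitivity <- function(object, ...) {
  naive_rr <- object$rr_hat[object$family == "naive"][1]
  df <- dplyr::filter(object, .data$family != "naive", !is.na(.data$rr_hat))
  df <- dplyr::mutate(
    df,
    param = dplyr::case_when(
      .data$family == "wB" ~ .data$beta,
      .data$family == "wC" ~ .data$gamma,
      TRUE ~ .data$gamma
    ),
    series = dplyr::if_else(.data$family == "wD",
                            paste0("wD, beta=", .data$beta), .data$family)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$param, y = .data$rr_hat,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = naive_rr, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::facet_wrap(~family, scales = "free_x") +
    ggplot2::labs(
      x = "selection-function parameter (beta for wB, gamma for wC/wD)",
      y = "adjusted risk ratio",
      colour = NULL,
      title = "Sensitivity of the ORB-adjusted estimate",
      subtitle = "dashed: naive estimate; dotted: null"
    )
}

#' Forest-style comparison of fits
#'
#' @param fits A named list of [orb_fit()] objects (names label the rows).
#' @param exponentiate Plot on the risk-ratio scale? Default `TRUE`.
#' @return A ggplot object.
#' @export
plot_forest <- function(fits, exponentiate = TRUE) {
  df <- purrr::imap_dfr(fits, function(f, nm) {
    tibble::tibble(label = nm, estimate = f$mu_hat,
                   lo = f$ci_mu[1], hi = f$ci_mu[2])
  })
  null_val <- 0
  if (exponentiate) {
    df <- dplyr::mutate(df, estimate = exp(.data$estimate),
                        lo = exp(.data$lo), hi = exp(.data$hi))
    null_val <- 1
  }
  df$label <- factor(df$label, levels = rev(df$label))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$label)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = null_val, linetype = "dotted") +
    ggplot2::labs(
      x = if (exponentiate) "risk ratio (95% PL CI)" else "effect (95% PL CI)",
      y = NULL
    )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
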