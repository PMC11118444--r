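#' Plot methods
#'
#' `autoplot()` methods give quick diagnostic views of fitted objects:
#' stationary identity probabilities for an `island_fit` or
#' `two_deme_fit`, and Monte Carlo estimates with 2-SE error bars for
#' `sim_estimates` (optionally overlaid with analytic reference values).
#'
#' @param object A fitted object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name popgst-autoplot
NULL

#' @rdname popgst-autoplot
#' @method autoplot island_fit
#' @export
autoplot.island_fit <- function(object, ...) {
  df <- tibble::tibble(
    quantity = factor(c("f", "g_w", "g_b"), levels = c("f", "g_w", "g_b")),
    value = unname(object$identities)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$quantity, y = .data$value)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(
      y = "stationary IBS probability", x = NULL,
      title = sprintf(
        "island model: G1* = %.3f, G2* = %.3f", object$g1, object$g2
      )
    ) +
    ggplot2::theme_minimal()
}

#' @rdname popgst-autoplot
#' @method autoplot two_deme_fit
#' @export
autoplot.two_deme_fit <- function(object, ...) {
  df <- tibble::tibble(
    quantity = factor(c("g_w0", "g_w1", "g_b"),
                      levels = c("g_w0", "g_w1", "g_b")),
    value = c(object$g_w0, object$g_w1, object$g_b)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$quantity, y = .data$value)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(
      y = "stationary IBS probability", x = NULL,
      title = sprintf(
        "two demes: beta_WT0 = %.3f, G_ST,0* = %.3f (r_min = %.3f)",
        object$beta_wt0, object$gst0_star, object$r_min
      )
    ) +
    ggplot2::theme_minimal()
}

#' @rdname popgst-autoplot
#' @param reference Optional named numeric vector (names among `f`,
#'   `g_w`, `g_b`) of analytic values to overlay.
#' @method autoplot sim_estimates
#' @export
autoplot.sim_estimates <- function(object, reference = NULL, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$quantity, y = .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$estimate - 2 * .data$se,
      ymax = .data$estimate + 2 * .data$se
    )) +
    ggplot2::labs(y = "IBS probability (estimate, 2 SE)", x = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(reference)) {
    rdf <- tibble::tibble(quantity = names(reference), value = unname(reference))
    p <- p + ggplot2::geom_point(
      data = rdf, ggplot2::aes(x = .data$quantity, y = .data$value),
      colour = "red", shape = 4, size = 3
    )
  }
  p
}

#' Negativity threshold as a function of migration
#'
#' Plots [r_min()] against the focal deme's scaled migration rate `M0`
#' for one or more values of `M1` and `theta`, with the `r = 1/2`
#' reference: under soft migration the threshold declines uniformly as
#' the number of newly migrated genes grows.
#'
#' @param M0 Numeric vector of focal-deme migration rates.
#' @param M1 Other deme's migration rate(s).
#' @param theta Scaled mutation rate(s).
#' @return A ggplot object.
#' @examples
#' plot_r_min(M0 = seq(1, 20, by = 0.5), M1 = c(0.5, 2), theta = 0.5)
#' @export
plot_r_min <- function(M0, M1 = 0.5, theta = 0.5) {
  grid <- tidyr::expand_grid(M0 = M0, M1 = M1, theta = theta) |>
    dplyr::mutate(
      r_min = r_min(.data$M0, .data$M1, .data$theta),
      curve = sprintf("M1 = %g, theta = %g", .data$M1, .data$theta)
    )
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$M0, y = .data$r_min,
                                     colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(
      x = "M0 (focal-deme scaled migration)", y = "r_min",
      colour = NULL,
      title = "Minimum deme-0 share for negative deme-specific indices"
    ) +
    ggplot2::theme_minimal()
}
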