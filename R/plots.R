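#' Plot a fitted descriptive model
#'
#' Observed vs predicted perceived weight, with the identity line.
#'
#' @param object A `swi_descriptive_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.swi_descriptive_fit <- function(object, ...) {
  d <- tibble::tibble(observed = object$fitted + object$residuals,
                      predicted = object$fitted)
  ggplot2::ggplot(d, ggplot2::aes(.data$predicted, .data$observed)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "red") +
    ggplot2::labs(x = "Predicted perceived weight (g)",
                  y = "Observed (normalised) estimate (g)",
                  title = sprintf("Descriptive model: R² = %.3f", object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Plot the density influence implied by a coefficient set
#'
#' The effective density coefficients as a function of weight difference:
#' large near zero weight difference (the size-weight-illusion regime),
#' shrinking to `beta2` (judged) and 0 (other) as the difference grows.
#'
#' @param coeffs A [descriptive_coefficients()] vector.
#' @param delta_w Weight differences (g) to display.
#' @return A ggplot object.
#' @export
plot_density_influence <- function(coeffs, delta_w = seq(0, 400, by = 2)) {
  density_influence(coeffs, delta_w) |>
    tidyr::pivot_longer(c("judged", "other"), names_to = "object",
                        values_to = "coefficient") |>
    ggplot2::ggplot(ggplot2::aes(.data$delta_w, .data$coefficient,
                                 colour = .data$object)) +
    ggplot2::geom_line(linewidth = 1) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::labs(x = "|weight difference| (g)",
                  y = "Effective density coefficient (g per g/cm³)") +
    ggplot2::theme_minimal()
}

#' Plot a bias field
#'
#' Arrows from the true log weight ratio to the mean perceived log weight
#' ratio for each pair, over the (log volume ratio, log weight ratio) plane;
#' the dashed identity line marks equal density.
#'
#' @param object A `swi_bias_field`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.swi_bias_field <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$logV_ratio, .data$logW_ratio)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "red") +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$logV_ratio,
                                       yend = .data$logW_ratio + .data$bias),
                          arrow = ggplot2::arrow(length = ggplot2::unit(1.5, "mm")),
                          colour = "grey30") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "log volume ratio", y = "log weight ratio") +
    ggplot2::theme_minimal()
}

#' Plot a fitted efficient-coding ratio model
#'
#' Empirical vs predicted per-pair bias in log weight ratio.
#'
#' @param object A `swi_ratio_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.swi_ratio_fit <- function(object, ...) {
  d <- tibble::tibble(empirical = object$bias_field$bias,
                      predicted = object$predicted)
  ggplot2::ggplot(d, ggplot2::aes(.data$predicted, .data$empirical)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "red") +
    ggplot2::labs(x = "Predicted bias (log weight ratio)",
                  y = "Empirical bias",
                  title = sprintf("Efficient-coding ratio model: R² = %.3f",
                                  object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Plot a component ladder
#'
#' Variance explained as each model component is added greedily.
#'
#' @param object A `swi_component_ladder`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.swi_component_ladder <- function(object, ...) {
  d <- dplyr::mutate(object, component = factor(.data$component,
                                                levels = .data$component))
  ggplot2::ggplot(d, ggplot2::aes(.data$component, .data$r_squared)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Component added", y = expression(R^2)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
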