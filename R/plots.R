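#' Plot daily or cumulative budgets of a simulation period
#'
#' @param object A `period_result`.
#' @param what `"daily"` or `"cumulative"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.period_result <- function(object, what = c("cumulative", "daily"),
                                   ...) {
  what <- match.arg(what)
  df <- if (what == "daily") object$daily else object$cumulative
  long <- df |>
    dplyr::select("day", dplyr::starts_with("net_photo")) |>
    tidyr::pivot_longer(-"day", names_to = "class", names_prefix =
                          "net_photo_", values_to = "mol") |>
    dplyr::filter(.data$class != "plant" | TRUE)
  ggplot2::ggplot(long, ggplot2::aes(.data$day, .data$mol,
                                     colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "day after start of treatment",
                  y = sprintf("%s net photosynthesis (mol CO2 plant-1%s)",
                              what, if (what == "daily") " d-1" else ""),
                  colour = "shoot class") +
    ggplot2::theme_minimal()
}

#' Plot a fitted light-response curve
#'
#' @param object A `light_response_fit`.
#' @param ... Unused.
#' @return A ggplot of the data points and the fitted non-rectangular
#'   hyperbola.
#' @export
autoplot.light_response_fit <- function(object, ...) {
  p <- object$params
  grid <- tibble::tibble(I = seq(0, max(object$data$I), length.out = 200))
  grid$A <- net_photosynthesis(p, grid$I)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$I, .data$A)) +
    ggplot2::geom_line(data = grid, colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "incident PAR (umol m-2 s-1)",
                  y = "net photosynthesis (umol CO2 m-2 s-1)") +
    ggplot2::theme_minimal()
}

#' Relative-light profile of a traced scene
#'
#' Histogram of per-leaf relative incident light (Q/Q0) by shoot class.
#'
#' @param light A `light_result`.
#' @param bins Histogram bins.
#' @return A ggplot.
#' @export
plot_light_profile <- function(light, bins = 30) {
  leaves <- dplyr::filter(light$organs, .data$organ == "leaf") |>
    dplyr::mutate(q_rel = .data$incident_flux / light$incoming_par)
  ggplot2::ggplot(leaves, ggplot2::aes(.data$q_rel,
                                       fill = .data$shoot_class)) +
    ggplot2::geom_histogram(bins = bins, position = "identity",
                            alpha = 0.6) +
    ggplot2::labs(x = "relative incident light Q/Q0", y = "leaves",
                  fill = "shoot class") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
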