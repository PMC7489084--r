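#' Tidy a fitted light-response curve
#'
#' @param x A `light_response_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`,
#'   `fixed`).
#' @export
tidy.light_response_fit <- function(x, ...) {
  p <- x$params
  tibble::tibble(
    term = c("phi", "amax", "rd", "theta"),
    estimate = c(p$phi, p$amax, p$rd, p$theta),
    fixed = c(FALSE, FALSE, FALSE, TRUE))
}

#' One-row summary of a light-response fit
#'
#' @param x A `light_response_fit`.
#' @param ... Unused.
#' @return A tibble with `rmse`, `converged`, `degenerate`, `n`.
#' @export
glance.light_response_fit <- function(x, ...) {
  tibble::tibble(rmse = x$rmse, converged = x$converged,
                 degenerate = x$degenerate, n = x$n)
}

#' Tidy a simulation period result
#'
#' @param x A `period_result`.
#' @param ... Unused.
#' @return The daily budget in long form: `day`, `quantity` (absorbed_par or
#'   net_photo), `class`, `value` (mol per plant per day).
#' @export
tidy.period_result <- function(x, ...) {
  x$daily |>
    tidyr::pivot_longer(-"day", names_to = "name", values_to = "value") |>
    tidyr::separate_wider_regex(
      "name", patterns = c(quantity = "absorbed_par|net_photo", "_",
                           class = ".*"))
}

#' One-row summary of a simulation period
#'
#' @param x A `period_result`.
#' @param ... Unused.
#' @return A tibble with the treatment, days simulated, cumulative plant /
#'   upright / bent photosynthesis and the final bent fraction.
#' @export
glance.period_result <- function(x, ...) {
  fin <- utils::tail(x$cumulative, 1)
  tibble::tibble(
    treatment = x$scenario$treatment, days = x$days,
    net_photo_plant = fin$net_photo_plant,
    net_photo_upright = fin$net_photo_upright,
    net_photo_bent = fin$net_photo_bent,
    bent_fraction = fin$bent_fraction)
}
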