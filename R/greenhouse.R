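#' Greenhouse light-control configuration
#'
#' Transmission factors and control rules of a Venlo-type glasshouse with
#' supplemental high-pressure-sodium lighting and a shading screen. Lamps run
#' only inside the photoperiod and switch with hysteresis on outside global
#' radiation (on below `lamp_on_below`, off above `lamp_off_above`); the
#' screen closes above `screen_close_above` and opens below
#' `screen_open_below`.
#'
#' @param greenhouse_transmission Overall structure transmission (default 0.6).
#' @param screen_transmission Shading-screen transmission (default 0.7).
#' @param lamp_ppfd Lamp PAR at canopy level, umol m^-2 s^-1 (default 150).
#' @param lamp_on_below,lamp_off_above Lamp hysteresis thresholds, W m^-2.
#' @param screen_open_below,screen_close_above Screen hysteresis thresholds.
#' @param photoperiod `c(start_hour, end_hour)`, lamps allowed in
#'   `[start, end)` (default 2 to 21 h).
#' @param par_per_global Conversion from global radiation (W m^-2) to PAR
#'   (umol m^-2 s^-1), default 2.1 umol J^-1 (about half of global is PAR at
#'   4.57 umol J^-1).
#' @return A list of class `greenhouse_config`.
#' @export
greenhouse_config <- function(greenhouse_transmission = 0.6,
                              screen_transmission = 0.7, lamp_ppfd = 150,
                              lamp_on_below = 200, lamp_off_above = 300,
                              screen_open_below = 500,
                              screen_close_above = 600,
                              photoperiod = c(2, 21), par_per_global = 2.1) {
  stopifnot(lamp_on_below < lamp_off_above,
            screen_open_below < screen_close_above,
            greenhouse_transmission > 0, greenhouse_transmission <= 1,
            screen_transmission > 0, screen_transmission <= 1)
  structure(list(greenhouse_transmission = greenhouse_transmission,
                 screen_transmission = screen_transmission,
                 lamp_ppfd = lamp_ppfd, lamp_on_below = lamp_on_below,
                 lamp_off_above = lamp_off_above,
                 screen_open_below = screen_open_below,
                 screen_close_above = screen_close_above,
                 photoperiod = photoperiod,
                 par_per_global = par_per_global),
            class = "greenhouse_config")
}

# hysteresis state trajectories for the whole series; returns logical columns
control_series <- function(series, config) {
  g <- series$outside_global
  n <- length(g)
  hod <- series$hour_of_day
  in_photo <- hod >= config$photoperiod[1] & hod < config$photoperiod[2]
  lamps <- logical(n)
  screen <- logical(n)
  # initial states from the first value against the nearest threshold midpoint
  lamp_state <- g[1] < (config$lamp_on_below + config$lamp_off_above) / 2
  screen_state <- g[1] > (config$screen_open_below +
                            config$screen_close_above) / 2
  for (i in seq_len(n)) {
    if (g[i] < config$lamp_on_below) lamp_state <- TRUE
    if (g[i] > config$lamp_off_above) lamp_state <- FALSE
    if (g[i] > config$screen_close_above) screen_state <- TRUE
    if (g[i] < config$screen_open_below) screen_state <- FALSE
    lamps[i] <- lamp_state && in_photo[i]
    screen[i] <- screen_state
  }
  tibble::tibble(lamps_on = lamps, screen_closed = screen)
}

#' Lamp and screen state at one time point
#'
#' Replays the hysteresis control over the series up to time `t` and reports
#' the state there. Lamps are forced off outside the photoperiod.
#'
#' @param series Weather tibble with columns `time` (hours from series
#'   start), `hour_of_day` and `outside_global` (W m^-2).
#' @param config A [greenhouse_config()].
#' @param t Time (same units as `series$time`).
#' @return A list `(lamps_on, screen_closed)`.
#' @export
control_state <- function(series, config, t) {
  i <- findInterval(t, series$time)
  if (i < 1 || t > max(series$time)) stop("t outside the weather series")
  st <- control_series(series[seq_len(i), ], config)
  list(lamps_on = st$lamps_on[i], screen_closed = st$screen_closed[i])
}

#' PAR inside the greenhouse from outside global radiation
#'
#' Applies the greenhouse transmission, the screen transmission when closed,
#' the global-to-PAR conversion, and adds the lamp PAR when lamps are on:
#' `inside = outside * par_per_global * tau_gh * (tau_screen if closed) +
#' lamp_ppfd * lamps_on`.
#'
#' @inheritParams control_state
#' @return A list with `fine` (the 5-min series plus `lamps_on`,
#'   `screen_closed`, `inside_par`) and `hourly` (tibble `day, hour,
#'   inside_par` of hourly means).
#' @export
inside_par <- function(series, config = greenhouse_config()) {
  st <- control_series(series, config)
  tau <- config$greenhouse_transmission *
    ifelse(st$screen_closed, config$screen_transmission, 1)
  par <- pmax(0, series$outside_global * config$par_per_global * tau) +
    config$lamp_ppfd * st$lamps_on
  fine <- dplyr::bind_cols(series, st)
  fine$inside_par <- par
  hourly <- fine |>
    dplyr::mutate(day = floor(.data$time / 24) + 1,
                  hour = floor(.data$hour_of_day)) |>
    dplyr::group_by(.data$day, .data$hour) |>
    dplyr::summarise(inside_par = mean(.data$inside_par), .groups = "drop")
  list(fine = fine, hourly = hourly)
}

#' Mean inside PAR over the photoperiod
#'
#' @param series,config As in [inside_par()].
#' @return Mean of the 5-min inside PAR over photoperiod time steps.
#' @export
photoperiod_mean_par <- function(series, config = greenhouse_config()) {
  out <- inside_par(series, config)$fine
  keep <- out$hour_of_day >= config$photoperiod[1] &
    out$hour_of_day < config$photoperiod[2]
  mean(out$inside_par[keep])
}
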