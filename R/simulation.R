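#' Scenario description for a simulation run
#'
#' Bundles the knobs of a growth-cycle simulation: treatment, optional
#' bent-LAI override, upright shoot count, mixed developmental stages,
#' ground reflectance, direct-light fraction and bent-leaf angle model.
#'
#' @param treatment `"0B"`, `"1B"` or `"3B"`.
#' @param bent_lai_override Optional bent-shoot LAI replacing the treatment
#'   default (not allowed for 0B).
#' @param upright_shoot_count 4, 6 or 8 upright shoots per plant.
#' @param mixed_stages Assemble upright shoots from parameter sets of
#'   different measurement days (steady mixed-stage canopy).
#' @param ground_reflectance Ground reflectance fraction.
#' @param direct_fraction Fraction of incoming light treated as direct.
#' @param direct_elevation Elevation of the direct beam, degrees.
#' @param angle_model Bent-leaf angle model.
#' @return A list of class `scenario`.
#' @export
scenario <- function(treatment = "3B", bent_lai_override = NULL,
                     upright_shoot_count = 4, mixed_stages = FALSE,
                     ground_reflectance = 0.5, direct_fraction = 0,
                     direct_elevation = 45, angle_model = "spherical") {
  stopifnot(treatment %in% c("0B", "1B", "3B"),
            upright_shoot_count %in% c(4, 6, 8))
  if (treatment == "0B" && !is.null(bent_lai_override)) {
    stop("bent_lai_override is inconsistent with treatment 0B")
  }
  structure(list(treatment = treatment,
                 bent_lai_override = bent_lai_override,
                 upright_shoot_count = upright_shoot_count,
                 mixed_stages = mixed_stages,
                 ground_reflectance = ground_reflectance,
                 direct_fraction = direct_fraction,
                 direct_elevation = direct_elevation,
                 angle_model = angle_model),
            class = "scenario")
}

# per-plant bent-shoot leaf areas (cm^2) for a scenario at the given density
bent_areas_for <- function(scn, density, bent_lai = c("1B" = 1.2, "3B" = 3.6)) {
  n_bent <- c("0B" = 0, "1B" = 1, "3B" = 3)[[scn$treatment]]
  if (n_bent == 0) return(NULL)
  lai <- if (!is.null(scn$bent_lai_override)) {
    scn$bent_lai_override
  } else {
    bent_lai[[scn$treatment]]
  }
  rep(lai / density * 1e4 / n_bent, n_bent)
}

#' Integrate one day of photosynthesis from a traced scene
#'
#' One geometric trace per rebuilt scene is reused across the hours of the
#' photoperiod: for fixed geometry the transport operator is linear in the
#' source strength, so per-leaf flux densities scale with that hour's PAR.
#' Leaf capacity follows the relative-light gradient (computed once from the
#' reference trace); hourly net photosynthesis per leaf comes from the
#' non-rectangular hyperbola on the scaled incident flux density and is
#' summed over the photoperiod into mol CO2 per plant per day by shoot
#' class, together with absorbed PAR.
#'
#' @param scene A `canopy_scene`.
#' @param hourly_par Numeric vector of photoperiod-hour PAR values
#'   (umol m^-2 s^-1), one per hour of the light period.
#' @param gradient An [amax_gradient()].
#' @param light Optional precomputed `light_result` for `scene` (traced at
#'   any reference PAR); if missing it is traced here.
#' @param day Day label for the budget row.
#' @param ... Passed to [trace()] when `light` is missing.
#' @return A one-row `daily budget` tibble: `day`, then absorbed PAR and net
#'   photosynthesis (mol per plant per day) for upright, bent and plant.
#' @export
simulate_day <- function(scene, hourly_par, gradient = amax_gradient(),
                         light = NULL, day = scene$day, ...) {
  if (any(hourly_par < 0)) stop("hourly PAR must be non-negative")
  if (is.null(light)) light <- trace(scene, ...)
  leaves <- assign_leaf_parameters(scene, light, gradient)
  n_plants <- prod(scene$domain$layout)
  rel_inc <- leaves$incident_flux / light$incoming_par   # per unit PAR
  rel_abs <- leaves$absorbed_flux / light$incoming_par
  upright <- leaves$shoot_class == "upright"
  a_net <- c(upright = 0, bent = 0)
  a_par <- c(upright = 0, bent = 0)
  for (p in hourly_par) {
    I <- rel_inc * p
    s <- leaves$phi * I + leaves$amax
    disc <- pmax(0, s^2 - 4 * leaves$theta * leaves$amax * leaves$phi * I)
    A <- (s - sqrt(disc)) / (2 * leaves$theta) - leaves$rd
    contrib <- A * leaves$area_m2 * 3600 / 1e6      # mol CO2 per hour
    par_abs <- rel_abs * p * leaves$area_m2 * 3600 / 1e6
    a_net["upright"] <- a_net["upright"] + sum(contrib[upright])
    a_net["bent"] <- a_net["bent"] + sum(contrib[!upright])
    a_par["upright"] <- a_par["upright"] + sum(par_abs[upright])
    a_par["bent"] <- a_par["bent"] + sum(par_abs[!upright])
  }
  pu <- a_par[["upright"]] / n_plants
  pb <- a_par[["bent"]] / n_plants
  nu <- a_net[["upright"]] / n_plants
  nb <- a_net[["bent"]] / n_plants
  tibble::tibble(
    day = day,
    absorbed_par_upright = pu, absorbed_par_bent = pb,
    absorbed_par_plant = pu + pb,
    net_photo_upright = nu, net_photo_bent = nb,
    net_photo_plant = nu + nb)
}

#' Simulate a growth cycle
#'
#' Rebuilds the scene every `rebuild_every` days (days 1, 4, ..., up to
#' `freeze_day`, then frozen), traces each rebuilt geometry once, and
#' integrates hourly photosynthesis per day from the weather-derived inside
#' PAR. Architecture for days before the first measurement day is clamped to
#' the earliest measured parameter set (nothing earlier exists to
#' interpolate from).
#'
#' @param scn A [scenario()].
#' @param db Architecture database.
#' @param weather Weather series (see [generate_weather()]); must cover
#'   `days` days.
#' @param days Number of days to simulate (default 35).
#' @param rebuild_every Scene rebuild interval in days (default 3).
#' @param freeze_day Last rebuild day (default 25).
#' @param gradient An [amax_gradient()].
#' @param config A [greenhouse_config()].
#' @param density Plants per m^2.
#' @param layout,replication Plot layout (see [build_canopy()]).
#' @param bent_lai Named defaults for bent LAI per treatment.
#' @param n_rays Rays per trace.
#' @param seed Integer seed; the run is deterministic given (inputs, seed).
#' @param optics An [optical_properties()].
#' @return A list of class `period_result` with `daily` (tibble of daily
#'   budgets), `cumulative` (running sums plus `bent_fraction`) and the
#'   call's configuration.
#' @export
simulate_period <- function(scn, db, weather, days = 35, rebuild_every = 3,
                            freeze_day = 25, gradient = amax_gradient(),
                            config = greenhouse_config(), density = 7.5,
                            layout = c(2, 9), replication = 10,
                            bent_lai = c("1B" = 1.2, "3B" = 3.6),
                            n_rays = 2e5, seed = 1,
                            optics = optical_properties()) {
  stopifnot(inherits(scn, "scenario"))
  hourly <- inside_par(weather, config)$hourly
  hourly <- dplyr::filter(hourly, .data$hour >= config$photoperiod[1],
                          .data$hour < config$photoperiod[2])
  if (max(hourly$day) < days) stop("weather series shorter than ", days,
                                   " days")
  dome <- build_sky_dome(direct_fraction = scn$direct_fraction,
                         direct_elevation = scn$direct_elevation)
  first_meas <- min(db$day)
  rebuild_days <- seq(1, min(freeze_day, days), by = rebuild_every)
  scene <- NULL
  light <- NULL
  daily <- vector("list", days)
  for (d in seq_len(days)) {
    if (d %in% rebuild_days) {
      build_day <- max(d, first_meas)  # clamp early days to first measurement
      sub_seed <- (seed * 1009 + d * 97) %% 2^30
      scene <- build_canopy(
        scn$treatment, build_day, db,
        bent_areas = bent_areas_for(scn, density, bent_lai),
        density = density, layout = layout, replication = replication,
        ground_reflectance = scn$ground_reflectance,
        angle_model = scn$angle_model,
        upright_shoot_count = scn$upright_shoot_count,
        mixed_stages = scn$mixed_stages, seed = sub_seed)
      light <- trace(scene, dome, incoming_par = 360, n_rays = n_rays,
                     seed = sub_seed + 1, optics = optics)
    }
    par_d <- dplyr::filter(hourly, .data$day == d)$inside_par
    daily[[d]] <- simulate_day(scene, par_d, gradient, light = light,
                               day = d)
  }
  daily <- dplyr::bind_rows(daily)
  cumulative <- daily |>
    dplyr::mutate(dplyr::across(-"day", cumsum)) |>
    dplyr::mutate(bent_fraction = ifelse(.data$net_photo_plant > 0,
                                         .data$net_photo_bent /
                                           .data$net_photo_plant, 0))
  structure(list(daily = daily, cumulative = cumulative, scenario = scn,
                 days = days, seed = seed),
            class = "period_result")
}

#' @export
print.period_result <- function(x, ...) {
  fin <- utils::tail(x$cumulative, 1)
  cat("<period_result>", x$scenario$treatment, "-", x$days, "days\n")
  cat(sprintf("  cumulative net photosynthesis: plant %.2f, upright %.2f, bent %.2f mol/plant\n",
              fin$net_photo_plant, fin$net_photo_upright, fin$net_photo_bent))
  cat(sprintf("  final bent fraction: %.2f\n", fin$bent_fraction))
  invisible(x)
}

#' Run a suite of scenarios and compare their budgets
#'
#' Time-course scenarios are run through [simulate_period()]; steady-state
#' scenarios (`mixed_stages = TRUE`) are computed from a single scene at the
#' mean photoperiod PAR (default 360 umol m^-2 s^-1) over one photoperiod.
#'
#' @param scenarios Named list of [scenario()] objects.
#' @param db,weather,... Passed to [simulate_period()].
#' @param steady_par Constant PAR for steady-state scenarios.
#' @param steady_hours Photoperiod hours for steady-state scenarios.
#' @return A tibble with one row per scenario: cumulative (or per-day) plant,
#'   upright and bent photosynthesis and the bent fraction.
#' @export
run_scenario_suite <- function(scenarios, db, weather = NULL,
                               steady_par = 360, steady_hours = 19, ...) {
  dots <- list(...)
  purrr::imap_dfr(scenarios, function(scn, name) {
    if (isTRUE(scn$mixed_stages)) {
      density <- dots$density %||% 7.5
      seed <- dots$seed %||% 1
      scene <- build_canopy(
        scn$treatment, day = max(db$day), db,
        bent_areas = bent_areas_for(scn, density,
                                    dots$bent_lai %||%
                                      c("1B" = 1.2, "3B" = 3.6)),
        density = density, layout = dots$layout %||% c(2, 9),
        replication = dots$replication %||% 10,
        ground_reflectance = scn$ground_reflectance,
        angle_model = scn$angle_model,
        upright_shoot_count = scn$upright_shoot_count,
        mixed_stages = TRUE, seed = seed)
      b <- simulate_day(scene, rep(steady_par, steady_hours),
                        dots$gradient %||% amax_gradient(),
                        dome = build_sky_dome(
                          direct_fraction = scn$direct_fraction,
                          direct_elevation = scn$direct_elevation),
                        n_rays = dots$n_rays %||% 2e5, seed = seed + 1)
      tibble::tibble(
        scenario = name, treatment = scn$treatment,
        upright_shoots = scn$upright_shoot_count, steady_state = TRUE,
        net_photo_plant = b$net_photo_plant,
        net_photo_upright = b$net_photo_upright,
        net_photo_bent = b$net_photo_bent,
        bent_fraction = b$net_photo_bent / b$net_photo_plant)
    } else {
      res <- simulate_period(scn, db, weather, ...)
      fin <- utils::tail(res$cumulative, 1)
      tibble::tibble(
        scenario = name, treatment = scn$treatment,
        upright_shoots = scn$upright_shoot_count, steady_state = FALSE,
        net_photo_plant = fin$net_photo_plant,
        net_photo_upright = fin$net_photo_upright,
        net_photo_bent = fin$net_photo_bent,
        bent_fraction = fin$bent_fraction)
    }
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write daily and cumulative budgets to CSV
#'
#' @param result A `period_result`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_budget_csv <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(result$daily, file.path(dir, "daily_budget.csv"))
  readr::write_csv(result$cumulative, file.path(dir, "cumulative_budget.csv"))
  invisible(dir)
}
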