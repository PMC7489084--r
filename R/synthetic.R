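#' Target final architecture per treatment
#'
#' Published harvest means used as endpoints for the synthetic growth
#' trajectories, per treatment, with per-shoot variation derived from the
#' printed standard errors (sd over the 18 replicate shoots).
#'
#' @param treatment `"0B"`, `"1B"` or `"3B"`.
#' @return A list of final means and lognormal sdlog values.
#' @export
synthetic_targets <- function(treatment = c("0B", "1B", "3B")) {
  treatment <- match.arg(treatment)
  i <- c("0B" = 1, "1B" = 2, "3B" = 3)[[treatment]]
  t1 <- rose_table1()
  pick <- function(trait) {
    unlist(dplyr::filter(t1, .data$trait == !!trait)[, c("B0", "B1", "B3")],
           use.names = FALSE)[i]
  }
  sem <- function(trait) {
    dplyr::filter(t1, .data$trait == !!trait)$sem
  }
  # sd over the 18 replicate shoots ~ sem * sqrt(18); cv -> lognormal sdlog
  sdlog <- function(trait) {
    cv <- sem(trait) * sqrt(18) / pick(trait)
    sqrt(log(1 + cv^2))
  }
  list(treatment = treatment,
       stem_length_cm = pick("stem_length_cm"),
       stem_diameter_mm = pick("stem_diameter_mm"),
       leaf_number = round(pick("leaf_number")),
       shoot_leaf_area_cm2 = pick("shoot_leaf_area_cm2"),
       flower_width_cm = pick("flower_width_cm"),
       sdlog_leaf_area = sdlog("shoot_leaf_area_cm2"),
       sdlog_stem_length = sdlog("stem_length_cm"),
       bent_lai = c("0B" = 0, "1B" = 1.2, "3B" = 3.6)[[treatment]])
}

# shoot-level logistic development: fraction of final size (area basis),
# midpoint day 12, 95% of final at day 25; normalised to 1 at day 25
growth_fraction <- function(day, t_mid = 12, frac_at_25 = 0.95) {
  tau <- (25 - t_mid) / log(frac_at_25 / (1 - frac_at_25))
  l <- function(d) 1 / (1 + exp(-(d - t_mid) / tau))
  l(day) / l(25)
}

#' Generate a synthetic architecture database
#'
#' Per-shoot logistic growth trajectories whose day-25 values reach the
#' treatment's published harvest means, with lognormal between-shoot
#' variation scaled to the printed standard errors. Leaves appear
#' progressively up the shoot (about five visible at day 6, all by day 19);
#' leaf dimensions are sized so the allometric area of the visible leaves
#' sums to the shoot leaf-area trajectory. All per-organ trajectories are
#' non-decreasing and the database is a pure function of (parameters, seed).
#'
#' @param treatment `"0B"`, `"1B"` or `"3B"`.
#' @param n_shoots Number of shoots in the database (default 18).
#' @param measurement_days Days on which parameter sets exist (default
#'   6, 9, 14, 19, 25).
#' @param targets Endpoint targets, see [synthetic_targets()].
#' @param coef Allometric leaf-area coefficient.
#' @param seed Integer seed.
#' @return An architecture database tibble (see
#'   [interpolate_architecture()] for the column schema).
#' @export
generate_architecture_db <- function(treatment = "3B", n_shoots = 18,
                                     measurement_days = c(6, 9, 14, 19, 25),
                                     targets = synthetic_targets(treatment),
                                     coef = 0.7, seed = 1) {
  stopifnot(n_shoots >= 1)
  n_leaf <- targets$leaf_number
  # rank profile: mid-shoot leaves and internodes are the largest
  w <- sin(pi * (seq_len(n_leaf) - 0.5) / n_leaf)^0.7 + 0.3
  w <- w / sum(w)
  with_seed(seed, {
    out <- vector("list", n_shoots)
    for (s in seq_len(n_shoots)) {
      f_area <- rlnorm(1, -targets$sdlog_leaf_area^2 / 2,
                       targets$sdlog_leaf_area)
      f_len <- rlnorm(1, -targets$sdlog_stem_length^2 / 2,
                      targets$sdlog_stem_length)
      area_final <- targets$shoot_leaf_area_cm2 * f_area * w
      intl_final <- targets$stem_length_cm * f_len * w
      diam_final <- targets$stem_diameter_mm *
        rlnorm(n_leaf, -0.05^2 / 2, 0.05)
      leaflet_n <- sample(c(3, 5, 7), n_leaf, replace = TRUE,
                          prob = c(0.2, 0.6, 0.2))
      incl <- runif(n_leaf, 20, 50)
      fw_final <- targets$flower_width_cm * rlnorm(1, -0.05^2 / 2, 0.05)
      rows <- vector("list", length(measurement_days))
      for (j in seq_along(measurement_days)) {
        d <- measurement_days[j]
        g <- growth_fraction(d)
        n_vis <- min(n_leaf, ceiling(n_leaf * min(1, d / 18)))
        vis <- seq_len(n_leaf) <= n_vis
        area_d <- area_final * g * vis
        len_d <- sqrt(area_d / (0.6 * coef))  # width = 0.6 * length
        rows[[j]] <- tibble::tibble(
          shoot_id = s, day = d, rank = seq_len(n_leaf),
          internode_length_cm = intl_final * g * vis,
          internode_diameter_mm = pmax(diam_final * sqrt(g), 1) * vis,
          leaf_length_cm = len_d,
          leaf_width_cm = 0.6 * len_d,
          leaflet_count = leaflet_n,
          leaf_inclination_deg = incl,
          flower_width_cm = fw_final * max(0, min(1, (d - 15) / 10)))
      }
      out[[s]] <- dplyr::bind_rows(rows)
    }
  })
  dplyr::bind_rows(out)
}

#' Generate synthetic light-response curves
#'
#' Points on the non-rectangular hyperbola at the requested light levels,
#' plus Gaussian noise on the assimilation rate.
#'
#' @param params A [photo_params()].
#' @param light_levels Incident PAR levels; default is the nine-step
#'   measurement series 1500, 1100, 700, 400, 200, 150, 100, 75, 50.
#' @param noise_sd Gaussian noise sd on A, umol m^-2 s^-1.
#' @param n_curves Number of replicate curves.
#' @param seed Integer seed.
#' @return Tibble with `curve_id`, `I`, `A`.
#' @export
generate_light_response <- function(params = photo_params(),
                                    light_levels = c(1500, 1100, 700, 400,
                                                     200, 150, 100, 75, 50),
                                    noise_sd = 0, n_curves = 1, seed = 1) {
  stopifnot(noise_sd >= 0, n_curves >= 1)
  a0 <- net_photosynthesis(params, light_levels)
  with_seed(seed, {
    out <- purrr::map_dfr(seq_len(n_curves), function(k) {
      tibble::tibble(curve_id = k, I = light_levels,
                     A = a0 + rnorm(length(light_levels), 0, noise_sd))
    })
  })
  out
}

#' Generate a synthetic outside-radiation weather series
#'
#' Half-sinusoid daily global radiation (daylight 06:00-21:00, zero at
#' night) at 5-min resolution with lognormal day-to-day amplitude variation.
#' The amplitude scale is calibrated (by root finding on the full
#' greenhouse-processing chain, including lamp and screen switching) so the
#' photoperiod-mean inside PAR matches `mean_photoperiod_par_target`.
#'
#' @param n_days Number of days.
#' @param mean_photoperiod_par_target Target photoperiod-mean inside PAR,
#'   umol m^-2 s^-1 (default 360).
#' @param config A [greenhouse_config()] used for the calibration.
#' @param day_sdlog Day-to-day lognormal sdlog of the amplitude.
#' @param seed Integer seed.
#' @return A weather tibble: `time` (hours since start), `day`,
#'   `hour_of_day`, `outside_global` (W m^-2).
#' @export
generate_weather <- function(n_days = 35, mean_photoperiod_par_target = 360,
                             config = greenhouse_config(), day_sdlog = 0.35,
                             seed = 1) {
  stopifnot(n_days >= 1)
  step <- 5 / 60
  time <- seq(0, n_days * 24 - step, by = step)
  hod <- time %% 24
  day <- floor(time / 24) + 1
  sunrise <- 6
  sunset <- 21
  daylight <- hod >= sunrise & hod <= sunset
  shape <- ifelse(daylight,
                  sin(pi * (hod - sunrise) / (sunset - sunrise)), 0)
  with_seed(seed, {
    amp_day <- rlnorm(n_days, -day_sdlog^2 / 2, day_sdlog)
  })
  base <- shape * amp_day[day]
  mk <- function(scale) {
    tibble::tibble(time = time, day = day, hour_of_day = hod,
                   outside_global = scale * base)
  }
  f <- function(scale) {
    photoperiod_mean_par(mk(scale), config) - mean_photoperiod_par_target
  }
  # lamps alone bound the mean from below; find the bracketing amplitude
  lo <- 1
  hi <- 2000
  if (f(lo) > 0) lo <- 1e-3
  scale <- uniroot(f, c(lo, hi), tol = 1e-4)$root
  mk(scale)
}
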