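#' Printed harvest table for the bending experiment
#'
#' Architectural traits, fresh weight and organ dry weights of individual
#' upright shoots at harvest (35 d after the start of treatment), per
#' treatment (0, 1 or 3 bent shoots per plant). These published means are
#' inputs to the derived-metric and translocation computations.
#'
#' @return A tibble with `trait`, `B0`, `B1`, `B3`, `sem`.
#' @export
rose_table1 <- function() {
  tibble::tribble(
    ~trait, ~B0, ~B1, ~B3, ~sem,
    "stem_length_cm", 76, 85, 88, 1.82,
    "stem_diameter_mm", 6.09, 7.03, 7.67, 0.19,
    "stem_biomass_per_length_g_cm", 0.063, 0.084, 0.101, 0.01,
    "leaf_number", 14, 14, 14, 0.44,
    "shoot_leaf_area_cm2", 1000, 1198, 1412, 44.10,
    "leaf_mass_per_area_g_m2", 41.4, 43.6, 42.9, 2.46,
    "flower_width_cm", 11.9, 12.5, 12.6, 6.57,
    "shoot_fresh_weight_g", 58, 74, 85, 4.73,
    "shoot_dry_weight_g", 12.4, 16.7, 19.7, 1.38,
    "stem_dry_weight_g", 4.8, 7.2, 8.9, 0.61,
    "leaf_dry_weight_g", 4.1, 5.2, 6.1, 0.43,
    "flower_dry_weight_g", 3.5, 4.3, 4.8, 0.37
  )
}

#' Fractional dry-weight increase of upright shoots over the no-bent baseline
#'
#' `f_dwt = (d - d0B) / d0B`; may be negative if shoots are lighter than the
#' baseline.
#'
#' @param upright_dwt Upright shoot dry weight, g per plant (1B or 3B).
#' @param upright_dwt_0B Baseline (0B) upright shoot dry weight (> 0).
#' @return The fractional increase (vectorised).
#' @export
fraction_dwt_increase <- function(upright_dwt, upright_dwt_0B) {
  if (any(upright_dwt_0B <= 0)) stop("baseline dry weight must be positive")
  (upright_dwt - upright_dwt_0B) / upright_dwt_0B
}

#' Assimilates accumulated in upright shoots with a bent canopy
#'
#' Assuming the fractional assimilate increase equals the fractional
#' dry-weight increase: `Upright_ass = (1 + f_dwt) * Upright_ass_0B`, where
#' the baseline equals the simulated cumulative net photosynthesis of 0B
#' upright shoots.
#'
#' @param f_dwt Fractional dry-weight increase (see
#'   [fraction_dwt_increase()]).
#' @param upright_ass_0B Baseline accumulated assimilates, mol per plant.
#' @return Accumulated assimilates, mol per plant.
#' @export
upright_assimilates <- function(f_dwt, upright_ass_0B) {
  stopifnot(all(upright_ass_0B >= 0))
  (1 + f_dwt) * upright_ass_0B
}

#' Fraction of bent-shoot photosynthate translocated to upright shoots
#'
#' `f_trans = (Upright_ass - Upright_photo) / Bent_photo`: the share of
#' bent-shoot photosynthesis needed to account for the upright-shoot
#' assimilate gain beyond the uprights' own photosynthesis.
#'
#' @param upright_ass Accumulated assimilates in upright shoots, mol/plant.
#' @param upright_photo Simulated cumulative upright-shoot photosynthesis.
#' @param bent_photo Simulated cumulative bent-shoot photosynthesis (> 0).
#' @return The translocated fraction (vectorised).
#' @export
fraction_translocated <- function(upright_ass, upright_photo, bent_photo) {
  if (any(bent_photo <= 0)) stop("bent photosynthesis must be positive")
  (upright_ass - upright_photo) / bent_photo
}

#' Translocation accounting from relative quantities
#'
#' Composes the dry-weight, assimilate and translocation steps for a set of
#' treatments with a common 0B baseline. Baseline cumulative upright
#' photosynthesis is normalised to `upright_ass_0B`; per treatment the plant
#' total (relative to the 0B upright total) is split into upright and bent
#' parts via the bent contribution fraction.
#'
#' @param treatments Tibble with columns `treatment`, `upright_dwt`,
#'   `plant_photo_rel` (plant cumulative photosynthesis relative to 0B
#'   upright = 1) and `bent_share` (bent fraction of the plant total).
#' @param upright_dwt_0B Baseline upright dry weight, g per plant.
#' @param upright_ass_0B Baseline accumulated assimilates (default 1,
#'   normalised units).
#' @return The input tibble with `f_dwt`, `upright_ass`, `upright_photo`,
#'   `bent_photo` and `f_trans` appended.
#' @export
translocation_summary <- function(treatments, upright_dwt_0B,
                                  upright_ass_0B = 1) {
  treatments |>
    dplyr::mutate(
      f_dwt = fraction_dwt_increase(.data$upright_dwt, upright_dwt_0B),
      upright_ass = upright_assimilates(.data$f_dwt, upright_ass_0B),
      upright_photo = .data$plant_photo_rel * (1 - .data$bent_share),
      bent_photo = .data$plant_photo_rel * .data$bent_share,
      f_trans = fraction_translocated(.data$upright_ass,
                                      .data$upright_photo,
                                      .data$bent_photo))
}

#' Relative root-mean-square error
#'
#' RMSE of simulated vs measured values divided by the mean of the measured
#' values; invariant under a common positive rescaling of both vectors.
#'
#' @param simulated,measured Equal-length numeric vectors (n >= 2; measured
#'   mean nonzero).
#' @return The rRMSE (>= 0; 0 iff the vectors agree elementwise).
#' @export
rrmse <- function(simulated, measured) {
  stopifnot(length(simulated) == length(measured), length(measured) >= 2)
  xb <- mean(measured)
  if (xb == 0) stop("mean of measured values is zero; rRMSE undefined")
  sqrt(mean((simulated - measured)^2)) / xb
}

#' Squared Pearson correlation of paired values
#'
#' @inheritParams rrmse
#' @return r^2 in [0, 1].
#' @export
r_squared <- function(simulated, measured) {
  stats::cor(simulated, measured)^2
}

#' Derived metrics from a harvest table
#'
#' Recomputes, per treatment: percent increases vs the 0B baseline for dry
#' and fresh weight, stem biomass per unit length, and organ allocation
#' fractions (organ dry weight / shoot dry weight). Percentages follow the
#' round-half-up-to-integer convention of the published tables.
#'
#' @param table A harvest table in the layout of [rose_table1()].
#' @return A tibble with one row per treatment and the derived columns
#'   `dwt_increase_pct`, `fwt_increase_pct`, `stem_per_length_g_cm`,
#'   `stem_fraction`, `leaf_fraction`, `flower_fraction`.
#' @export
table1_derived <- function(table = rose_table1()) {
  get <- function(trait) {
    row <- dplyr::filter(table, .data$trait == !!trait)
    if (nrow(row) != 1) stop("missing trait in table: ", trait)
    c(row$B0, row$B1, row$B3)
  }
  dwt <- get("shoot_dry_weight_g")
  fwt <- get("shoot_fresh_weight_g")
  stem <- get("stem_dry_weight_g")
  leaf <- get("leaf_dry_weight_g")
  flower <- get("flower_dry_weight_g")
  slen <- get("stem_length_cm")
  tibble::tibble(
    treatment = c("0B", "1B", "3B"),
    shoot_dwt_g = dwt,
    dwt_increase_pct = round_half_up(100 * fraction_dwt_increase(dwt, dwt[1])),
    fwt_increase_pct = round_half_up(100 * fraction_dwt_increase(fwt, fwt[1])),
    stem_per_length_g_cm = round_half_up(stem / slen, 3),
    stem_fraction = round_half_up(stem / dwt, 2),
    leaf_fraction = round_half_up(leaf / dwt, 2),
    flower_fraction = round_half_up(flower / dwt, 2)
  )
}
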