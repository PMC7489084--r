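#' Optical properties of canopy surfaces
#'
#' Broadband PAR reflectance and transmittance. Rose-leaf defaults come from
#' spectrophotometric measurements (reflectance 0.08, transmittance 0.06);
#' stems and flowers share the leaf reflectance but transmit nothing.
#'
#' @param leaf_reflectance,leaf_transmittance Leaf optical fractions.
#' @param stem_reflectance,stem_transmittance Stem (and flower) fractions.
#' @param ground_reflectance Ground reflectance (0-1); a scene's own value
#'   takes precedence when tracing unless overridden.
#' @return A list of class `optical_properties`.
#' @export
optical_properties <- function(leaf_reflectance = 0.08,
                               leaf_transmittance = 0.06,
                               stem_reflectance = 0.08,
                               stem_transmittance = 0,
                               ground_reflectance = 0.5) {
  vals <- c(leaf_reflectance, leaf_transmittance, stem_reflectance,
            stem_transmittance, ground_reflectance)
  stopifnot(all(vals >= 0), all(vals <= 1),
            leaf_reflectance + leaf_transmittance <= 1,
            stem_reflectance + stem_transmittance <= 1)
  structure(list(leaf_reflectance = leaf_reflectance,
                 leaf_transmittance = leaf_transmittance,
                 stem_reflectance = stem_reflectance,
                 stem_transmittance = stem_transmittance,
                 ground_reflectance = ground_reflectance),
            class = "optical_properties")
}

#' Discretised sky dome of diffuse light
#'
#' The hemisphere is divided into zenith rings, each carrying directions at
#' equal azimuth spacing; weights are the fraction of horizontal-plane flux
#' from each direction. Gradation `"SOC"` is the standard overcast sky
#' (radiance proportional to `(1 + 2 cos(theta)) / 3`, brightest at zenith);
#' `"uniform"` is an isotropic sky. A direct-light fraction can be added as a
#' single extra direction at a fixed elevation (a sensitivity knob; no solar
#' ephemeris is modelled).
#'
#' @param n_directions Approximate number of diffuse directions (default 72).
#' @param gradation `"SOC"` or `"uniform"`.
#' @param direct_fraction Fraction (0-1) of flux from the direct direction.
#' @param direct_elevation Elevation (degrees above horizon) of the direct
#'   direction; required when `direct_fraction > 0`.
#' @param direct_azimuth Azimuth (degrees) of the direct direction.
#' @return A `sky_dome`: tibble of `dx, dy, dz` unit direction components
#'   (pointing downward, `dz < 0`), `weight`, `zenith_deg`, plus attributes.
#' @export
build_sky_dome <- function(n_directions = 72,
                           gradation = c("SOC", "uniform"),
                           direct_fraction = 0, direct_elevation = NULL,
                           direct_azimuth = 0) {
  gradation <- match.arg(gradation)
  stopifnot(n_directions >= 1, direct_fraction >= 0, direct_fraction <= 1)
  if (direct_fraction > 0 && is.null(direct_elevation)) {
    stop("direct_fraction > 0 requires a direct_elevation")
  }
  n_rings <- max(1L, round(sqrt(n_directions / 2)))
  edges <- seq(0, pi / 2, length.out = n_rings + 1)
  mid <- (edges[-1] + edges[-(n_rings + 1)]) / 2
  # directions per ring proportional to sin(theta) (solid angle)
  n_az <- pmax(1L, round(n_directions * sin(mid) / sum(sin(mid))))
  rad <- function(th) switch(gradation,
                             SOC = (1 + 2 * cos(th)) / 3,
                             uniform = rep(1, length(th)))
  rows <- list()
  for (i in seq_len(n_rings)) {
    th <- mid[i]
    # flux through the horizontal from this ring: radiance * cos * solid angle
    wring <- rad(th) * cos(th) * (cos(edges[i]) - cos(edges[i + 1])) * 2 * pi
    az <- (seq_len(n_az[i]) - 0.5) * 2 * pi / n_az[i]
    rows[[i]] <- tibble::tibble(
      dx = sin(th) * cos(az), dy = sin(th) * sin(az), dz = -cos(th),
      weight = wring / n_az[i], zenith_deg = th * 180 / pi, direct = FALSE)
  }
  dome <- dplyr::bind_rows(rows)
  dome$weight <- dome$weight / sum(dome$weight) * (1 - direct_fraction)
  if (direct_fraction > 0) {
    el <- deg2rad(direct_elevation)
    azr <- deg2rad(direct_azimuth)
    dome <- dplyr::bind_rows(dome, tibble::tibble(
      dx = cos(el) * cos(azr), dy = cos(el) * sin(azr), dz = -sin(el),
      weight = direct_fraction, zenith_deg = 90 - direct_elevation,
      direct = TRUE))
  }
  structure(dome, class = c("sky_dome", class(dome)),
            gradation = gradation, direct_fraction = direct_fraction)
}

#' Trace diffuse sky light through a canopy scene
#'
#' Monte Carlo ray tracing: rays are launched from a plane above the canopy
#' at positions uniform over the (toroidally wrapped) plot with directions
#' drawn from the sky dome; at every leaf/stem hit the ray is reflected,
#' transmitted or absorbed with the surface's optical probabilities
#' (Lambertian scattering), and the ground reflects or absorbs likewise.
#' Sampling the event outcome at each interaction conserves energy exactly:
#' every ray's weight ends in a leaf, the ground, or escapes upward.
#'
#' @param scene A `canopy_scene`.
#' @param dome A `sky_dome` (default: 72-direction SOC dome).
#' @param incoming_par Above-canopy PAR on the horizontal, umol m^-2 s^-1.
#' @param n_rays Number of rays (>= 1000).
#' @param seed Integer seed (deterministic result for fixed seed).
#' @param optics An [optical_properties()] object.
#' @param sensors Optional tibble of virtual sensors with columns
#'   `sensor_id, x, y, z, length, width` (cosine-corrected horizontal
#'   receivers of the given footprint, mimicking a line quantum sensor).
#' @return A `light_result`: list with `organs` (per-organ tibble adding
#'   `absorbed_flux` and `incident_flux` densities, umol m^-2 s^-1),
#'   `sensors` (readings, umol m^-2 s^-1), and an energy audit
#'   (`leaf_absorbed`, `ground_absorbed`, `escaped`, `total_emitted`,
#'   umol s^-1 over the plot).
#' @export
trace <- function(scene, dome = build_sky_dome(), incoming_par = 360,
                  n_rays = 2e5, seed = 1, optics = optical_properties(),
                  sensors = NULL) {
  stopifnot(inherits(scene, "canopy_scene"), n_rays >= 1e3,
            incoming_par >= 0)
  org <- scene$organs
  refl <- ifelse(org$organ == "leaf", optics$leaf_reflectance,
                 optics$stem_reflectance)
  tran <- ifelse(org$organ == "leaf", optics$leaf_transmittance,
                 optics$stem_transmittance)
  # make the geometry truly periodic: triangles protruding beyond a domain
  # wall get a wrapped copy so the toroidal domain has no thinned edges
  per <- wrap_periodic(scene$tri, scene$tri_organ, scene$domain$lx,
                       scene$domain$ly)
  zmax_geom <- if (nrow(per$tri) > 0) max(per$tri[, c(3, 6, 9)]) else 1
  smat <- matrix(0, 0, 5)
  if (!is.null(sensors) && nrow(sensors) > 0) {
    smat <- cbind(sensors$x - sensors$length / 2,
                  sensors$x + sensors$length / 2,
                  sensors$y - sensors$width / 2,
                  sensors$y + sensors$width / 2, sensors$z)
    zmax_geom <- max(zmax_geom, max(sensors$z))
  }
  z_top <- zmax_geom + 0.05
  gr <- scene$domain$ground_reflectance
  if (is.null(gr)) gr <- optics$ground_reflectance
  res <- trace_rays_cpp(per$tri, as.integer(per$tri_organ), refl, tran,
                        scene$domain$lx, scene$domain$ly, z_top, gr,
                        as.matrix(dome[, c("dx", "dy", "dz")]), dome$weight,
                        smat, incoming_par, as.integer(n_rays), seed)
  org$absorbed_flux <- res$organ_absorbed / org$area_m2
  org$incident_flux <- res$organ_incident / org$area_m2
  sens_out <- NULL
  if (nrow(smat) > 0) {
    area <- (smat[, 2] - smat[, 1]) * (smat[, 4] - smat[, 3])
    sens_out <- dplyr::mutate(sensors, reading = res$sensor_flux / area)
  }
  structure(list(
    organs = org, sensors = sens_out,
    leaf_absorbed = sum(res$organ_absorbed[org$organ == "leaf"]),
    other_absorbed = sum(res$organ_absorbed[org$organ != "leaf"]),
    ground_absorbed = res$ground_absorbed, escaped = res$escaped,
    total_emitted = res$total_emitted, incoming_par = incoming_par,
    n_rays = n_rays, seed = seed
  ), class = "light_result")
}

#' @export
print.light_result <- function(x, ...) {
  cat("<light_result>", x$n_rays, "rays, incoming PAR", x$incoming_par,
      "umol m-2 s-1\n")
  tot <- x$total_emitted
  cat(sprintf(
    "  absorbed: leaves %.1f%%, other organs %.1f%%, ground %.1f%%; escaped %.1f%%\n",
    100 * x$leaf_absorbed / tot, 100 * x$other_absorbed / tot,
    100 * x$ground_absorbed / tot, 100 * x$escaped / tot))
  invisible(x)
}

#' Relative light readings at virtual sensor positions
#'
#' Traces the scene with virtual sensors and normalises every reading by the
#' above-canopy reference sensor, mirroring the field practice of reporting
#' light relative to that above the upright shoots (Q/Q0).
#'
#' @param scene A `canopy_scene`.
#' @param dome A `sky_dome`.
#' @param positions Tibble with `sensor_id, x, y, z` and optionally
#'   `length, width` (default 0.5 m x 0.1 m) and a logical `reference`
#'   column; if absent, the highest sensor is the reference.
#' @param ... Passed to [trace()].
#' @return The `positions` tibble with `reading` and `relative_reading`.
#' @export
sensor_profile <- function(scene, dome = build_sky_dome(), positions, ...) {
  stopifnot(nrow(positions) >= 1)
  if (!"length" %in% names(positions)) positions$length <- 0.5
  if (!"width" %in% names(positions)) positions$width <- 0.1
  if (!"reference" %in% names(positions)) {
    positions$reference <- positions$z == max(positions$z)
  }
  lr <- trace(scene, dome, sensors = positions, ...)
  out <- lr$sensors
  ref <- out$reading[which(out$reference)[1]]
  if (!isTRUE(ref > 0)) stop("reference sensor reading is zero")
  out$relative_reading <- out$reading / ref
  out
}

#' Write per-organ light results to CSV
#'
#' @param light A `light_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_light_csv <- function(light, path) {
  readr::write_csv(
    dplyr::select(light$organs, "organ_id", "plant", "shoot", "shoot_class",
                  "organ", "area_m2", "absorbed_flux", "incident_flux"),
    path)
  invisible(path)
}
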