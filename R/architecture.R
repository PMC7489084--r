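#' Leaf area from length and width
#'
#' Compound rose-leaf area follows an allometric relationship with the
#' product of leaf length and width, `area = coef * length * width`. The
#' coefficient is estimated from destructive measurements (see
#' [estimate_allometric_coef()]); the default 0.7 is typical for compound
#' rose leaves.
#'
#' @param length Leaf length, cm (tip of terminal leaflet to petiole base).
#' @param width Leaf width at the widest point, cm.
#' @param coef Dimensionless allometric coefficient (> 0).
#' @return Leaf area in cm^2 (vectorised).
#' @export
#' @examples
#' allometric_leaf_area(10, 5)
allometric_leaf_area <- function(length, width, coef = 0.7) {
  stopifnot(coef > 0)
  if (any(length < 0) || any(width < 0)) {
    stop("leaf length and width must be non-negative")
  }
  coef * length * width
}

#' Estimate the allometric coefficient from destructive leaf measurements
#'
#' Ordinary least squares through the origin of measured leaf area on the
#' product length x width.
#'
#' @param leaves Data frame with columns `length`, `width`, `area`.
#' @return A one-row tibble with `coef`, `r_squared` and `n`.
#' @export
estimate_allometric_coef <- function(leaves) {
  stopifnot(all(c("length", "width", "area") %in% names(leaves)))
  lw <- leaves$length * leaves$width
  fit <- lm(area ~ 0 + lw, data = tibble::tibble(area = leaves$area, lw = lw))
  tibble::tibble(
    coef = unname(coef(fit)[1]),
    r_squared = stats::cor(leaves$area, lw)^2,
    n = nrow(leaves)
  )
}

#' Interpolate an architecture database to an arbitrary day
#'
#' Per-rank architectural parameters (internode and leaf dimensions, flower
#' width) are measured on a handful of days; between measurement days values
#' are linearly interpolated from the two closest days, and from
#' `freeze_after` onwards the last measured set is used unchanged (organ
#' expansion has essentially stopped by then). Days before the first
#' measurement are refused: there is nothing to extrapolate from.
#'
#' @param db Architecture database: a data frame with columns `shoot_id`,
#'   `day`, `rank`, `internode_length_cm`, `internode_diameter_mm`,
#'   `leaf_length_cm`, `leaf_width_cm`, `leaflet_count`,
#'   `leaf_inclination_deg`, `flower_width_cm`.
#' @param shoot_id Which shoot's parameter sets to use.
#' @param day Query day (may be fractional).
#' @param freeze_after Day after which parameters stay at their last measured
#'   values (default 25).
#' @return A tibble with one row per rank plus the interpolated flower width,
#'   same column schema as `db` without `shoot_id`/`day`.
#' @export
interpolate_architecture <- function(db, shoot_id, day, freeze_after = 25) {
  sid <- shoot_id
  d <- dplyr::filter(db, .data$shoot_id == sid)
  if (nrow(d) == 0) stop("shoot_id not found in database: ", sid)
  days <- sort(unique(d$day))
  if (day < days[1]) {
    stop("day ", day, " is before the first measurement day (", days[1],
         "); no backwards extrapolation")
  }
  q <- min(day, freeze_after, max(days))
  vals <- c("internode_length_cm", "internode_diameter_mm", "leaf_length_cm",
            "leaf_width_cm", "leaflet_count", "leaf_inclination_deg",
            "flower_width_cm")
  if (q %in% days) {
    out <- dplyr::filter(d, .data$day == q)
    return(dplyr::select(dplyr::arrange(out, .data$rank), "rank",
                         dplyr::all_of(vals)))
  }
  d0 <- max(days[days < q])
  d1 <- min(days[days > q])
  f <- (q - d0) / (d1 - d0)
  lo <- dplyr::arrange(dplyr::filter(d, .data$day == d0), .data$rank)
  hi <- dplyr::arrange(dplyr::filter(d, .data$day == d1), .data$rank)
  ranks <- sort(union(lo$rank, hi$rank))
  blank <- tibble::tibble(rank = ranks)
  lo <- dplyr::left_join(blank, lo, by = "rank")
  hi <- dplyr::left_join(blank, hi, by = "rank")
  out <- tibble::tibble(rank = ranks)
  for (v in vals) {
    a <- lo[[v]]
    b <- hi[[v]]
    a[is.na(a)] <- 0  # organ not yet present on the earlier day
    b[is.na(b)] <- 0
    out[[v]] <- (1 - f) * a + f * b
  }
  out$leaflet_count <- pmax(1, round(out$leaflet_count))
  out
}

# triangle fan approximating an ellipse (2:1 aspect) with exactly the target
# area, lying in the local xy-plane with its base at the origin and its long
# axis along +x
leaflet_fan <- function(area_cm2, n_fan = 6) {
  area_m2 <- area_cm2 * 1e-4
  th <- seq(0, 2 * pi, length.out = n_fan + 1)
  # unit ellipse centred at (0.5, 0): runs from x = 0 (attachment) to x = 1
  px <- 0.5 + 0.5 * cos(th)
  py <- 0.25 * sin(th)
  tri <- matrix(0, n_fan, 9)
  for (i in seq_len(n_fan)) {
    tri[i, ] <- c(0.5, 0, 0, px[i], py[i], 0, px[i + 1], py[i + 1], 0)
  }
  s <- sqrt(area_m2 / sum(triangle_areas(tri)))
  tri[, c(1, 2, 4, 5, 7, 8)] <- tri[, c(1, 2, 4, 5, 7, 8)] * s
  tri
}

# planar compound leaf: leaflets pinnately arranged along a rachis with one
# terminal leaflet; per-leaflet area = leaf area / leaflet_count
compound_leaf <- function(leaf_length_cm, leaf_width_cm, leaflet_count,
                          coef = 0.7, n_fan = 6) {
  area_cm2 <- allometric_leaf_area(leaf_length_cm, leaf_width_cm, coef)
  if (area_cm2 <= 0) return(matrix(0, 0, 9))
  m <- max(1L, as.integer(round(leaflet_count)))
  per <- area_cm2 / m
  rachis <- leaf_length_cm * 1e-2 * 0.6  # petiole+rachis span of attachment points
  fans <- vector("list", m)
  fan0 <- leaflet_fan(per, n_fan)
  leaflet_len <- max(fan0[, 4])  # extent along +x
  # terminal leaflet at the rachis tip
  fans[[1]] <- transform_tri(fan0, diag(3), c(rachis, 0, 0))
  if (m > 1) {
    n_lat <- m - 1
    pos <- rachis * (seq_len(n_lat)) / (n_lat + 1)
    side <- rep(c(1, -1), length.out = n_lat)
    for (i in seq_len(n_lat)) {
      ang <- side[i] * deg2rad(55)
      fans[[i + 1]] <- transform_tri(fan0, rot_z(ang), c(pos[i], 0, 0))
    }
  }
  do.call(rbind, fans)
}

#' Build a 3-D upright flower shoot from a parameter set
#'
#' An upright shoot is a stack of phytomers (internode + compound leaf) topped
#' by a flower. Successive leaves are rotated by the phyllotactic angle around
#' the stem; each compound leaf is a planar pinnate arrangement of elliptical
#' leaflet fans whose summed mesh area equals the allometric leaf area.
#'
#' @param params Parameter set as returned by [interpolate_architecture()].
#' @param base Base position of the shoot, metres (z up, ground at z = 0).
#' @param phyllotaxis Angle between successive leaves, degrees (default 137.5).
#' @param azimuth0 Azimuth of the first leaf, degrees.
#' @param coef Allometric leaf-area coefficient.
#' @param n_fan Triangles per leaflet fan.
#' @return A list with `organs` (tibble: organ, rank, area_m2) and `tri`
#'   (triangle matrix) and `tri_organ` (row index into `organs` per triangle).
#' @export
build_upright_shoot <- function(params, base = c(0, 0, 0), phyllotaxis = 137.5,
                                azimuth0 = 0, coef = 0.7, n_fan = 6) {
  stopifnot(nrow(params) >= 1)
  params <- dplyr::arrange(params, .data$rank)
  if (!identical(as.integer(params$rank), seq_len(nrow(params)))) {
    stop("parameter set has missing or duplicated ranks")
  }
  tri_list <- list()
  organ_rows <- list()
  tri_org <- integer(0)
  z <- 0
  oi <- 0L
  add <- function(tri, organ, rank) {
    if (nrow(tri) == 0) return(invisible(NULL))
    oi <<- oi + 1L
    tri_list[[length(tri_list) + 1L]] <<- tri
    tri_org <<- c(tri_org, rep(oi, nrow(tri)))
    organ_rows[[oi]] <<- tibble::tibble(
      organ = organ, rank = rank, area_m2 = sum(triangle_areas(tri)))
    invisible(NULL)
  }
  for (i in seq_len(nrow(params))) {
    p <- params[i, ]
    il <- p$internode_length_cm * 1e-2
    if (il > 0) {
      add(stem_prism(p$internode_diameter_mm * 1e-3, il, z), "stem", p$rank)
    }
    z <- z + il
    area <- allometric_leaf_area(p$leaf_length_cm, p$leaf_width_cm, coef)
    if (area > 0) {
      leaf <- compound_leaf(p$leaf_length_cm, p$leaf_width_cm,
                            p$leaflet_count, coef, n_fan)
      R <- rot_z(deg2rad(azimuth0 + (i - 1) * phyllotaxis)) %*%
        rot_y(deg2rad(p$leaf_inclination_deg))
      add(transform_tri(leaf, R, c(0, 0, z)), "leaf", p$rank)
    }
  }
  fw <- params$flower_width_cm[1] * 1e-2
  if (isTRUE(fw > 0)) {
    add(flower_disk(fw, z + 0.02), "flower", NA_integer_)
  }
  organs <- dplyr::bind_rows(organ_rows)
  tri <- if (length(tri_list)) do.call(rbind, tri_list) else matrix(0, 0, 9)
  tri <- transform_tri(tri, diag(3), base)
  list(organs = organs, tri = tri, tri_organ = tri_org,
       stem_length_m = sum(params$internode_length_cm) * 1e-2)
}

# hexagonal prism for an internode, axis vertical from z0 to z0+len
stem_prism <- function(diameter_m, len, z0) {
  r <- diameter_m / 2
  a <- seq(0, 2 * pi, length.out = 7)
  x <- r * cos(a)
  y <- r * sin(a)
  tri <- matrix(0, 12, 9)
  for (i in 1:6) {
    tri[2 * i - 1, ] <- c(x[i], y[i], z0, x[i + 1], y[i + 1], z0,
                          x[i + 1], y[i + 1], z0 + len)
    tri[2 * i, ] <- c(x[i], y[i], z0, x[i + 1], y[i + 1], z0 + len,
                      x[i], y[i], z0 + len)
  }
  tri
}

# octagonal cone approximating the flower: petals are not a solid plate, so
# the effective silhouette is taken as 60% of the measured bloom width
flower_disk <- function(width_m, z) {
  r <- 0.6 * width_m / 2
  h <- 0.8 * r
  a <- seq(0, 2 * pi, length.out = 9)
  tri <- matrix(0, 8, 9)
  for (i in 1:8) {
    tri[i, ] <- c(0, 0, z + h, r * cos(a[i]), r * sin(a[i]), z,
                  r * cos(a[i + 1]), r * sin(a[i + 1]), z)
  }
  tri
}

#' Build a bent-shoot leaf cloud
#'
#' Bent shoots are represented as a cloud of leaves randomly distributed in
#' the volume they occupy, with a configurable leaf-angle model. Under the
#' spherical model all leaf-surface orientations are equally probable (leaf
#' normals uniform on the sphere); `horizontal` and `vertical` are the two
#' contrasting extremes used in sensitivity analyses. Total leaf area is
#' conserved exactly: individual leaf areas are drawn lognormal and rescaled
#' to sum to `total_area_cm2`.
#'
#' @param total_area_cm2 Total leaf area of the bent shoot, cm^2 (> 0).
#' @param volume Axis-aligned box `c(xmin, xmax, ymin, ymax, zmin, zmax)` in
#'   metres.
#' @param n_leaves Number of leaves; default `ceiling(total_area_cm2 / 30)`
#'   (mean leaf area 30 cm^2).
#' @param angle_model One of `"spherical"`, `"horizontal"`, `"vertical"`.
#' @param seed Integer seed; same seed gives an identical cloud.
#' @param sigma_log Lognormal sd of individual leaf areas.
#' @return A list with `organs`, `tri`, `tri_organ` as in
#'   [build_upright_shoot()], plus `normals` (n x 3) and `total_area_m2`.
#' @export
build_bent_shoot <- function(total_area_cm2, volume, n_leaves = NULL,
                             angle_model = c("spherical", "horizontal",
                                             "vertical"),
                             seed = NULL, sigma_log = 0.3) {
  angle_model <- match.arg(angle_model)
  stopifnot(total_area_cm2 > 0, length(volume) == 6)
  ext <- volume[c(2, 4, 6)] - volume[c(1, 3, 5)]
  if (any(ext <= 0)) stop("bent-shoot volume must have positive extent")
  if (is.null(n_leaves)) n_leaves <- max(1L, ceiling(total_area_cm2 / 30))
  with_seed(seed, {
    areas <- rlnorm(n_leaves, sdlog = sigma_log)
    areas <- areas / sum(areas) * total_area_cm2 * 1e-4  # m^2, exact total
    cx <- runif(n_leaves, volume[1], volume[2])
    cy <- runif(n_leaves, volume[3], volume[4])
    cz <- runif(n_leaves, volume[5], volume[6])
    normals <- switch(angle_model,
      spherical = {
        z <- runif(n_leaves, -1, 1)
        ph <- runif(n_leaves, 0, 2 * pi)
        r <- sqrt(pmax(0, 1 - z^2))
        cbind(r * cos(ph), r * sin(ph), z)
      },
      horizontal = cbind(rep(0, n_leaves), 0, 1),
      vertical = {
        ph <- runif(n_leaves, 0, 2 * pi)
        cbind(cos(ph), sin(ph), 0)
      })
    spin <- runif(n_leaves, 0, 2 * pi)
  })
  tri <- matrix(0, 2 * n_leaves, 9)
  for (i in seq_len(n_leaves)) {
    h <- sqrt(areas[i]) / 2  # half-side of a square leaf
    n <- normals[i, ]
    a <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    t1 <- a - sum(a * n) * n
    t1 <- t1 / sqrt(sum(t1^2))
    t2 <- c(n[2] * t1[3] - n[3] * t1[2], n[3] * t1[1] - n[1] * t1[3],
            n[1] * t1[2] - n[2] * t1[1])
    u <- cos(spin[i]) * t1 + sin(spin[i]) * t2
    v <- -sin(spin[i]) * t1 + cos(spin[i]) * t2
    ctr <- c(cx[i], cy[i], cz[i])
    p1 <- ctr - h * u - h * v
    p2 <- ctr + h * u - h * v
    p3 <- ctr + h * u + h * v
    p4 <- ctr - h * u + h * v
    tri[2 * i - 1, ] <- c(p1, p2, p3)
    tri[2 * i, ] <- c(p1, p3, p4)
  }
  organs <- tibble::tibble(organ = "leaf", rank = seq_len(n_leaves),
                           area_m2 = areas)
  list(organs = organs, tri = tri,
       tri_organ = rep(seq_len(n_leaves), each = 2), normals = normals,
       total_area_m2 = sum(areas))
}

#' Assemble a canopy scene from raw geometry
#'
#' Low-level constructor used by [build_canopy()] and by custom test
#' geometries (single leaves, homogeneous slabs).
#'
#' @param organs Tibble with columns `plant, shoot, shoot_class, organ,
#'   rank, area_m2` (an `organ_id` column is added).
#' @param tri Triangle matrix (n x 9).
#' @param tri_organ Row index into `organs` for every triangle.
#' @param lx,ly Periodic domain size, m.
#' @param density Plants per m^2.
#' @param layout `c(rows, cols)`.
#' @param replication Conceptual copies in x and y.
#' @param ground_reflectance Ground reflectance fraction.
#' @param treatment,day,seed Metadata.
#' @return A `canopy_scene`.
#' @export
canopy_scene <- function(organs, tri, tri_organ, lx, ly, density = 7.5,
                         layout = c(1, 1), replication = 1,
                         ground_reflectance = 0.5, treatment = "0B",
                         day = NA, seed = NULL) {
  stopifnot(nrow(tri) == length(tri_organ), lx > 0, ly > 0, density > 0,
            replication >= 1)
  organs$organ_id <- seq_len(nrow(organs))
  structure(list(
    organs = organs, tri = tri, tri_organ = tri_organ,
    domain = list(lx = lx, ly = ly, density = density, layout = layout,
                  replication = replication,
                  ground_reflectance = ground_reflectance),
    treatment = treatment, day = day, seed = seed
  ), class = "canopy_scene")
}

#' Build a full canopy scene for a bending treatment
#'
#' Lays out plants in double-gutter growth beds, mirroring a commercial
#' cut-rose arrangement: rows (gutters) are grouped in pairs `row_spacing`
#' apart, beds repeat at `bed_pitch`, and the in-row plant spacing follows
#' from the overall density. Each plant carries `upright_shoot_count`
#' upright shoots (parameter sets drawn from the architecture database and
#' interpolated to `day`) and 0, 1 or 3 bent-shoot leaf clouds according to
#' the treatment; bent shoots spread over the bed width (`bent_width`),
#' hanging into the path as in practice. The traced domain is the layout
#' footprint with toroidal wrapping, so a finite plot stands in for
#' `replication^2` copies.
#'
#' @param treatment `"0B"`, `"1B"` or `"3B"` (number of bent shoots per plant).
#' @param day Day after the start of treatment.
#' @param db Architecture database (see [interpolate_architecture()]).
#' @param bent_areas Numeric vector, leaf area (cm^2) of each bent shoot per
#'   plant; required for 1B/3B.
#' @param density Plants per m^2.
#' @param layout `c(rows, cols)` plants in the simulated plot.
#' @param replication Conceptual copies in x and y (effective plant count =
#'   rows * cols * replication^2).
#' @param ground_reflectance Fraction of light reflected by the ground.
#' @param bed_pitch Distance (m) between bed centres (the domain repeats at
#'   this pitch in y).
#' @param row_spacing Distance (m) between the two gutters of a bed.
#' @param bent_width Width (m) over which bent-shoot leaves spread, centred
#'   on the bed (bent shoots arch 0.8-0.9 m out over the path each side).
#' @param lean_deg Outward lean of upright shoots from vertical, degrees
#'   (vase-shaped plant form).
#' @param crown_height Height (m) of the shoot bases above the ground.
#' @param bent_zone Heights `c(zmin, zmax)` (m) of the bent-shoot layer.
#' @param angle_model Bent-leaf angle model (see [build_bent_shoot()]).
#' @param upright_shoot_count Upright shoots per plant (default 4).
#' @param mixed_stages If `TRUE`, each upright shoot is interpolated at a day
#'   sampled from the database's measurement days instead of `day` (mixed
#'   developmental stages).
#' @param seed Integer seed; the scene is a pure function of inputs and seed.
#' @param coef Allometric leaf-area coefficient.
#' @return A `canopy_scene` object.
#' @export
build_canopy <- function(treatment = c("0B", "1B", "3B"), day, db,
                         bent_areas = NULL, density = 7.5, layout = c(2, 9),
                         replication = 10, ground_reflectance = 0.5,
                         bed_pitch = 2, row_spacing = 0.5, bent_width = 1.8,
                         crown_height = 0.7, bent_zone = c(0.2, 0.7),
                         lean_deg = 15,
                         angle_model = "spherical", upright_shoot_count = 4,
                         mixed_stages = FALSE, seed = NULL, coef = 0.7) {
  treatment <- match.arg(treatment)
  stopifnot(density > 0, replication >= 1)
  n_bent <- c("0B" = 0L, "1B" = 1L, "3B" = 3L)[[treatment]]
  if (n_bent > 0 && is.null(bent_areas)) {
    stop("bent_areas must be supplied for treatments 1B/3B")
  }
  if (n_bent > 0) bent_areas <- rep_len(bent_areas, n_bent)
  rows <- layout[1]
  cols <- layout[2]
  n_beds <- ceiling(rows / 2)
  ly <- n_beds * bed_pitch
  in_row <- rows / (density * ly)  # plant spacing along the gutter
  lx <- cols * in_row
  # gutter y-positions: pairs around each bed centre (odd last bed centred)
  row_y <- numeric(rows)
  for (r in seq_len(rows)) {
    b <- ceiling(r / 2)
    yc <- (b - 0.5) * bed_pitch
    paired <- 2 * b <= rows
    row_y[r] <- if (paired) {
      yc + ifelse(r %% 2 == 1, -1, 1) * row_spacing / 2
    } else {
      yc
    }
  }
  bed_center <- ((ceiling(seq_len(rows) / 2)) - 0.5) * bed_pitch
  shoot_ids <- unique(db$shoot_id)
  meas_days <- sort(unique(db$day))

  organs_all <- list()
  tri_all <- list()
  torg_all <- list()
  n_org <- 0L
  with_seed(seed, {
    plant <- 0L
    for (r in seq_len(rows)) {
      for (cc in seq_len(cols)) {
        plant <- plant + 1L
        px <- (cc - 0.5) * in_row
        py <- row_y[r]
        for (s in seq_len(upright_shoot_count)) {
          sid <- sample(shoot_ids, 1)
          qday <- if (mixed_stages) sample(meas_days, 1) else day
          pars <- interpolate_architecture(db, sid, qday)
          az <- (s - 1) * 360 / upright_shoot_count + runif(1, 0, 360 /
                                                             upright_shoot_count)
          bx <- px + 0.05 * cos(deg2rad(az))
          by <- py + 0.05 * sin(deg2rad(az))
          sh <- build_upright_shoot(pars, base = c(0, 0, 0),
                                    azimuth0 = runif(1, 0, 360), coef = coef)
          # vase form: shoots lean outward from the plant centre
          azr <- deg2rad(az)
          lean <- rot_z(azr) %*% rot_y(deg2rad(lean_deg)) %*% rot_z(-azr)
          sh$tri <- transform_tri(sh$tri, lean, c(bx, by, crown_height))
          if (nrow(sh$organs) > 0) {
            o <- dplyr::mutate(sh$organs, plant = plant, shoot = s,
                               shoot_class = "upright")
            organs_all[[length(organs_all) + 1L]] <- o
            tri_all[[length(tri_all) + 1L]] <- sh$tri
            torg_all[[length(torg_all) + 1L]] <- sh$tri_organ + n_org
            n_org <- n_org + nrow(o)
          }
        }
        if (n_bent > 0) {
          vol <- c(px - in_row / 2, px + in_row / 2,
                   bed_center[r] - bent_width / 2,
                   bed_center[r] + bent_width / 2,
                   bent_zone[1], bent_zone[2])
          for (b in seq_len(n_bent)) {
            bs <- build_bent_shoot(bent_areas[b], vol,
                                   angle_model = angle_model,
                                   seed = sample.int(2^30, 1))
            o <- dplyr::mutate(bs$organs, plant = plant,
                               shoot = upright_shoot_count + b,
                               shoot_class = "bent")
            organs_all[[length(organs_all) + 1L]] <- o
            tri_all[[length(tri_all) + 1L]] <- bs$tri
            torg_all[[length(torg_all) + 1L]] <- bs$tri_organ + n_org
            n_org <- n_org + nrow(o)
          }
        }
      }
    }
  })
  organs <- dplyr::bind_rows(organs_all)
  organs$organ_id <- seq_len(nrow(organs))
  organs <- dplyr::select(organs, "organ_id", "plant", "shoot", "shoot_class",
                          "organ", "rank", "area_m2")
  structure(list(
    organs = organs,
    tri = if (length(tri_all)) do.call(rbind, tri_all) else matrix(0, 0, 9),
    tri_organ = if (length(torg_all)) unlist(torg_all) else integer(0),
    domain = list(lx = lx, ly = ly, density = density, layout = layout,
                  replication = replication,
                  ground_reflectance = ground_reflectance),
    treatment = treatment, day = day, seed = seed
  ), class = "canopy_scene")
}

#' @export
print.canopy_scene <- function(x, ...) {
  n_plants <- prod(x$domain$layout)
  cat("<canopy_scene> treatment", x$treatment, "day", x$day, "\n")
  cat("  plants:", n_plants, "(", n_plants * x$domain$replication^2,
      "effective with replication", x$domain$replication, ")\n")
  cat("  organs:", nrow(x$organs), " triangles:", nrow(x$tri), "\n")
  cat(sprintf("  upright LAI %.2f, bent LAI %.2f\n", scene_lai(x, "upright"),
              scene_lai(x, "bent")))
  invisible(x)
}

#' Leaf area index of a scene by shoot class
#'
#' @param scene A `canopy_scene`.
#' @param class `"upright"`, `"bent"` or `"all"`.
#' @return LAI (m^2 leaf per m^2 ground).
#' @export
scene_lai <- function(scene, class = "all") {
  o <- dplyr::filter(scene$organs, .data$organ == "leaf")
  if (class != "all") o <- dplyr::filter(o, .data$shoot_class == class)
  sum(o$area_m2) / (scene$domain$lx * scene$domain$ly)
}

#' Export a scene as a Wavefront OBJ file for visual inspection
#'
#' @param scene A `canopy_scene`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scene_obj <- function(scene, path) {
  tri <- scene$tri
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(tri))) {
    for (k in 0:2) {
      cat(sprintf("v %.6f %.6f %.6f\n", tri[i, 3 * k + 1], tri[i, 3 * k + 2],
                  tri[i, 3 * k + 3]), file = con)
    }
  }
  for (i in seq_len(nrow(tri))) {
    cat(sprintf("f %d %d %d\n", 3 * i - 2, 3 * i - 1, 3 * i), file = con)
  }
  invisible(path)
}
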