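test_that("allometric leaf area follows coef * length * width and rejects bad input", {
  expect_equal(allometric_leaf_area(0, 5, 0.7), 0)
  expect_equal(allometric_leaf_area(10, 5, 0.7), 35)
  expect_equal(allometric_leaf_area(c(2, 3), c(1, 2), 0.5), c(1, 3))
  expect_error(allometric_leaf_area(-1, 5, 0.7), "non-negative")
  expect_error(allometric_leaf_area(1, 5, 0), "coef")
})

test_that("allometric coefficient is recovered from noisy destructive data", {
  set.seed(42)
  n <- 200
  len <- runif(n, 5, 20)
  wid <- 0.6 * len * runif(n, 0.8, 1.2)
  area <- 0.7 * len * wid * (1 + rnorm(n, 0, 0.1))
  leaves <- tibble::tibble(length = len, width = wid, area = area)
  est <- estimate_allometric_coef(leaves)
  # independent oracle: closed-form OLS through the origin
  lw <- len * wid
  oracle <- sum(area * lw) / sum(lw^2)
  expect_equal(est$coef, oracle, tolerance = 1e-12)
  expect_lt(abs(est$coef - 0.7) / 0.7, 0.05)
})

test_that("architecture interpolation is exact on stored days, linear between, frozen after day 25", {
  db <- tidyr::expand_grid(shoot_id = 1, day = c(9, 14, 25), rank = 1:2) |>
    dplyr::mutate(internode_length_cm = ifelse(day == 9, 10,
                                               ifelse(day == 14, 14, 20)),
                  internode_diameter_mm = 5, leaf_length_cm = day,
                  leaf_width_cm = day / 2, leaflet_count = 5,
                  leaf_inclination_deg = 30, flower_width_cm = 10)
  exact <- interpolate_architecture(db, 1, 14)
  expect_equal(exact$internode_length_cm, c(14, 14))
  mid <- interpolate_architecture(db, 1, 11.5)
  expect_equal(mid$internode_length_cm, c(12, 12))
  frozen <- interpolate_architecture(db, 1, 30)
  expect_equal(frozen$internode_length_cm, c(20, 20))
  expect_equal(frozen, interpolate_architecture(db, 1, 25))
  expect_error(interpolate_architecture(db, 1, 5), "before the first")
})

test_that("interpolation treats organs absent on the earlier day as zero-sized", {
  db <- dplyr::bind_rows(
    tibble::tibble(shoot_id = 1, day = 9, rank = 1, internode_length_cm = 10,
                   internode_diameter_mm = 5, leaf_length_cm = 8,
                   leaf_width_cm = 4, leaflet_count = 5,
                   leaf_inclination_deg = 30, flower_width_cm = 0),
    tidyr::expand_grid(shoot_id = 1, day = 14, rank = 1:2) |>
      dplyr::mutate(internode_length_cm = 12, internode_diameter_mm = 5,
                    leaf_length_cm = 10, leaf_width_cm = 5,
                    leaflet_count = 5, leaf_inclination_deg = 30,
                    flower_width_cm = 0))
  mid <- interpolate_architecture(db, 1, 11.5)
  expect_equal(nrow(mid), 2)
  expect_equal(mid$internode_length_cm[2], 6)  # halfway from absent (0)
})

test_that("upright shoots assemble one phytomer per rank with area-true mesh leaves", {
  db <- fix_db("3B")
  pars <- interpolate_architecture(db, 1, 25)
  sh <- build_upright_shoot(pars)
  leaf_organs <- dplyr::filter(sh$organs, organ == "leaf")
  expect_equal(nrow(leaf_organs), sum(pars$leaf_length_cm > 0))
  expect_equal(nrow(leaf_organs), 14)  # full parameter set at day 25
  # mesh areas match the allometric specification within 1%
  spec_area <- allometric_leaf_area(pars$leaf_length_cm, pars$leaf_width_cm,
                                    0.7) * 1e-4
  expect_lt(abs(sum(leaf_organs$area_m2) - sum(spec_area)) / sum(spec_area),
            0.01)
  expect_equal(sh$stem_length_m, sum(pars$internode_length_cm) / 100)
  # zero internodes give a flat shoot
  pars0 <- dplyr::mutate(pars, internode_length_cm = 0)
  expect_equal(build_upright_shoot(pars0)$stem_length_m, 0)
  # missing rank is rejected
  expect_error(build_upright_shoot(pars[-3, ]), "rank")
})

test_that("bent-shoot clouds conserve area and honour the angle model", {
  vol <- c(0, 1, 0, 1, 0.2, 0.7)
  bs <- build_bent_shoot(1000, vol, seed = 7)
  expect_lt(abs(bs$total_area_m2 - 0.1) / 0.1, 0.005)
  expect_equal(sum(triangle_areas_for_test(bs$tri)), bs$total_area_m2,
               tolerance = 1e-9)
  # spherical model: mean |cos(zenith of normal)| -> 0.5
  big <- build_bent_shoot(3e5, vol, n_leaves = 1e4, seed = 8)
  expect_lt(abs(mean(abs(big$normals[, 3])) - 0.5), 0.02)
  # horizontal model: all normals vertical (zero leaf inclination)
  hor <- build_bent_shoot(500, vol, angle_model = "horizontal", seed = 9)
  expect_true(all(abs(hor$normals[, 3]) == 1))
  vert <- build_bent_shoot(500, vol, angle_model = "vertical", seed = 9)
  expect_true(all(abs(vert$normals[, 3]) == 0))
  # centroids inside the volume: every triangle vertex within the box
  # extended by a leaf diagonal
  expect_error(build_bent_shoot(1000, c(0, 1, 0, 1, 0.7, 0.2)), "extent")
  expect_error(build_bent_shoot(0, vol))
  # determinism
  expect_identical(build_bent_shoot(1000, vol, seed = 5),
                   build_bent_shoot(1000, vol, seed = 5))
})

test_that("canopy scenes match the treatment layout and conserve leaf area", {
  db <- fix_db("3B")
  sc0 <- build_canopy("0B", 25, db, layout = c(2, 3), seed = 1)
  expect_equal(sum(sc0$organs$shoot_class == "bent"), 0)
  expect_equal(scene_lai(sc0, "bent"), 0)
  # four upright shoots per plant
  up <- dplyr::distinct(dplyr::filter(sc0$organs, shoot_class == "upright"),
                        plant, shoot)
  expect_true(all(table(up$plant) == 4))

  sc3 <- build_canopy("3B", 25, db, bent_areas = rep(1600, 3),
                      layout = c(2, 9), replication = 10, seed = 2)
  expect_equal(prod(sc3$domain$layout) * sc3$domain$replication^2, 1800)
  bent_shoots <- dplyr::distinct(
    dplyr::filter(sc3$organs, shoot_class == "bent"), plant, shoot)
  expect_true(all(table(bent_shoots$plant) == 3))
  expect_error(build_canopy("1B", 25, db, layout = c(2, 3)), "bent_areas")

  # scene leaf-area accounting: LAI recomputed from mesh areas agrees with
  # the organ-table sum to 1%
  mesh_lai <- sum(triangle_areas_for_test(
    sc3$tri[sc3$organs$organ[sc3$tri_organ] == "leaf", ])) /
    (sc3$domain$lx * sc3$domain$ly)
  expect_lt(abs(mesh_lai - scene_lai(sc3, "all")) / mesh_lai, 0.01)

  # same seed, bit-identical scene; different seed conserves bent area
  expect_identical(build_canopy("3B", 14, db, bent_areas = rep(1600, 3),
                                layout = c(2, 3), seed = 5),
                   build_canopy("3B", 14, db, bent_areas = rep(1600, 3),
                                layout = c(2, 3), seed = 5))
  alt <- build_canopy("3B", 14, db, bent_areas = rep(1600, 3),
                      layout = c(2, 3), seed = 6)
  ref <- build_canopy("3B", 14, db, bent_areas = rep(1600, 3),
                      layout = c(2, 3), seed = 5)
  expect_false(identical(alt$tri, ref$tri))
  expect_equal(scene_lai(alt, "bent"), scene_lai(ref, "bent"),
               tolerance = 1e-9)

  # every leaf triangle has finite positive area
  areas <- triangle_areas_for_test(sc3$tri)
  expect_true(all(is.finite(areas)) && all(areas > 0))
})

test_that("scenes export to a readable Wavefront OBJ", {
  sc <- single_leaf_scene()
  path <- withr::local_tempfile(fileext = ".obj")
  write_scene_obj(sc, path)
  lines <- readLines(path)
  expect_equal(sum(grepl("^v ", lines)), 3 * nrow(sc$tri))
  expect_equal(sum(grepl("^f ", lines)), nrow(sc$tri))
})
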