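# shared fixtures, built once per test run

# small synthetic architecture databases per treatment
fix_db <- local({
  cache <- list()
  function(treatment = "3B", n_shoots = 6, seed = 101) {
    key <- paste(treatment, n_shoots, seed)
    if (is.null(cache[[key]])) {
      cache[[key]] <<- generate_architecture_db(treatment, n_shoots,
                                                seed = seed)
    }
    cache[[key]]
  }
})

# a compact traced-canopy fixture (scene + light result)
fix_traced <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sc <- build_canopy("3B", 25, fix_db("3B"),
                         bent_areas = rep(3.6 / 7.5 * 1e4 / 3, 3),
                         layout = c(2, 3), seed = 11)
      lr <- trace(sc, n_rays = 5e4, seed = 12)
      cache <<- list(scene = sc, light = lr)
    }
    cache
  }
})

# single horizontal square leaf of `area_cm2` centred in a small periodic
# domain, with configurable ground reflectance
single_leaf_scene <- function(area_cm2 = 100, ground_reflectance = 0,
                              lx = 0.4, ly = 0.4, z = 0.5) {
  bs <- build_bent_shoot(area_cm2,
                         c(lx / 2 - 0.1, lx / 2 + 0.1,
                           ly / 2 - 0.1, ly / 2 + 0.1, z, z + 1e-4),
                         n_leaves = 1, angle_model = "horizontal", seed = 1)
  organs <- tibble::tibble(plant = 1L, shoot = 1L, shoot_class = "bent",
                           organ = "leaf", rank = 1L,
                           area_m2 = bs$total_area_m2)
  canopy_scene(organs, bs$tri, rep(1L, nrow(bs$tri)), lx, ly,
               ground_reflectance = ground_reflectance)
}

# homogeneous spherical-angle leaf slab with the requested LAI over a
# 1 m x 1 m periodic floor (the turbid-medium stand-in)
slab_scene <- function(lai, leaf_cm2 = 4, seed = 1, ground_reflectance = 0,
                       z0 = 0.2, z1 = 1.2) {
  L <- 1
  area_cm2 <- lai * L * L * 1e4
  bs <- build_bent_shoot(area_cm2, c(0, L, 0, L, z0, z1),
                         n_leaves = ceiling(area_cm2 / leaf_cm2),
                         angle_model = "spherical", seed = seed)
  n <- nrow(bs$organs)
  organs <- tibble::tibble(plant = 1L, shoot = 1L, shoot_class = "bent",
                           organ = "leaf", rank = seq_len(n),
                           area_m2 = bs$organs$area_m2)
  canopy_scene(organs, bs$tri, bs$tri_organ, L, L,
               ground_reflectance = ground_reflectance)
}

# independent triangle-area computation (cross-product, written out)
triangle_areas_for_test <- function(tri) {
  tri <- matrix(tri, ncol = 9)
  apply(tri, 1, function(v) {
    a <- v[4:6] - v[1:3]
    b <- v[7:9] - v[1:3]
    cx <- a[2] * b[3] - a[3] * b[2]
    cy <- a[3] * b[1] - a[1] * b[3]
    cz <- a[1] * b[2] - a[2] * b[1]
    0.5 * sqrt(cx^2 + cy^2 + cz^2)
  })
}

# black-surface optics (pure interception)
black_optics <- function() optical_properties(0, 0, 0, 0, 0)

# energy-audit closure of a light_result, as a fraction of emitted flux
audit_closure <- function(lr) {
  (lr$leaf_absorbed + lr$other_absorbed + lr$ground_absorbed + lr$escaped) /
    lr$total_emitted
}
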