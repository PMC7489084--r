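deg2rad <- function(x) x * pi / 180

# run code with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# rotation matrices (right-handed, z up)
rot_z <- function(a) {
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3, byrow = TRUE)
}
rot_y <- function(a) {
  matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)), 3, 3, byrow = TRUE)
}

# area of triangles stored as an n x 9 matrix (v0, v1, v2 coordinates)
triangle_areas <- function(tri) {
  if (nrow(tri) == 0) return(numeric(0))
  e1 <- tri[, 4:6, drop = FALSE] - tri[, 1:3, drop = FALSE]
  e2 <- tri[, 7:9, drop = FALSE] - tri[, 1:3, drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

# transform an n x 9 triangle matrix: rotate by 3x3 matrix R then translate
transform_tri <- function(tri, R = diag(3), shift = c(0, 0, 0)) {
  if (nrow(tri) == 0) return(tri)
  for (k in 0:2) {
    idx <- 3 * k + 1:3
    tri[, idx] <- tri[, idx, drop = FALSE] %*% t(R)
    tri[, idx] <- sweep(tri[, idx, drop = FALSE], 2, shift, "+")
  }
  tri
}

# duplicate triangles that cross the periodic x/y walls, shifted by the
# domain period, so rays wrapped at a wall still see the protruding parts
wrap_periodic <- function(tri, tri_organ, lx, ly) {
  if (nrow(tri) == 0) return(list(tri = tri, tri_organ = tri_organ))
  xs <- tri[, c(1, 4, 7), drop = FALSE]
  ys <- tri[, c(2, 5, 8), drop = FALSE]
  xmin <- pmin(xs[, 1], xs[, 2], xs[, 3])
  xmax <- pmax(xs[, 1], xs[, 2], xs[, 3])
  ymin <- pmin(ys[, 1], ys[, 2], ys[, 3])
  ymax <- pmax(ys[, 1], ys[, 2], ys[, 3])
  out_tri <- list(tri)
  out_org <- list(tri_organ)
  for (sx in -1:1) {
    for (sy in -1:1) {
      if (sx == 0 && sy == 0) next
      keep <- (xmin + sx * lx < lx) & (xmax + sx * lx > 0) &
        (ymin + sy * ly < ly) & (ymax + sy * ly > 0)
      if (!any(keep)) next
      shifted <- tri[keep, , drop = FALSE]
      shifted[, c(1, 4, 7)] <- shifted[, c(1, 4, 7)] + sx * lx
      shifted[, c(2, 5, 8)] <- shifted[, c(2, 5, 8)] + sy * ly
      out_tri[[length(out_tri) + 1L]] <- shifted
      out_org[[length(out_org) + 1L]] <- tri_organ[keep]
    }
  }
  list(tri = do.call(rbind, out_tri), tri_organ = unlist(out_org))
}

round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}
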