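test_that("the light response has the right limits and matches a quadratic-root oracle", {
  p <- photo_params(phi = 0.057, amax = 20.2, rd = 1.25, theta = 0.8)
  expect_equal(net_photosynthesis(p, 0), -1.25)
  expect_lt(abs(net_photosynthesis(p, 1e6) - (20.2 - 1.25)), 0.1)
  # independent oracle: solve theta*x^2 - (phi*I + amax)*x + phi*I*amax = 0
  # with polyroot and take the lesser root
  oracle <- function(I) {
    x <- Re(polyroot(c(p$phi * I * p$amax, -(p$phi * I + p$amax), p$theta)))
    min(x) - p$rd
  }
  grid <- seq(0.5, 2000, length.out = 1000)
  expect_equal(net_photosynthesis(p, grid), vapply(grid, oracle, 0),
               tolerance = 1e-9)
  expect_error(net_photosynthesis(photo_params(theta = 0.5), -1))
  expect_error(net_photosynthesis(list(phi = 0.05, amax = 20, rd = 1,
                                       theta = 1.2), 100), "theta")
})

test_that("the response is increasing, concave, and bounded by min(phi*I, amax)", {
  p <- photo_params()
  I <- seq(0, 3000, by = 5)
  A <- net_photosynthesis(p, I)
  expect_true(all(diff(A) > 0))
  expect_true(all(diff(diff(A)) < 1e-9))
  gross <- A + p$rd
  expect_true(all(gross <= pmin(p$phi * I, p$amax) + 1e-9))
})

test_that("theta -> 0 recovers the rectangular hyperbola", {
  p <- photo_params(theta = 1e-6)
  I <- c(10, 50, 200, 800, 1500)
  rect <- p$phi * I * p$amax / (p$phi * I + p$amax) - p$rd
  expect_equal(net_photosynthesis(p, I), rect, tolerance = 1e-4)
})

test_that("capacity follows the relative-light power law per shoot class", {
  g <- amax_gradient()
  expect_equal(amax_from_relative_light(g, 1, "upright"), 21.0)
  expect_equal(amax_from_relative_light(g, 1, "bent"), 16.9)
  expect_equal(amax_from_relative_light(g, 0.1, "bent"), 16.9 * 0.1^0.09)
  g0 <- amax_gradient(k = 0)
  expect_equal(amax_from_relative_light(g0, c(0.01, 0.5, 1), "upright"),
               rep(21, 3))
  q <- seq(0.01, 1, length.out = 50)
  expect_true(all(diff(amax_from_relative_light(g, q, "upright")) >= 0))
  expect_error(amax_from_relative_light(g, 0), "positive")
  expect_error(amax_from_relative_light(g, -0.5), "positive")
})

test_that("the log-log gradient fit recovers its generator", {
  q <- c(1, 0.6, 0.3, 0.12, 0.05)
  pts <- tibble::tibble(q_rel = q, amax = 21 * q^0.09)
  fit <- fit_amax_gradient(pts)
  expect_equal(fit$a0, 21, tolerance = 1e-9)
  expect_equal(fit$k, 0.09, tolerance = 1e-9)
  # two points: closed-form slope
  two <- tibble::tibble(q_rel = c(1, 0.25), amax = c(20, 17))
  fit2 <- fit_amax_gradient(two)
  expect_equal(fit2$k, (log(17) - log(20)) / (log(0.25) - log(1)),
               tolerance = 1e-12)
  # fixed-k intercept-only fit (the bent-shoot case)
  fitk <- fit_amax_gradient(tibble::tibble(q_rel = q, amax = 16.9 * q^0.09),
                            fix_k = 0.09)
  expect_equal(fitk$a0, 16.9, tolerance = 1e-9)
  expect_error(fit_amax_gradient(tibble::tibble(q_rel = c(1, -1),
                                                amax = c(1, 1))))
  # mutual inverse on noiseless data
  g <- amax_gradient(a0_upright = fit$a0, k = fit$k)
  expect_equal(amax_from_relative_light(g, q, "upright"), pts$amax,
               tolerance = 1e-9)
})

test_that("the gradient exponent is recovered under multiplicative noise", {
  set.seed(7)
  errs <- replicate(500, {
    q <- runif(100, 0.05, 1)
    amax <- 21 * q^0.09 * rlnorm(100, 0, 0.05)
    fit_amax_gradient(tibble::tibble(q_rel = q, amax = amax))$k - 0.09
  })
  expect_lt(median(abs(errs)), 0.03)
})

test_that("stepwise light-response fitting recovers noiseless parameters", {
  truth <- photo_params(0.057, 20.2, 1.25, 0.8)
  curve <- generate_light_response(truth)
  fit <- fit_light_response(curve[, c("I", "A")])
  expect_true(fit$converged)
  expect_lt(abs(fit$params$phi - 0.057) / 0.057, 0.02)
  expect_lt(abs(fit$params$amax - 20.2) / 20.2, 0.02)
  expect_lt(abs(fit$params$rd - 1.25) / 1.25, 0.02)
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "theta"], 0.8)
  expect_true(glance(fit)$converged)
})

test_that("a flat curve is flagged degenerate and a falling curve is refused", {
  flat <- tibble::tibble(I = c(50, 100, 400, 1500), A = rep(5, 4))
  fit <- fit_light_response(flat)
  expect_true(fit$degenerate)
  expect_lt(fit$params$phi, 1e-4)
  falling <- tibble::tibble(I = c(50, 100, 400, 1500), A = c(8, 6, 4, 2))
  expect_error(fit_light_response(falling), "decreases")
})

test_that("per-leaf parameters follow the gradient contracts", {
  fx <- fix_traced()
  g <- amax_gradient()
  leaves <- assign_leaf_parameters(fx$scene, fx$light, g)
  expect_true(all(leaves$q_rel > 0 & leaves$q_rel <= 1))
  # rd/amax identical across all leaves; phi common
  expect_equal(unique(round(leaves$rd / leaves$amax, 12)), g$rd_ratio)
  expect_equal(unique(leaves$phi), g$phi_common)
  # clipping never lifts capacity above the class A0
  expect_true(all(leaves$amax[leaves$shoot_class == "upright"] <=
                    g$a0_upright + 1e-9))
  expect_true(all(leaves$amax[leaves$shoot_class == "bent"] <=
                    g$a0_bent + 1e-9))
  # the most illuminated upright leaf approaches A0
  top <- dplyr::slice_max(dplyr::filter(leaves, shoot_class == "upright"),
                          q_rel, n = 1)
  expect_gt(top$amax, 0.95 * g$a0_upright)
  # bent vs upright at equal relative light differ by A0,bent / A0,upright
  expect_equal(amax_from_relative_light(g, 0.4, "bent") /
                 amax_from_relative_light(g, 0.4, "upright"), 16.9 / 21.0,
               tolerance = 1e-12)
})
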