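#' Leaf photosynthetic parameters
#'
#' Parameters of the non-rectangular hyperbola light response: quantum yield
#' `phi` (mol CO2 mol^-1 incident photon), light-saturated rate `amax`,
#' dark respiration `rd` (both umol CO2 m^-2 s^-1) and curvature `theta`
#' (dimensionless, in (0, 1); 0.8 by convention for rose).
#'
#' @param phi,amax,rd,theta Parameter values.
#' @return A list of class `photo_params`.
#' @export
photo_params <- function(phi = 0.057, amax = 20.2, rd = 1.25, theta = 0.8) {
  stopifnot(phi >= 0, amax >= 0, rd >= 0)
  if (!(theta > 0 && theta < 1)) stop("theta must be in (0, 1)")
  structure(list(phi = phi, amax = amax, rd = rd, theta = theta),
            class = "photo_params")
}

#' Net leaf photosynthesis (non-rectangular hyperbola)
#'
#' Gross photosynthesis is the lesser root of
#' `theta * x^2 - (phi * I + amax) * x + phi * I * amax = 0`,
#' and net photosynthesis subtracts dark respiration. The function is
#' strictly increasing and concave in incident light `I`, with `A(0) = -rd`
#' and `A -> amax - rd` as `I -> Inf`.
#'
#' @param p A [photo_params()] object (or list with the same fields).
#' @param I Incident PAR, umol m^-2 s^-1 (vectorised).
#' @return Net photosynthesis, umol CO2 m^-2 s^-1.
#' @export
#' @examples
#' net_photosynthesis(photo_params(), c(0, 200, 1500))
net_photosynthesis <- function(p, I) {
  if (!(p$theta > 0 && p$theta < 1)) stop("theta must be in (0, 1)")
  if (any(I < 0)) stop("incident light must be non-negative")
  s <- p$phi * I + p$amax
  disc <- pmax(0, s^2 - 4 * p$theta * p$amax * p$phi * I)
  (s - sqrt(disc)) / (2 * p$theta) - p$rd
}

#' Photosynthetic-capacity light gradient
#'
#' In a canopy, light-saturated photosynthetic capacity follows the light
#' gradient: `amax = A0 * q_rel^k`, where `q_rel = Q/Q0` is the light
#' experienced by a leaf relative to that above the canopy, `A0` is the
#' capacity of the most illuminated leaf, and `k` links the two gradients.
#' Upright and bent shoots share `k` but have their own `A0`. Dark
#' respiration is proportional to capacity (`rd = rd_ratio * amax`) and the
#' quantum yield is common to all leaves.
#'
#' @param a0_upright,a0_bent Capacity (umol m^-2 s^-1) of the most
#'   illuminated upright / bent leaf. Defaults are the fitted rose values
#'   21.0 and 16.9.
#' @param k Gradient exponent (default 0.09).
#' @param rd_ratio Rd/Amax proportionality (default 0.046, the least-squares
#'   slope through the origin over the measured (Amax, Rd) pairs of all leaf
#'   layers and shoot classes).
#' @param phi_common Common quantum yield (default 0.057).
#' @param theta Curvature factor (default 0.8).
#' @return A list of class `amax_gradient`.
#' @export
amax_gradient <- function(a0_upright = 21.0, a0_bent = 16.9, k = 0.09,
                          rd_ratio = 0.046, phi_common = 0.057, theta = 0.8) {
  stopifnot(a0_upright >= 0, a0_bent >= 0, k >= 0, rd_ratio >= 0,
            phi_common >= 0)
  structure(list(a0_upright = a0_upright, a0_bent = a0_bent, k = k,
                 rd_ratio = rd_ratio, phi_common = phi_common,
                 theta = theta),
            class = "amax_gradient")
}

#' Leaf capacity from relative light
#'
#' Evaluates `amax = A0 * q_rel^k` for the given shoot class.
#'
#' @param g An [amax_gradient()].
#' @param q_rel Relative light Q/Q0, in (0, 1] (vectorised).
#' @param shoot_class `"upright"` or `"bent"` (vectorised).
#' @return Amax, umol m^-2 s^-1.
#' @export
amax_from_relative_light <- function(g, q_rel,
                                     shoot_class = c("upright", "bent")) {
  if (any(q_rel <= 0)) stop("q_rel must be positive")
  if (any(q_rel > 1)) stop("q_rel must not exceed 1")
  shoot_class <- match.arg(shoot_class, several.ok = TRUE)
  a0 <- ifelse(shoot_class == "upright", g$a0_upright, g$a0_bent)
  a0 * q_rel^g$k
}

#' Fit the capacity-light gradient in log-log space
#'
#' Least-squares fit of `log(amax) = log(A0) + k * log(q_rel)`. With `fix_k`
#' only the intercept is fitted (used for bent shoots, which share the
#' upright-shoot `k`).
#'
#' @param points Data frame with columns `q_rel` and `amax` (both > 0).
#' @param fix_k Optional fixed exponent.
#' @return A one-row tibble with `a0`, `k`, `n`.
#' @export
fit_amax_gradient <- function(points, fix_k = NULL) {
  stopifnot(all(c("q_rel", "amax") %in% names(points)))
  if (any(points$q_rel <= 0) || any(points$amax <= 0)) {
    stop("q_rel and amax must be positive for the log-log fit")
  }
  n <- nrow(points)
  lx <- log(points$q_rel)
  ly <- log(points$amax)
  if (!is.null(fix_k)) {
    stopifnot(n >= 1)
    a0 <- exp(mean(ly - fix_k * lx))
    return(tibble::tibble(a0 = a0, k = fix_k, n = n))
  }
  stopifnot(n >= 2)
  fit <- lm(ly ~ lx)
  tibble::tibble(a0 = exp(unname(coef(fit)[1])), k = unname(coef(fit)[2]),
                 n = n)
}

#' Fit a light-response curve to the non-rectangular hyperbola
#'
#' Stepwise estimation with `theta` fixed: the quantum yield `phi` and dark
#' respiration `rd` are identified from the low-light points
#' (`I <= low_light`), and `amax` from the whole curve. Because the
#' hyperbola already bends below the `phi * I` line at moderate light, the
#' low-light fit is iterated against the current `amax` (alternating
#' (phi, rd) | amax and amax | (phi, rd)) until convergence, starting from a
#' straight-line fit. Noiseless curves are recovered exactly.
#'
#' @param curve Data frame with columns `I` (distinct, >= 0) and `A`.
#' @param theta Fixed curvature (default 0.8).
#' @param low_light Threshold (umol m^-2 s^-1) for the low-light subset.
#' @param max_iter,tol Convergence controls.
#' @return An object of class `light_response_fit` with elements `params`
#'   ([photo_params()]), `converged`, `degenerate`, `rmse`, `n`, `data`.
#' @export
fit_light_response <- function(curve, theta = 0.8, low_light = 200,
                               max_iter = 100, tol = 1e-10) {
  stopifnot(all(c("I", "A") %in% names(curve)), nrow(curve) >= 4)
  if (anyDuplicated(curve$I)) stop("light levels must be distinct")
  if (any(curve$I < 0)) stop("light levels must be non-negative")
  curve <- dplyr::arrange(curve, .data$I)
  if (all(diff(curve$A) <= 0) && any(diff(curve$A) < 0)) {
    stop("photosynthesis decreases with light over the whole curve; ",
         "non-physical input, fit not attempted")
  }
  lo <- dplyr::filter(curve, .data$I <= low_light)
  if (nrow(lo) < 2) lo <- utils::head(curve, 2)
  init <- lm(A ~ I, data = lo)
  phi <- max(0, unname(coef(init)[2]))
  rd <- max(0, -unname(coef(init)[1]))
  amax <- max(max(curve$A) + rd, phi * 10, 1e-6)
  degenerate <- FALSE
  if (phi < 1e-6) degenerate <- TRUE
  nrh <- function(phi, amax, rd, I) {
    s <- phi * I + amax
    (s - sqrt(pmax(0, s^2 - 4 * theta * amax * phi * I))) / (2 * theta) - rd
  }
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    old <- c(phi, amax, rd)
    # amax | (phi, rd): 1-D least squares on the full curve
    amax <- optimise(function(a) {
      sum((curve$A - nrh(phi, a, rd, curve$I))^2)
    }, c(1e-6, max(curve$A + rd) * 20))$minimum
    # (phi, rd) | amax on the low-light subset
    op <- optim(c(phi, rd), function(pr) {
      if (pr[1] < 0 || pr[2] < 0) return(1e30)
      sum((lo$A - nrh(pr[1], amax, pr[2], lo$I))^2)
    }, method = "Nelder-Mead",
    control = list(reltol = 1e-14, maxit = 500))
    phi <- max(0, op$par[1])
    rd <- max(0, op$par[2])
    if (max(abs(c(phi, amax, rd) - old) / pmax(abs(old), 1e-8)) < tol) {
      converged <- TRUE
      break
    }
  }
  pred <- nrh(phi, amax, rd, curve$I)
  structure(list(
    params = photo_params(phi = phi, amax = amax, rd = rd, theta = theta),
    converged = converged, degenerate = degenerate || phi < 1e-4,
    rmse = sqrt(mean((curve$A - pred)^2)), n = nrow(curve),
    data = dplyr::mutate(curve, fitted = pred)
  ), class = "light_response_fit")
}

#' @export
print.light_response_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<light_response_fit> phi %.4f, amax %.2f, rd %.3f, theta %.2f (n = %d)\n",
    p$phi, p$amax, p$rd, p$theta, x$n))
  if (x$degenerate) cat("  flagged degenerate (phi ~ 0)\n")
  invisible(x)
}

#' Assign per-leaf photosynthetic parameters from a light result
#'
#' Each leaf's relative light `q_rel` is its incident flux density divided by
#' the above-canopy PAR (clipped to `(eps, 1]`); its capacity follows the
#' class gradient, dark respiration is `rd_ratio * amax` and the quantum
#' yield is common to all leaves.
#'
#' @param scene The traced `canopy_scene`.
#' @param light The matching `light_result`.
#' @param g An [amax_gradient()].
#' @param eps Floor for `q_rel`.
#' @return The leaf subset of the organ tibble with `q_rel, amax, rd, phi,
#'   theta` columns appended.
#' @export
assign_leaf_parameters <- function(scene, light, g = amax_gradient(),
                                   eps = 1e-3) {
  leaves <- dplyr::filter(light$organs, .data$organ == "leaf")
  if (any(is.na(leaves$incident_flux))) {
    stop("light result lacks incident flux for some leaves")
  }
  leaves |>
    dplyr::mutate(
      q_rel = pmin(1, pmax(eps, .data$incident_flux / light$incoming_par)),
      amax = amax_from_relative_light(g, .data$q_rel, .data$shoot_class),
      rd = g$rd_ratio * .data$amax,
      phi = g$phi_common,
      theta = g$theta)
}
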