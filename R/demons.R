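#' Minimal intensity-driven demons registration
#'
#' A deterministic, monomodality Thirion-style demons fixture used to
#' produce realistic smooth-versus-jagged displacement fields for exercising
#' the vortex-map QA loop. Per iteration the optical-flow force
#' \deqn{\Delta u(x) = \frac{(f(x) - m(x + u(x)))\,\nabla f(x)}
#'       {|\nabla f(x)|^2 + (f(x) - m(x + u(x)))^2}}
#' is added to the current field (the update is zeroed where the
#' denominator falls below `1e-9`, the standard stabilisation in flat
#' regions), and, when `smooth_sigma_mm` is given, each displacement
#' component is Gaussian-smoothed after every iteration — the demons
#' regularisation whose absence produces the fragmented, high-curl fields
#' the vortex map is designed to flag.
#'
#' The force is intensity-scale dependent, so images are internally
#' rescaled to a unit dynamic range and the resulting per-iteration step is
#' bounded by half a voxel via `step_mm`.
#'
#' @param fixed,moving [image_volume()]s on the same grid.
#' @param iterations number of iterations (>= 1, default 50).
#' @param smooth_sigma_mm optional Gaussian sigma (mm) for per-iteration
#'   field smoothing; `NULL` disables regularisation.
#' @param step_mm maximum per-iteration displacement step in mm (default
#'   half the smallest spacing).
#' @return A [vector_field()] `u` such that `moving(x + u(x))`
#'   approximates `fixed(x)`.
#' @export
demons_register <- function(fixed, moving, iterations = 50L,
                            smooth_sigma_mm = NULL, step_mm = NULL) {
  stopifnot(inherits(fixed, "image_volume"), inherits(moving, "image_volume"))
  stop_if_incompatible(fixed, moving, "fixed/moving grids")
  if (iterations < 1L) stop("iterations must be >= 1")
  h <- header_of(fixed)
  if (is.null(step_mm)) step_mm <- min(h$spacing) / 2
  rng <- range(c(fixed$values, moving$values))
  scale <- max(rng[2] - rng[1], 1e-12)
  f <- (fixed$values - rng[1]) / scale
  m <- (moving$values - rng[1]) / scale
  mvol <- image_volume(m, h$spacing, h$origin, h$direction)
  s <- h$spacing
  gx <- partial_derivative(f, 1L, s)
  gy <- partial_derivative(f, 2L, s)
  gz <- partial_derivative(f, 3L, s)
  g2 <- gx^2 + gy^2 + gz^2
  zero <- array(0, h$shape)
  u <- vector_field(zero, zero, zero, s, h$origin, h$direction)
  for (it in seq_len(iterations)) {
    warped <- warp_image(mvol, u, "linear", background = 0)
    diff <- f - warped$values
    denom <- g2 + diff^2
    fac <- ifelse(denom < 1e-9, 0, diff / denom)
    du <- fac * gx; dv <- fac * gy; dw <- fac * gz
    stepnorm <- sqrt(du^2 + dv^2 + dw^2)
    cap <- ifelse(stepnorm > step_mm, step_mm / stepnorm, 1)
    uu <- u$u + du * cap; vv <- u$v + dv * cap; ww <- u$w + dw * cap
    if (!is.null(smooth_sigma_mm) && smooth_sigma_mm > 0) {
      uu <- gaussian_smooth(uu, smooth_sigma_mm, s)
      vv <- gaussian_smooth(vv, smooth_sigma_mm, s)
      ww <- gaussian_smooth(ww, smooth_sigma_mm, s)
    }
    u <- vector_field(uu, vv, ww, s, h$origin, h$direction)
  }
  u
}

#' Soft-edged sphere test image
#'
#' A sphere of the given HU on background, with a linear partial-volume ramp
#' of `edge_mm` at the rim so intensity gradients — which drive demons
#' forces — are spatially extended, as in real CT.
#'
#' @param header target grid.
#' @param center sphere centre, mm.
#' @param radius sphere radius, mm.
#' @param hu,background inside/outside intensities.
#' @param edge_mm rim ramp width, mm.
#' @return An [image_volume()].
#' @export
sphere_image <- function(header, center, radius, hu = 0, background = -1000,
                         edge_mm = 2) {
  h <- header_of(header)
  coords <- grid_coordinates(h)
  d <- sqrt((coords$x - center[1])^2 + (coords$y - center[2])^2 +
            (coords$z - center[3])^2)
  frac <- pmin(pmax((radius + edge_mm / 2 - d) / edge_mm, 0), 1)
  image_volume(background + (hu - background) * frac,
               h$spacing, h$origin, h$direction)
}
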