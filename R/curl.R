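# Finite-difference machinery operating along one array axis at a time.
# Each per-axis operator is a small n x n band matrix applied after rotating
# the target axis to the front, which keeps everything vectorised.

apply_along_axis <- function(g, axis, mat) {
  d <- dim(g)
  perm <- c(axis, setdiff(1:3, axis))
  gp <- aperm(g, perm)
  res <- mat %*% matrix(gp, nrow = d[axis])
  dim(res) <- d[perm]
  aperm(res, order(perm))
}

# n x n first-derivative operator: central differences in the interior,
# first-order one-sided stencils on the two boundary slabs; h in mm.
deriv_matrix <- function(n, h) {
  if (n < 2L) stop("axis must have at least 2 voxels to differentiate")
  D <- matrix(0, n, n)
  if (n > 2L) {
    idx <- 2:(n - 1)
    D[cbind(idx, idx + 1L)] <- 1 / (2 * h)
    D[cbind(idx, idx - 1L)] <- -1 / (2 * h)
  }
  D[1, 1] <- -1 / h; D[1, 2] <- 1 / h
  D[n, n - 1] <- -1 / h; D[n, n] <- 1 / h
  D
}

#' Partial derivative of a scalar grid along one physical axis
#'
#' Central differences `(f[i+1] - f[i-1]) / (2h)` at interior voxels and
#' first-order one-sided differences at the two boundary slabs, with `h` the
#' physical spacing of the axis in mm. Exact on grids affine in the
#' coordinate, and exact in the interior on quadratics.
#'
#' @param grid numeric 3-D array.
#' @param axis 1, 2, 3 or "x", "y", "z".
#' @param spacing per-axis spacing in mm (length 3).
#' @return Array of the same shape: the derivative in (grid units)/mm.
#' @export
partial_derivative <- function(grid, axis, spacing) {
  if (is.character(axis)) axis <- match(axis, c("x", "y", "z"))
  stopifnot(axis %in% 1:3, length(dim(grid)) == 3L)
  n <- dim(grid)[axis]
  apply_along_axis(grid, axis, deriv_matrix(n, spacing[axis]))
}

#' Curl of a displacement field
#'
#' Computes the vorticity vector
#' \deqn{\nabla\times u = (\partial w/\partial y - \partial v/\partial z,\;
#'       \partial u/\partial z - \partial w/\partial x,\;
#'       \partial v/\partial x - \partial u/\partial y)}
#' by finite differences on the physical grid (anisotropic spacing honoured
#' per axis). The curl of a mm-displacement over mm-position is
#' dimensionless. Components are expressed in the image axis frame; since
#' differentiation happens in index space scaled by spacing, no resampling is
#' involved for non-identity direction matrices, and the curl magnitude is
#' rotation-invariant.
#'
#' @param field a [vector_field()]; every axis needs at least 2 voxels.
#' @return A list of class `curl_field` with components `cx`, `cy`, `cz` and
#'   the source grid header fields.
#' @export
compute_curl <- function(field) {
  stopifnot(inherits(field, "vector_field"))
  if (any(field$shape < 2L))
    stop("every axis must have at least 2 voxels to differentiate")
  s <- field$spacing
  cx <- partial_derivative(field$w, 2L, s) - partial_derivative(field$v, 3L, s)
  cy <- partial_derivative(field$u, 3L, s) - partial_derivative(field$w, 1L, s)
  cz <- partial_derivative(field$v, 1L, s) - partial_derivative(field$u, 2L, s)
  structure(list(cx = cx, cy = cy, cz = cz, shape = field$shape,
                 spacing = field$spacing, origin = field$origin,
                 direction = field$direction),
            class = "curl_field")
}

#' Vortex map of a displacement field
#'
#' The voxelwise Euclidean magnitude of [compute_curl()]: a non-negative,
#' dimensionless scalar volume in which smooth anatomical deformation scores
#' near zero and local circulation ("vortexes") scores high. Hotspots flag
#' regions where a registration solution is unlikely to describe real tissue
#' motion.
#'
#' @param field a [vector_field()].
#' @return An object of class `vortex_map` (an [image_volume()] subclass with
#'   non-negative values on the source grid).
#' @export
vortex_map <- function(field) {
  cf <- compute_curl(field)
  m <- image_volume(sqrt(cf$cx^2 + cf$cy^2 + cf$cz^2), field$spacing,
                    field$origin, field$direction)
  class(m) <- c("vortex_map", class(m))
  m
}

#' Summary statistics of a vortex map
#'
#' Minimum, maximum, mean and 99th percentile over an optional mask. The
#' maximum is the primary figure of merit (clinical reports quote map
#' ranges); p99 is provided alongside because the maximum is a single-voxel
#' statistic. The percentile uses linear interpolation between order
#' statistics.
#'
#' @param map a `vortex_map` (or any [image_volume()]).
#' @param mask optional binary mask (`image_volume` or logical/numeric array)
#'   on the same grid; statistics are restricted to `mask > 0`.
#' @return A list of class `vortex_stats`: `min`, `max`, `mean`, `p99`,
#'   `n_voxels`.
#' @export
field_stats <- function(map, mask = NULL) {
  vals <- map$values
  if (!is.null(mask)) {
    mv <- if (inherits(mask, "image_volume")) {
      stop_if_incompatible(map, mask, "map/mask grids")
      mask$values
    } else mask
    if (!identical(dim(mv), dim(vals))) stop("mask shape does not match map")
    vals <- vals[mv > 0]
    if (length(vals) == 0L) stop("mask selects no voxels")
  }
  structure(list(min = min(vals), max = max(vals), mean = mean(vals),
                 p99 = unname(stats::quantile(vals, 0.99, type = 7)),
                 n_voxels = length(vals)),
            class = "vortex_stats")
}

#' @export
print.vortex_stats <- function(x, ...) {
  cat(sprintf(
    "vortex map over %d voxels: range %.4g .. %.4g, mean %.4g, p99 %.4g\n",
    x$n_voxels, x$min, x$max, x$mean, x$p99))
  invisible(x)
}

#' Gaussian smoothing of a scalar grid
#'
#' Separable Gaussian convolution with replicate-edge padding; sigma is given
#' in mm and converted to voxels per axis. Used by the demons fixture's
#' per-iteration field regularisation. `sigma_mm = 0` is the identity.
#'
#' @param grid numeric 3-D array.
#' @param sigma_mm Gaussian sigma in mm (scalar, applied on every axis).
#' @param spacing per-axis voxel size in mm.
#' @return Smoothed array of the same shape.
#' @export
gaussian_smooth <- function(grid, sigma_mm, spacing) {
  if (sigma_mm <= 0) return(grid)
  for (ax in 1:3) {
    sig <- sigma_mm / spacing[ax]
    r <- max(1L, ceiling(3 * sig))
    k <- exp(-0.5 * ((-r:r) / sig)^2)
    k <- k / sum(k)
    n <- dim(grid)[ax]
    # band matrix with replicate-edge boundary handling
    K <- matrix(0, n, n)
    for (j in seq_along(k)) {
      src <- pmin(pmax(seq_len(n) + (j - r - 1L), 1L), n)
      K[cbind(seq_len(n), src)] <- K[cbind(seq_len(n), src)] + k[j]
    }
    grid <- apply_along_axis(grid, ax, K)
  }
  grid
}
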