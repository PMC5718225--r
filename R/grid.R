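#' Construct a grid header
#'
#' A grid header carries the physical geometry of a voxel grid: shape in
#' voxels, per-axis spacing in mm, the physical origin of voxel (1,1,1), and
#' a 3x3 orthonormal direction matrix mapping index axes to physical axes.
#' The physical position of 0-based index `i` is
#' `origin + direction %*% (i * spacing)`.
#'
#' @param shape integer vector of length 3, voxels per axis (all >= 1).
#' @param spacing numeric vector of length 3, voxel size in mm (all > 0).
#' @param origin numeric vector of length 3, position of the first voxel (mm).
#' @param direction 3x3 orthonormal matrix (defaults to identity).
#' @return An object of class `grid_header`.
#' @export
grid_header <- function(shape, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        direction = diag(3)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  direction <- matrix(as.numeric(direction), 3, 3)
  if (length(shape) != 3L || any(shape < 1L))
    stop("shape must be three positive integers")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be three finite values (mm)")
  if (max(abs(crossprod(direction) - diag(3))) > 1e-6)
    stop("direction matrix must be orthonormal (tolerance 1e-6)")
  structure(list(shape = shape, spacing = spacing, origin = origin,
                 direction = direction),
            class = "grid_header")
}

#' Extract the grid header of a volume or field
#'
#' @param x a `vector_field`, `image_volume`, `vortex_map`, or `grid_header`.
#' @return A `grid_header`.
#' @export
header_of <- function(x) {
  if (inherits(x, "grid_header")) return(x)
  grid_header(x$shape, x$spacing, x$origin, x$direction)
}

#' Compare the geometry of two grids
#'
#' Checks shape equality, spacing agreement to 1e-6 mm, and origin agreement
#' to 1e-3 mm. Used to guard operations that require voxel-to-voxel
#' correspondence (this package never resamples).
#'
#' @param a,b grid headers, or objects carrying one (see [header_of()]).
#' @return A list with logical entries `same_shape`, `same_spacing`,
#'   `same_origin`, and `compatible` (the conjunction of the three).
#' @export
check_grids <- function(a, b) {
  a <- header_of(a); b <- header_of(b)
  out <- list(
    same_shape   = all(a$shape == b$shape),
    same_spacing = all(abs(a$spacing - b$spacing) <= 1e-6),
    same_origin  = all(abs(a$origin - b$origin) <= 1e-3)
  )
  out$compatible <- out$same_shape && out$same_spacing && out$same_origin
  out
}

stop_if_incompatible <- function(a, b, what = "grids") {
  cmp <- check_grids(a, b)
  if (!cmp$compatible)
    stop(sprintf("incompatible %s: same_shape=%s same_spacing=%s same_origin=%s",
                 what, cmp$same_shape, cmp$same_spacing, cmp$same_origin))
  invisible(cmp)
}

#' Physical coordinates of every voxel
#'
#' @param header a `grid_header` (or an object carrying one).
#' @return A list of three arrays (`x`, `y`, `z`), each of the grid's shape,
#'   giving the physical coordinate of each voxel centre in mm.
#' @export
grid_coordinates <- function(header) {
  h <- header_of(header)
  n <- h$shape
  ix <- (seq_len(n[1]) - 1) * h$spacing[1]
  iy <- (seq_len(n[2]) - 1) * h$spacing[2]
  iz <- (seq_len(n[3]) - 1) * h$spacing[3]
  # index-space offsets on each axis, then rotate into the physical frame
  gx <- array(ix, n)
  gy <- array(rep(iy, each = n[1]), n)
  gz <- array(rep(iz, each = n[1] * n[2]), n)
  D <- h$direction
  list(x = h$origin[1] + D[1, 1] * gx + D[1, 2] * gy + D[1, 3] * gz,
       y = h$origin[2] + D[2, 1] * gx + D[2, 2] * gy + D[2, 3] * gz,
       z = h$origin[3] + D[3, 1] * gx + D[3, 2] * gy + D[3, 3] * gz)
}

#' @export
print.grid_header <- function(x, ...) {
  cat(sprintf("grid %dx%dx%d, spacing %s mm, origin %s mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              paste(format(x$spacing), collapse = "x"),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}
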