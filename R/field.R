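#' Construct a displacement vector field
#'
#' A `vector_field` holds a 3-D displacement field u = (u, v, w): three scalar
#' grids giving the displacement in mm along the first, second and third
#' physical axes, together with grid geometry. This is the native output of a
#' deformable image registration and the input to the vortex-map metric.
#'
#' All three components must share one shape and be finite everywhere; NaN or
#' Inf displacements are rejected at construction rather than silently
#' propagated into the vortex map.
#'
#' @param u,v,w numeric 3-D arrays of identical shape, displacement in mm.
#' @param spacing,origin,direction grid geometry, see [grid_header()].
#' @return An object of class `vector_field`.
#' @export
vector_field <- function(u, v, w, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         direction = diag(3)) {
  if (length(dim(u)) != 3L)
    stop("components must be 3-D arrays")
  if (!identical(dim(u), dim(v)) || !identical(dim(u), dim(w)))
    stop("components u, v, w must share one shape")
  if (anyNA(u) || anyNA(v) || anyNA(w) ||
      !all(is.finite(range(u))) || !all(is.finite(range(v))) ||
      !all(is.finite(range(w))))
    stop("displacement values must be finite")
  h <- grid_header(dim(u), spacing, origin, direction)
  structure(list(u = u, v = v, w = w, shape = h$shape, spacing = h$spacing,
                 origin = h$origin, direction = h$direction),
            class = "vector_field")
}

#' Construct a scalar image volume
#'
#' Carrier for CT/CBCT-like anatomy (Hounsfield units) or any scalar grid on
#' the same geometry model as [vector_field()]. Binary structure masks are
#' `image_volume`s with values in \{0, 1\}.
#'
#' @param values numeric 3-D array.
#' @param spacing,origin,direction grid geometry, see [grid_header()].
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         direction = diag(3)) {
  if (length(dim(values)) != 3L)
    stop("values must be a 3-D array")
  if (anyNA(values) || !all(is.finite(range(values))))
    stop("image values must be finite")
  h <- grid_header(dim(values), spacing, origin, direction)
  structure(list(values = values, shape = h$shape, spacing = h$spacing,
                 origin = h$origin, direction = h$direction),
            class = "image_volume")
}

#' @export
print.vector_field <- function(x, ...) {
  mag <- sqrt(x$u^2 + x$v^2 + x$w^2)
  cat("displacement vector field\n  ")
  print(header_of(x))
  cat(sprintf("  |u| range %.4g .. %.4g mm, mean %.4g mm\n",
              min(mag), max(mag), mean(mag)))
  invisible(x)
}

#' @export
print.image_volume <- function(x, ...) {
  cat("scalar image volume\n  ")
  print(header_of(x))
  cat(sprintf("  value range %.5g .. %.5g\n", min(x$values), max(x$values)))
  invisible(x)
}
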