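# Synthetic phantoms, analytic deformations with closed-form curl, random
# smooth fields, and defect/artifact injectors. These emulate the QA
# protocol of a rigid body phantom with constant-HU cylinder/cube inserts
# imaged at 2.5 mm slice thickness, deformed by known fields and corrupted
# by CBCT-like streak and HU-calibration artifacts.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", .GlobalEnv, inherits = FALSE)) {
    old <- get(".Random.seed", .GlobalEnv)
    on.exit(assign(".Random.seed", old, .GlobalEnv))
  } else {
    on.exit(rm(".Random.seed", envir = .GlobalEnv))
  }
  set.seed(seed)
  code
}

#' Declare a synthetic phantom
#'
#' @param shape grid shape in voxels.
#' @param spacing voxel size in mm; the default 1 x 1 x 2.5 mm mimics a CT
#'   acquisition with 2.5 mm slice thickness.
#' @param origin physical origin, mm.
#' @param background_hu background intensity (air, -1000 HU).
#' @param inserts list of inserts; each a list with `shape` ("cylinder" or
#'   "cube"), `center` (mm), `size` (cylinder: `c(radius, height)` mm, axis
#'   along z; cube: side length or three side lengths, mm), and `hu`.
#' @return A `phantom_spec` list, validated lazily by [make_phantom()].
#' @export
phantom_spec <- function(shape = c(64, 64, 32), spacing = c(1, 1, 2.5),
                         origin = c(0, 0, 0), background_hu = -1000,
                         inserts = list()) {
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 origin = as.numeric(origin),
                 background_hu = background_hu, inserts = inserts),
            class = "phantom_spec")
}

insert_mask <- function(ins, coords) {
  cx <- coords$x - ins$center[1]
  cy <- coords$y - ins$center[2]
  cz <- coords$z - ins$center[3]
  if (ins$shape == "cylinder") {
    r <- ins$size[1]; h <- ins$size[2]
    cx^2 + cy^2 <= r^2 & abs(cz) <= h / 2
  } else if (ins$shape == "cube") {
    s <- rep(ins$size, length.out = 3)
    abs(cx) <= s[1] / 2 & abs(cy) <= s[2] / 2 & abs(cz) <= s[3] / 2
  } else stop("unknown insert shape: ", ins$shape)
}

insert_extent <- function(ins) {
  if (ins$shape == "cylinder") {
    r <- ins$size[1]; h <- ins$size[2]
    rbind(ins$center - c(r, r, h / 2), ins$center + c(r, r, h / 2))
  } else {
    s <- rep(ins$size, length.out = 3)
    rbind(ins$center - s / 2, ins$center + s / 2)
  }
}

#' Build a constant-HU phantom volume with per-insert masks
#'
#' Voxels whose physical centre lies inside an insert take that insert's HU
#' (later inserts overwrite earlier ones); everything else is background.
#' Voxel-centre containment makes the voxel counts deterministic and
#' testable against analytic volumes.
#'
#' @param spec a [phantom_spec()].
#' @return A list: `image` (an [image_volume()]) and `masks` (one binary
#'   [image_volume()] per insert, named `insert_1`, `insert_2`, ... or by
#'   the insert's `name` if given).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- grid_header(spec$shape, spec$spacing, spec$origin)
  coords <- grid_coordinates(h)
  lo <- h$origin
  hi <- h$origin + (h$shape - 1) * h$spacing
  vol <- array(spec$background_hu, spec$shape)
  masks <- list()
  for (i in seq_along(spec$inserts)) {
    ins <- spec$inserts[[i]]
    ext <- insert_extent(ins)
    if (any(ext[1, ] < lo) || any(ext[2, ] > hi))
      stop("insert ", i, " extends outside the grid")
    m <- insert_mask(ins, coords)
    vol[m] <- ins$hu
    nm <- ins$name %||% paste0("insert_", i)
    masks[[nm]] <- image_volume(array(as.numeric(m), spec$shape),
                                spec$spacing, spec$origin)
  }
  list(image = image_volume(vol, spec$spacing, spec$origin), masks = masks)
}

#' Analytic displacement fields with closed-form curl
#'
#' Generates reference deformations whose curl is known exactly:
#' \describe{
#'   \item{translation}{constant vector (curl 0).}
#'   \item{rotation}{u = omega x (r - c), rigid rotation rate; curl is
#'     2*omega everywhere.}
#'   \item{expansion}{radial field m (r - c) max(0, 1 - |r - c|/R):
#'     compactly supported inflation/shrinkage mimicking tumour volume
#'     change; curl-free by symmetry.}
#'   \item{gradient}{u = grad(phi) for a quadratic polynomial phi
#'     (coefficients named `x2, y2, z2, xy, xz, yz, x, y, z`); exactly
#'     curl-free.}
#' }
#'
#' @param kind one of `"translation"`, `"rotation"`, `"expansion"`,
#'   `"gradient"`.
#' @param header target grid (a `grid_header` or object carrying one).
#' @param vector translation vector, mm.
#' @param omega rotation-rate vector (dimensionless curl/2).
#' @param center rotation/expansion centre, mm.
#' @param magnitude expansion magnitude (peak radial displacement factor).
#' @param radius expansion support radius, mm.
#' @param phi named coefficients of the quadratic polynomial.
#' @return A [vector_field()].
#' @export
analytic_field <- function(kind, header, vector = c(0, 0, 0),
                           omega = c(0, 0, 0.1), center = NULL,
                           magnitude = 1, radius = 20,
                           phi = c(x2 = 1, y2 = 1)) {
  h <- header_of(header)
  coords <- grid_coordinates(h)
  mid <- h$origin + (h$shape - 1) * h$spacing / 2
  if (is.null(center)) center <- mid
  zeros <- array(0, h$shape)
  comp <- switch(kind,
    translation = list(u = zeros + vector[1], v = zeros + vector[2],
                       w = zeros + vector[3]),
    rotation = {
      rx <- coords$x - center[1]; ry <- coords$y - center[2]
      rz <- coords$z - center[3]
      list(u = omega[2] * rz - omega[3] * ry,
           v = omega[3] * rx - omega[1] * rz,
           w = omega[1] * ry - omega[2] * rx)
    },
    expansion = {
      rx <- coords$x - center[1]; ry <- coords$y - center[2]
      rz <- coords$z - center[3]
      d <- sqrt(rx^2 + ry^2 + rz^2)
      f <- magnitude * pmax(0, 1 - d / radius)
      list(u = rx * f, v = ry * f, w = rz * f)
    },
    gradient = {
      p <- function(nm) if (nm %in% names(phi)) phi[[nm]] else 0
      x <- coords$x; y <- coords$y; z <- coords$z
      list(u = 2 * p("x2") * x + p("xy") * y + p("xz") * z + p("x"),
           v = 2 * p("y2") * y + p("xy") * x + p("yz") * z + p("y"),
           w = 2 * p("z2") * z + p("xz") * x + p("yz") * y + p("z"))
    },
    stop("unknown field kind: ", kind))
  vector_field(comp$u, comp$v, comp$w, h$spacing, h$origin, h$direction)
}

# Uniform cubic B-spline basis weights for local coordinate t in [0,1).
bspline_weights <- function(t) {
  cbind((1 - t)^3 / 6,
        (3 * t^3 - 6 * t^2 + 4) / 6,
        (-3 * t^3 + 3 * t^2 + 3 * t + 1) / 6,
        t^3 / 6)
}

# nx x K interpolation matrix from K lattice nodes (spacing hs mm, first
# node at -hs relative to the grid origin) to nx voxels at spacing h.
bspline_axis_matrix <- function(n, h, hs) {
  pos <- (seq_len(n) - 1) * h / hs + 1  # in node units, node 0 at -hs
  i <- floor(pos)
  t <- pos - i
  K <- max(i) + 3L
  W <- matrix(0, n, K)
  B <- bspline_weights(t)
  for (m in 0:3)
    W[cbind(seq_len(n), i + m)] <- B[, m + 1]
  W
}

#' Random smooth field from a cubic B-spline lattice
#'
#' Draws independent node displacements uniformly in
#' `[-amplitude, amplitude]` mm per component on a sparse control lattice
#' and interpolates to the voxel grid with uniform cubic B-splines — the
#' displacement at any voxel is obtained by interpolation from the closest
#' lattice nodes, as in parametric B-spline registration. Coarser lattices
#' (larger `node_spacing_mm`) act as stronger regularisation and yield
#' smoother, lower-curl fields. Bit-reproducible for a fixed seed.
#'
#' @param header target grid.
#' @param node_spacing_mm lattice node spacing in mm (>= 2 voxels).
#' @param amplitude_mm maximum node displacement per component, mm.
#' @param seed integer RNG seed.
#' @return A [vector_field()].
#' @export
bspline_random_field <- function(header, node_spacing_mm, amplitude_mm,
                                 seed) {
  h <- header_of(header)
  if (any(node_spacing_mm < 2 * h$spacing))
    stop("node spacing must be at least 2 voxels")
  hs <- rep(node_spacing_mm, length.out = 3)
  W <- lapply(1:3, function(ax)
    bspline_axis_matrix(h$shape[ax], h$spacing[ax], hs[ax]))
  K <- vapply(W, ncol, 0L)
  comps <- with_seed(seed, lapply(1:3, function(k)
    array(stats::runif(prod(K), -amplitude_mm, amplitude_mm), K)))
  interp <- function(C) {
    A <- W[[1]] %*% matrix(C, K[1], K[2] * K[3])        # nx x (Ky Kz)
    dim(A) <- c(h$shape[1], K[2], K[3])
    A <- aperm(A, c(2, 1, 3))
    A <- W[[2]] %*% matrix(A, K[2], h$shape[1] * K[3])  # ny x (nx Kz)
    dim(A) <- c(h$shape[2], h$shape[1], K[3])
    A <- aperm(A, c(3, 2, 1))
    A <- W[[3]] %*% matrix(A, K[3], h$shape[1] * h$shape[2])
    dim(A) <- c(h$shape[3], h$shape[1], h$shape[2])
    aperm(A, c(2, 3, 1))
  }
  if (amplitude_mm == 0)
    comps <- lapply(comps, function(C) array(0, K))
  vector_field(interp(comps[[1]]), interp(comps[[2]]), interp(comps[[3]]),
               h$spacing, h$origin, h$direction)
}

#' Inject a localised rotational defect
#'
#' Adds a compactly supported swirl
#' `delta_u = omega x (r - c) * w(|r - c| / radius)` with the smooth bump
#' `w(t) = (1 - t^2)^2` (1 at the centre, 0 at the rim, zero slope at the
#' centre so the peak curl magnitude is close to `2 |omega|`). Outside the
#' radius the field is untouched. This is the canonical "vectors engage in
#' circular motion" failure a vortex map must flag.
#'
#' @param field a [vector_field()].
#' @param center defect centre, mm (must lie inside the grid).
#' @param radius support radius, mm (> 0).
#' @param omega rotation-rate vector; the injected curl peaks near
#'   `2 |omega|`.
#' @return The modified [vector_field()].
#' @export
inject_vortex <- function(field, center, radius, omega) {
  stopifnot(inherits(field, "vector_field"))
  if (radius <= 0) stop("radius must be > 0")
  h <- header_of(field)
  lo <- h$origin; hi <- h$origin + (h$shape - 1) * h$spacing
  if (any(center < lo) || any(center > hi))
    stop("center lies outside the grid")
  coords <- grid_coordinates(h)
  rx <- coords$x - center[1]; ry <- coords$y - center[2]
  rz <- coords$z - center[3]
  t2 <- (rx^2 + ry^2 + rz^2) / radius^2
  wgt <- ifelse(t2 < 1, (1 - t2)^2, 0)
  vector_field(field$u + (omega[2] * rz - omega[3] * ry) * wgt,
               field$v + (omega[3] * rx - omega[1] * rz) * wgt,
               field$w + (omega[1] * ry - omega[2] * rx) * wgt,
               h$spacing, h$origin, h$direction)
}

#' Inject a CBCT-like image artifact
#'
#' Two artifact kinds seen in cone-beam CT are emulated:
#' \describe{
#'   \item{streak_crosshair}{on the axial slice through `center`, voxels
#'     within `width_vox` voxels of two orthogonal lines (along x and y)
#'     through the centre, up to `arm_length_vox` voxels per arm, are set to
#'     `hu` — mimicking high-density streak artifacts.}
#'   \item{hu_offset}{values inside `mask` are shifted by `delta` HU —
#'     mimicking CT-number calibration errors.}
#' }
#'
#' @param image an [image_volume()].
#' @param kind `"streak_crosshair"` or `"hu_offset"`.
#' @param center crosshair centre, mm.
#' @param width_vox half-width of each streak arm in voxels (default 0.5,
#'   i.e. a 1-voxel-wide line).
#' @param arm_length_vox arm length in voxels from the centre.
#' @param hu intensity assigned to streak voxels.
#' @param mask binary mask ([image_volume()] or array) for `hu_offset`.
#' @param delta HU shift for `hu_offset`.
#' @return The modified [image_volume()].
#' @export
inject_artifact <- function(image, kind, center = NULL, width_vox = 0.5,
                            arm_length_vox = 8, hu = 1000, mask = NULL,
                            delta = 0) {
  stopifnot(inherits(image, "image_volume"))
  vals <- image$values
  if (kind == "streak_crosshair") {
    h <- header_of(image)
    if (is.null(center))
      center <- h$origin + (h$shape - 1) * h$spacing / 2
    cidx <- round((center - h$origin) / h$spacing) + 1
    k <- as.integer(cidx[3])
    if (k < 1L || k > h$shape[3]) stop("center lies outside the grid")
    ii <- slice.index(vals, 1); jj <- slice.index(vals, 2)
    di <- abs(ii - cidx[1]); dj <- abs(jj - cidx[2])
    on_slice <- slice.index(vals, 3) == k
    arm_x <- dj <= width_vox & di <= arm_length_vox
    arm_y <- di <= width_vox & dj <= arm_length_vox
    vals[on_slice & (arm_x | arm_y)] <- hu
  } else if (kind == "hu_offset") {
    if (is.null(mask)) stop("hu_offset requires a mask")
    mv <- if (inherits(mask, "image_volume")) mask$values else mask
    if (!identical(dim(mv), dim(vals))) stop("mask shape mismatch")
    vals[mv > 0] <- vals[mv > 0] + delta
  } else stop("unknown artifact kind: ", kind)
  image_volume(vals, image$spacing, image$origin, image$direction)
}

#' Warp a scalar image with a displacement field
#'
#' Backward warping: `output(x) = image(x + u(x))`, with nearest-neighbour
#' or trilinear interpolation. Samples falling outside the volume take
#' `background`.
#'
#' @param image an [image_volume()].
#' @param field a [vector_field()] on the same grid.
#' @param interpolation `"linear"` (default) or `"nearest"`.
#' @param background value for out-of-volume samples (default: minimum of
#'   the image, i.e. air for HU data).
#' @return The warped [image_volume()].
#' @export
warp_image <- function(image, field, interpolation = c("linear", "nearest"),
                       background = NULL) {
  interpolation <- match.arg(interpolation)
  stopifnot(inherits(image, "image_volume"), inherits(field, "vector_field"))
  stop_if_incompatible(image, field, "image/field grids")
  if (is.null(background)) background <- min(image$values)
  h <- header_of(image)
  d <- h$shape
  # sample position in continuous 1-based index space; direction^T maps the
  # physical displacement back into index axes
  Dt <- t(h$direction)
  du <- Dt[1, 1] * field$u + Dt[1, 2] * field$v + Dt[1, 3] * field$w
  dv <- Dt[2, 1] * field$u + Dt[2, 2] * field$v + Dt[2, 3] * field$w
  dw <- Dt[3, 1] * field$u + Dt[3, 2] * field$v + Dt[3, 3] * field$w
  px <- c(slice.index(image$values, 1)) + c(du) / h$spacing[1]
  py <- c(slice.index(image$values, 2)) + c(dv) / h$spacing[2]
  pz <- c(slice.index(image$values, 3)) + c(dw) / h$spacing[3]
  vals <- c(image$values)
  lin <- function(i, j, k) vals[i + d[1] * (j - 1L) + d[1] * d[2] * (k - 1L)]
  if (interpolation == "nearest") {
    i <- round(px); j <- round(py); k <- round(pz)
    inb <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2] & k >= 1 & k <= d[3]
    out <- rep(background, length(px))
    out[inb] <- lin(i[inb], j[inb], k[inb])
  } else {
    i0 <- floor(px); j0 <- floor(py); k0 <- floor(pz)
    fx <- px - i0; fy <- py - j0; fz <- pz - k0
    inb <- i0 >= 1 & i0 + 1 <= d[1] & j0 >= 1 & j0 + 1 <= d[2] &
           k0 >= 1 & k0 + 1 <= d[3]
    out <- rep(background, length(px))
    i0 <- i0[inb]; j0 <- j0[inb]; k0 <- k0[inb]
    fx <- fx[inb]; fy <- fy[inb]; fz <- fz[inb]
    out[inb] <-
      lin(i0,      j0,      k0)      * (1 - fx) * (1 - fy) * (1 - fz) +
      lin(i0 + 1L, j0,      k0)      * fx       * (1 - fy) * (1 - fz) +
      lin(i0,      j0 + 1L, k0)      * (1 - fx) * fy       * (1 - fz) +
      lin(i0 + 1L, j0 + 1L, k0)      * fx       * fy       * (1 - fz) +
      lin(i0,      j0,      k0 + 1L) * (1 - fx) * (1 - fy) * fz +
      lin(i0 + 1L, j0,      k0 + 1L) * fx       * (1 - fy) * fz +
      lin(i0,      j0 + 1L, k0 + 1L) * (1 - fx) * fy       * fz +
      lin(i0 + 1L, j0 + 1L, k0 + 1L) * fx       * fy       * fz
  }
  image_volume(array(out, d), h$spacing, h$origin, h$direction)
}

#' Approximate inverse of a displacement field
#'
#' Fixed-point iteration `v_{k+1}(x) = -u(x + v_k(x))`: the standard
#' first-order inversion used to sanity-check warps on synthetic data.
#' Out-of-volume lookups clamp to the nearest edge voxel.
#'
#' @param field a [vector_field()].
#' @param iterations fixed-point iterations (default 20).
#' @return A [vector_field()] approximating the inverse deformation.
#' @export
invert_field <- function(field, iterations = 20L) {
  h <- header_of(field)
  d <- h$shape
  sample_comp <- function(g, px, py, pz) {
    # trilinear with edge clamping
    px <- pmin(pmax(px, 1), d[1]); py <- pmin(pmax(py, 1), d[2])
    pz <- pmin(pmax(pz, 1), d[3])
    i0 <- pmin(floor(px), d[1] - 1L); j0 <- pmin(floor(py), d[2] - 1L)
    k0 <- pmin(floor(pz), d[3] - 1L)
    fx <- px - i0; fy <- py - j0; fz <- pz - k0
    vals <- c(g)
    lin <- function(i, j, k) vals[i + d[1] * (j - 1L) + d[1] * d[2] * (k - 1L)]
    lin(i0, j0, k0) * (1 - fx) * (1 - fy) * (1 - fz) +
      lin(i0 + 1L, j0, k0) * fx * (1 - fy) * (1 - fz) +
      lin(i0, j0 + 1L, k0) * (1 - fx) * fy * (1 - fz) +
      lin(i0 + 1L, j0 + 1L, k0) * fx * fy * (1 - fz) +
      lin(i0, j0, k0 + 1L) * (1 - fx) * (1 - fy) * fz +
      lin(i0 + 1L, j0, k0 + 1L) * fx * (1 - fy) * fz +
      lin(i0, j0 + 1L, k0 + 1L) * (1 - fx) * fy * fz +
      lin(i0 + 1L, j0 + 1L, k0 + 1L) * fx * fy * fz
  }
  bx <- c(slice.index(field$u, 1)); by <- c(slice.index(field$u, 2))
  bz <- c(slice.index(field$u, 3))
  vu <- vv <- vw <- numeric(length(bx))
  for (it in seq_len(iterations)) {
    px <- bx + vu / h$spacing[1]
    py <- by + vv / h$spacing[2]
    pz <- bz + vw / h$spacing[3]
    vu <- -sample_comp(field$u, px, py, pz)
    vv <- -sample_comp(field$v, px, py, pz)
    vw <- -sample_comp(field$w, px, py, pz)
  }
  vector_field(array(vu, d), array(vv, d), array(vw, d),
               h$spacing, h$origin, h$direction)
}

#' Dilate a binary mask
#'
#' Chebyshev (box) dilation by `voxels` voxels, used to give structure
#' masks a tolerance margin when testing whether hotspots fall "inside" an
#' artifact region.
#'
#' @param mask an [image_volume()] with values in \{0, 1\}.
#' @param voxels dilation radius in voxels.
#' @return The dilated binary [image_volume()].
#' @export
dilate_mask <- function(mask, voxels = 3L) {
  m <- mask$values > 0
  d <- dim(m)
  for (rep in seq_len(voxels)) {
    for (ax in 1:3) {
      perm <- c(ax, setdiff(1:3, ax))
      a <- aperm(m, perm)
      n <- dim(a)[1]
      lo <- a; lo[2:n, , ] <- a[1:(n - 1), , ] | a[2:n, , ]
      hi <- lo; hi[1:(n - 1), , ] <- lo[1:(n - 1), , ] | lo[2:n, , ]
      m <- aperm(hi, order(perm))
    }
  }
  image_volume(array(as.numeric(m), d), mask$spacing, mask$origin,
               mask$direction)
}

#' Scaled-down phantom QA protocol
#'
#' Builds the full synthetic QA experiment: a rigid-body-style phantom with
#' two cylinder inserts and one cube control on a 64x64x64 grid with 2.5 mm
#' slices; a "fixed" acquisition in which the two cylinders are expanded
#' (mimicking tumour volume change between scans) and which additionally
#' carries a crosshair streak artifact and an HU-calibration offset region
#' (the CBCT-like target image); and the demons registration of the clean
#' "moving" phantom onto that target. Registration runs without field
#' smoothing — the low-regularization regime in which artifacts provoke
#' fragmented, high-curl displacement.
#'
#' The expected physics: the streak and HU-offset regions, which violate
#' the monomodality assumption, become the strongest vortex hotspots, while
#' the cleanly expanded inserts produce smoother, lower-curl deformation.
#'
#' @param iterations demons iterations (default 60).
#' @param smooth_sigma_mm demons field smoothing; `NULL` (default)
#'   reproduces the artifact-hotspot regime.
#' @return A list: `fixed`, `moving` ([image_volume()]s), `field`
#'   (the demons [vector_field()]), `map` (its `vortex_map`),
#'   `insert_masks` (expanded inserts + control, on the fixed image),
#'   `artifact_masks` (`streak`, `hu_offset`).
#' @export
phantom_protocol <- function(iterations = 60L, smooth_sigma_mm = NULL) {
  shape <- c(64L, 64L, 64L); spacing <- c(1, 1, 2.5)
  mk <- function(r1, r2) phantom_spec(shape, spacing, inserts = list(
    list(shape = "cylinder", center = c(20, 20, 80), size = c(r1, 40),
         hu = 0, name = "insert_1"),
    list(shape = "cylinder", center = c(44, 44, 80), size = c(r2, 40),
         hu = 100, name = "insert_2"),
    list(shape = "cube", center = c(44, 20, 80), size = 16,
         hu = -200, name = "insert_3")))
  moving <- make_phantom(mk(8, 6))
  fixed <- make_phantom(mk(11, 9))     # inserts expanded between scans
  streak_center <- c(20, 44, 80)
  hu_mask <- make_phantom(phantom_spec(shape, spacing, inserts = list(
    list(shape = "cylinder", center = c(32, 32, 40), size = c(6, 15),
         hu = 1))))$masks[[1]]
  fimg <- inject_artifact(fixed$image, "streak_crosshair",
                          center = streak_center, arm_length_vox = 10,
                          hu = 1000)
  fimg <- inject_artifact(fimg, "hu_offset", mask = hu_mask, delta = 400)
  h <- header_of(fimg)
  ci <- round((streak_center - h$origin) / h$spacing) + 1
  streak_mask <- array(0, shape)
  streak_mask[(ci[1] - 10):(ci[1] + 10), (ci[2] - 10):(ci[2] + 10), ci[3]] <- 1
  # keep only the crosshair arms, not the whole square
  ii <- slice.index(streak_mask, 1); jj <- slice.index(streak_mask, 2)
  streak_mask[abs(ii - ci[1]) > 0.5 & abs(jj - ci[2]) > 0.5] <- 0
  field <- demons_register(fimg, moving$image, iterations = iterations,
                           smooth_sigma_mm = smooth_sigma_mm)
  list(fixed = fimg, moving = moving$image, field = field,
       map = vortex_map(field),
       insert_masks = fixed$masks,
       artifact_masks = list(
         streak = image_volume(streak_mask, spacing),
         hu_offset = hu_mask))
}
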