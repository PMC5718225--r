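# Hotspot localisation in a vortex map and plausibility classification.
# Connected components of the suprathreshold set are labelled via the
# adjacency graph of suprathreshold voxels (igraph::components); 6- or
# 26-connectivity is selected by the neighbour offsets used to build edges.

neighbour_offsets <- function(connectivity) {
  if (connectivity == 6L) {
    rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  } else if (connectivity == 26L) {
    off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
    # keep one representative of each symmetric pair
    off[off %*% c(1, 3, 9) > 0, , drop = FALSE]
  } else stop("connectivity must be 6 or 26")
}

#' Detect vortex hotspot regions
#'
#' Labels the connected components of `map > threshold`, discards components
#' smaller than `min_region_size` voxels, and summarises each surviving
#' region. Labels are assigned in scan order (first axis fastest); the
#' returned list is sorted by peak value descending, ties broken by
#' ascending label, so the strongest hotspot comes first.
#'
#' @param map a `vortex_map` (see [vortex_map()]).
#' @param threshold detection threshold (> 0); the default is the lower edge
#'   of the non-physical band.
#' @param connectivity 6 (face neighbours) or 26 (face+edge+corner).
#' @param min_region_size smallest region kept, in voxels (>= 1).
#' @return A list of `vortex_region` objects, each with `label`,
#'   `voxel_count`, `volume_mm3`, `peak_value`, `peak_index` (1-based voxel
#'   index), `centroid_mm` (intensity-weighted physical centroid), and the
#'   region's voxel linear indices in `voxels`.
#' @export
detect_regions <- function(map, threshold = 5, connectivity = 26L,
                           min_region_size = 3L) {
  stopifnot(inherits(map, "image_volume"))
  if (threshold <= 0) stop("threshold must be > 0")
  if (min_region_size < 1L) stop("min_region_size must be >= 1")
  vals <- map$values
  d <- dim(vals)
  sel <- which(vals > threshold)
  if (length(sel) == 0L) return(list())
  vid <- integer(prod(d)); vid[sel] <- seq_along(sel)
  ind <- arrayInd(sel, d)
  offs <- neighbour_offsets(as.integer(connectivity))
  edges <- NULL
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(ind, 2, offs[r, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    lin <- nb[ok, 1] + d[1] * (nb[ok, 2] - 1L) + d[1] * d[2] * (nb[ok, 3] - 1L)
    tgt <- vid[lin]
    hit <- tgt > 0L
    if (any(hit))
      edges <- rbind(edges, cbind(which(ok)[hit], tgt[hit]))
  }
  g <- igraph::make_empty_graph(n = length(sel), directed = FALSE)
  if (!is.null(edges))
    g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  # component ids in scan order of each component's first voxel
  first_seen <- !duplicated(comp)
  order_map <- integer(max(comp))
  order_map[comp[first_seen]] <- seq_len(sum(first_seen))
  comp <- order_map[comp]

  coords <- grid_coordinates(map)
  voxvol <- prod(map$spacing)
  regions <- list()
  lab <- 0L
  for (cid in seq_len(max(comp))) {
    vox <- sel[comp == cid]
    if (length(vox) < min_region_size) next
    lab <- lab + 1L
    v <- vals[vox]
    peak_at <- vox[which.max(v)]
    wsum <- sum(v)
    regions[[lab]] <- structure(list(
      label = lab,
      voxel_count = length(vox),
      volume_mm3 = length(vox) * voxvol,
      peak_value = max(v),
      peak_index = as.integer(arrayInd(peak_at, d)),
      centroid_mm = c(sum(coords$x[vox] * v), sum(coords$y[vox] * v),
                      sum(coords$z[vox] * v)) / wsum,
      voxels = vox), class = "vortex_region")
  }
  if (length(regions) == 0L) return(list())
  ord <- order(-vapply(regions, `[[`, 0, "peak_value"),
               vapply(regions, `[[`, 0L, "label"))
  regions[ord]
}

#' @export
print.vortex_region <- function(x, ...) {
  cat(sprintf(
    "vortex region #%d: peak %.3f at voxel (%s), %d voxels (%.1f mm^3), centroid (%s) mm\n",
    x$label, x$peak_value, paste(x$peak_index, collapse = ","),
    x$voxel_count, x$volume_mm3,
    paste(sprintf("%.1f", x$centroid_mm), collapse = ", ")))
  invisible(x)
}

#' Default plausibility bands
#'
#' Clinically valid registration solutions show curl magnitudes roughly in
#' the 0–5 range while non-physical solutions reach 5 and beyond, with values
#' above 3 typical of regions an algorithm struggled to match; the default
#' bands encode that reading. Both edges are configurable per site.
#'
#' @param valid_max upper edge of the plausible range (default 5).
#' @param borderline_min lower edge of the borderline range (default 3).
#' @return A named list with the two thresholds, validated.
#' @export
plausibility_bands <- function(valid_max = 5, borderline_min = 3) {
  if (!(0 < borderline_min && borderline_min < valid_max))
    stop("bands must satisfy 0 < borderline_min < valid_max")
  list(valid_max = valid_max, borderline_min = borderline_min)
}

#' Classify the plausibility of a registration solution
#'
#' The verdict derives deterministically from the vortex-map maximum:
#' `nonphysical` when `max >= valid_max`, `borderline` when
#' `borderline_min <= max < valid_max`, `plausible` below. Regions are
#' carried along for reporting but do not influence the category — location-
#' based judgement (hotspots far from clinically important structures may be
#' acceptable) is surfaced separately by [structure_report()] and left to
#' the physician, mirroring how gamma-index QA is read.
#'
#' @param stats a `vortex_stats` from [field_stats()].
#' @param regions list from [detect_regions()] (may be empty).
#' @param bands see [plausibility_bands()].
#' @return A list of class `plausibility_verdict`: `category`, `max_value`,
#'   `n_regions`, `bands`.
#' @export
classify <- function(stats, regions = list(), bands = plausibility_bands()) {
  bands <- plausibility_bands(bands$valid_max, bands$borderline_min)
  m <- stats$max
  category <- if (m >= bands$valid_max) "nonphysical"
              else if (m >= bands$borderline_min) "borderline"
              else "plausible"
  structure(list(category = category, max_value = m,
                 n_regions = length(regions), bands = bands),
            class = "plausibility_verdict")
}

#' @export
print.plausibility_verdict <- function(x, ...) {
  cat(sprintf("verdict: %s (map max %.3f; bands: plausible < %g <= borderline < %g <= nonphysical; %d region%s)\n",
              x$category, x$max_value, x$bands$borderline_min,
              x$bands$valid_max, x$n_regions,
              if (x$n_regions == 1L) "" else "s"))
  invisible(x)
}

mask_surface_indices <- function(maskvals) {
  d <- dim(maskvals)
  inside <- maskvals > 0
  eroded <- inside
  # surface = inside voxels with an outside 6-neighbour (grid edge counts)
  for (ax in 1:3) {
    n <- d[ax]
    if (n < 2L) next
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(inside, perm)
    m <- dim(a)[1]
    prev <- a; prev[2:m, , ] <- a[1:(m - 1), , ]; prev[1, , ] <- FALSE
    nxt <- a; nxt[1:(m - 1), , ] <- a[2:m, , ]; nxt[m, , ] <- FALSE
    eroded <- eroded & aperm(prev & nxt, order(perm))
  }
  which(inside & !eroded)
}

#' Relate detected regions to anatomical structures
#'
#' For each named structure mask: the peak map value inside the mask, the
#' minimum distance (mm) from any region's centroid to the mask surface
#' (0 when a region's voxels intersect the mask), and a flag that is TRUE
#' when any region intersects the mask. High-curl regions near or inside
#' clinically important structures are the ones that matter; this report
#' supports that location-based reading.
#'
#' @param regions list from [detect_regions()].
#' @param structures named list of binary masks ([image_volume()]s) on the
#'   map's grid.
#' @param map the `vortex_map` the regions were detected in.
#' @return A data.frame with columns `structure`, `peak_inside`,
#'   `distance_mm` (`Inf` when there are no regions), `flag`.
#' @export
structure_report <- function(regions, structures, map) {
  stopifnot(is.list(structures), !is.null(names(structures)))
  coords <- NULL
  rows <- lapply(names(structures), function(nm) {
    msk <- structures[[nm]]
    stop_if_incompatible(map, msk, sprintf("map/mask '%s' grids", nm))
    mv <- msk$values
    inside <- which(mv > 0)
    peak_inside <- if (length(inside)) max(map$values[inside]) else 0
    if (length(regions) == 0L)
      return(data.frame(structure = nm, peak_inside = peak_inside,
                        distance_mm = Inf, flag = FALSE))
    intersects <- any(vapply(regions, function(r)
      any(mv[r$voxels] > 0), logical(1)))
    if (intersects) {
      dist <- 0
    } else {
      if (is.null(coords)) coords <<- grid_coordinates(map)
      surf <- mask_surface_indices(mv)
      sx <- coords$x[surf]; sy <- coords$y[surf]; sz <- coords$z[surf]
      dist <- min(vapply(regions, function(r) {
        c0 <- r$centroid_mm
        sqrt(min((sx - c0[1])^2 + (sy - c0[2])^2 + (sz - c0[3])^2))
      }, numeric(1)))
    }
    data.frame(structure = nm, peak_inside = peak_inside,
               distance_mm = dist, flag = intersects)
  })
  do.call(rbind, rows)
}
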