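# Gaussian-bump map fixture: analytic construction with brute-force
# suprathreshold enumeration as the oracle.
bump_map <- function(h, centers_vox, peaks, sigma_vox = 2) {
  vals <- array(0, h$shape)
  co <- list(i = slice.index(vals, 1), j = slice.index(vals, 2),
             k = slice.index(vals, 3))
  for (b in seq_along(peaks)) {
    c0 <- centers_vox[[b]]
    d2 <- (co$i - c0[1])^2 + (co$j - c0[2])^2 + (co$k - c0[3])^2
    vals <- vals + peaks[b] * exp(-d2 / (2 * sigma_vox^2))
  }
  m <- image_volume(vals, h$spacing, h$origin)
  class(m) <- c("vortex_map", class(m))
  m
}

test_that("a uniform low map yields no regions", {
  h <- small_header()
  m <- vortex_map(analytic_field("rotation", h, omega = c(0, 0, 0.1)))
  expect_length(detect_regions(m, threshold = 5), 0)
})

test_that("a single bump is found at its center with the right extent", {
  h <- grid_header(c(24, 24, 16), c(1, 1, 2))
  center <- c(12, 14, 8)
  m <- bump_map(h, list(center), peaks = 8)
  regs <- detect_regions(m, threshold = 5, connectivity = 26L,
                         min_region_size = 1L)
  expect_length(regs, 1)
  r <- regs[[1]]
  expect_equal(r$peak_index, as.integer(center))
  expect_equal(r$peak_value, max(m$values))
  # brute-force enumeration of the suprathreshold set
  expect_equal(sort(r$voxels), which(m$values > 5))
  expect_equal(r$voxel_count, sum(m$values > 5))
  expect_equal(r$volume_mm3, sum(m$values > 5) * prod(h$spacing))
  # centroid within one voxel of the bump centre (physical mm)
  ctr_mm <- h$origin + (center - 1) * h$spacing
  expect_lt(max(abs(r$centroid_mm - ctr_mm) / h$spacing), 1)
})

test_that("two disjoint bumps yield two regions ordered by peak", {
  h <- grid_header(c(32, 20, 12))
  m <- bump_map(h, list(c(8, 10, 6), c(24, 10, 6)), peaks = c(7, 9))
  regs <- detect_regions(m, threshold = 5, min_region_size = 1L)
  expect_length(regs, 2)
  expect_equal(regs[[1]]$peak_index, c(24L, 10L, 6L))
  expect_equal(regs[[2]]$peak_index, c(8L, 10L, 6L))
  expect_gt(regs[[1]]$peak_value, regs[[2]]$peak_value)
  # the union of region voxels is the full suprathreshold set
  expect_equal(sort(c(regs[[1]]$voxels, regs[[2]]$voxels)),
               which(m$values > 5))
})

test_that("min_region_size discards small components", {
  h <- grid_header(c(16, 16, 8))
  vals <- array(0, h$shape)
  vals[4, 4, 4] <- 10            # single-voxel speck
  vals[10:12, 10:12, 4] <- 8     # 9-voxel blob
  m <- image_volume(vals); class(m) <- c("vortex_map", class(m))
  regs <- detect_regions(m, threshold = 5, min_region_size = 3L)
  expect_length(regs, 1)
  expect_equal(regs[[1]]$voxel_count, 9L)
})

test_that("raising the threshold never grows the detected voxel total", {
  h <- grid_header(c(20, 20, 10))
  m <- bump_map(h, list(c(6, 6, 5), c(15, 15, 5)), peaks = c(6, 9))
  total <- function(thr) sum(vapply(
    detect_regions(m, thr, min_region_size = 1L), `[[`, 0L, "voxel_count"))
  tots <- vapply(c(1, 2, 4, 6, 8), total, 0)
  expect_true(all(diff(tots) <= 0))
})

test_that("6-connectivity refines 26-connectivity", {
  # two voxels touching only at a corner: one 26-region, two 6-regions
  h <- grid_header(c(8, 8, 8))
  vals <- array(0, h$shape)
  vals[4, 4, 4] <- 9; vals[5, 5, 5] <- 9
  m <- image_volume(vals); class(m) <- c("vortex_map", class(m))
  expect_length(detect_regions(m, 5, connectivity = 26L,
                               min_region_size = 1L), 1)
  expect_length(detect_regions(m, 5, connectivity = 6L,
                               min_region_size = 1L), 2)
})

test_that("plausibility classification follows the configured bands", {
  mkstats <- function(mx) structure(
    list(min = 0, max = mx, mean = mx / 2, p99 = mx, n_voxels = 100L),
    class = "vortex_stats")
  # reference solutions: a tightly regularized B-spline map topping out at
  # 0.65 is plausible; demons maps reaching 26.92 or 67.34 are nonphysical
  expect_equal(classify(mkstats(0.65))$category, "plausible")
  expect_equal(classify(mkstats(26.92))$category, "nonphysical")
  expect_equal(classify(mkstats(67.34))$category, "nonphysical")
  expect_equal(classify(mkstats(0))$category, "plausible")
  expect_equal(classify(mkstats(4))$category, "borderline")
  expect_equal(classify(mkstats(5))$category, "nonphysical")  # closed edge
  expect_equal(classify(mkstats(3))$category, "borderline")
  # custom bands and contract violations
  expect_equal(classify(mkstats(4),
                        bands = plausibility_bands(10, 6))$category,
               "plausible")
  expect_error(plausibility_bands(3, 5), "bands")
  # the verdict depends on the regions argument only through reporting
  v1 <- classify(mkstats(4), regions = list())
  v2 <- classify(mkstats(4), regions = list(1, 2, 3))
  expect_identical(v1$category, v2$category)
  expect_equal(v2$n_regions, 3L)
})

test_that("structure report flags intersections and measures distances", {
  h <- grid_header(c(30, 20, 10))
  m <- bump_map(h, list(c(6, 10, 5)), peaks = 9)
  regs <- detect_regions(m, 5, min_region_size = 1L)
  inside <- array(0, h$shape); inside[2:10, 6:14, 3:7] <- 1
  far <- array(0, h$shape); far[24:28, 6:14, 3:7] <- 1
  masks <- list(target = image_volume(inside, h$spacing),
                organ = image_volume(far, h$spacing))
  rep <- structure_report(regs, masks, m)
  expect_true(rep$flag[rep$structure == "target"])
  expect_equal(rep$distance_mm[rep$structure == "target"], 0)
  expect_equal(rep$peak_inside[rep$structure == "target"], max(m$values))
  expect_false(rep$flag[rep$structure == "organ"])
  # brute-force distance oracle: centroid to every mask surface voxel
  co <- grid_coordinates(h)
  surf_ok <- which(far > 0)
  c0 <- regs[[1]]$centroid_mm
  dist_all <- sqrt((co$x[surf_ok] - c0[1])^2 + (co$y[surf_ok] - c0[2])^2 +
                   (co$z[surf_ok] - c0[3])^2)
  got <- rep$distance_mm[rep$structure == "organ"]
  expect_equal(got, min(dist_all), tolerance = 1e-10)

  # no regions: flags false, infinite distance sentinel
  rep0 <- structure_report(list(), masks, m)
  expect_true(all(!rep0$flag))
  expect_true(all(is.infinite(rep0$distance_mm)))

  # mismatched grid is refused
  bad <- image_volume(array(0, c(5, 5, 5)))
  expect_error(structure_report(regs, list(x = bad), m), "incompatible")
})

test_that("centroid distance at known separation is measured correctly", {
  h <- grid_header(c(40, 12, 12))
  vals <- array(0, h$shape)
  vals[5, 6, 6] <- 10; vals[6, 6, 6] <- 9.5; vals[5, 7, 6] <- 9.5
  m <- image_volume(vals); class(m) <- c("vortex_map", class(m))
  regs <- detect_regions(m, 5, min_region_size = 1L)
  msk <- array(0, h$shape); msk[25:35, , ] <- 1
  rep <- structure_report(regs, list(wall = image_volume(msk)), m)
  # centroid is ~ (4.3, 5.3, 5) mm; mask surface starts at x = 24 mm
  expect_equal(rep$distance_mm, 24 - regs[[1]]$centroid_mm[1],
               tolerance = 1.0)
})
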