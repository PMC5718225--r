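test_that("phantom cylinder voxel count matches the analytic volume", {
  # generic placement: centre off the voxel-centre lattice, so the
  # inclusive boundary rule does not add a systematic half-voxel shell
  spec <- phantom_spec(shape = c(64, 64, 40), spacing = c(1, 1, 2.5),
                       inserts = list(list(shape = "cylinder",
                                           center = c(32.5, 32.5, 51.25),
                                           size = c(20, 40), hu = 0)))
  ph <- make_phantom(spec)
  count <- sum(ph$masks[[1]]$values)
  analytic <- pi * 20^2 * 40 / 2.5  # voxel volume 2.5 mm^3
  expect_lt(abs(count - analytic) / analytic, 0.03)
  expect_equal(sort(unique(as.vector(ph$image$values))), c(-1000, 0))
})

test_that("cube insert count matches brute-force point-in-cube enumeration", {
  spec <- phantom_spec(shape = c(24, 24, 24), spacing = c(1, 1, 1),
                       inserts = list(list(shape = "cube",
                                           center = c(11, 11, 11),
                                           size = 10, hu = 100)))
  ph <- make_phantom(spec)
  # voxel centres at integers 0..23; |c - 11| <= 5 selects 11 per axis
  brute <- sum(abs(0:23 - 11) <= 5)^3
  expect_equal(sum(ph$masks[[1]]$values), brute)
})

test_that("empty insert list gives a uniform background and misplaced inserts fail", {
  ph <- make_phantom(phantom_spec(shape = c(8, 8, 8), spacing = c(1, 1, 1)))
  expect_true(all(ph$image$values == -1000))
  expect_error(make_phantom(phantom_spec(
    shape = c(16, 16, 16), spacing = c(1, 1, 1),
    inserts = list(list(shape = "cube", center = c(2, 2, 2), size = 10,
                        hu = 0)))),
    "outside the grid")
})

test_that("expansion fields are compactly supported and curl-free inside", {
  h <- grid_header(c(32, 32, 32))
  f <- analytic_field("expansion", h, center = c(15.5, 15.5, 15.5),
                      magnitude = 0.3, radius = 10)
  co <- grid_coordinates(h)
  d <- sqrt((co$x - 15.5)^2 + (co$y - 15.5)^2 + (co$z - 15.5)^2)
  mag <- sqrt(f$u^2 + f$v^2 + f$w^2)
  expect_true(all(mag[d >= 10] == 0))
  expect_gt(max(mag), 0)
  # radial fields are analytically irrotational, but the linear falloff is
  # not polynomial in (x, y, z), so finite differences leave a small
  # discretisation residual rather than exact zeros
  m <- vortex_map(f)
  expect_lt(max(m$values[d < 8 & d > 2]), 0.05 * 2 * 0.3)
})

test_that("b-spline random fields are reproducible and scale with amplitude", {
  h <- grid_header(c(20, 20, 16), c(1, 1, 2.5))
  f1 <- bspline_random_field(h, 10, 2, seed = 42)
  f2 <- bspline_random_field(h, 10, 2, seed = 42)
  expect_identical(f1$u, f2$u)
  expect_identical(f1$w, f2$w)
  f3 <- bspline_random_field(h, 10, 2, seed = 43)
  expect_gt(max(abs(f1$u - f3$u)), 0)
  f0 <- bspline_random_field(h, 10, 0, seed = 42)
  expect_true(all(f0$u == 0) && all(f0$v == 0) && all(f0$w == 0))
  expect_error(bspline_random_field(h, 1.0, 2, seed = 1), "node spacing")
})

test_that("coarser b-spline lattices act as stronger regularization", {
  h <- grid_header(c(32, 32, 32))
  for (seed in 1:10) {
    fine <- bspline_random_field(h, 8, 3, seed = 100 + seed)
    coarse <- bspline_random_field(h, 24, 3, seed = 100 + seed)
    expect_lte(max(vortex_map(coarse)$values),
               max(vortex_map(fine)$values))
  }
})

test_that("injected vortexes have the advertised strength and support", {
  h <- grid_header(c(32, 32, 32))
  f <- inject_vortex(zero_field(h), center = c(16, 16, 16), radius = 8,
                     omega = c(0, 0, 4))
  m <- vortex_map(f)
  expect_lt(abs(max(m$values) - 8) / 8, 0.10)
  co <- grid_coordinates(h)
  d <- sqrt((co$x - 16)^2 + (co$y - 16)^2 + (co$z - 16)^2)
  expect_true(all(m$values[d > 8 + 2] == 0))
  # the peak sits at the injection centre
  expect_lt(max(abs(arrayInd(which.max(m$values), h$shape) - c(17, 17, 17))),
            2)
  # curl against the naive oracle on the injected kernel
  hsm <- grid_header(c(14, 14, 14))
  fs <- inject_vortex(zero_field(hsm), center = c(6.5, 6.5, 6.5),
                      radius = 5, omega = c(0, 0, 2))
  ref <- naive_curl(fs); got <- compute_curl(fs)
  expect_lt(max(abs(got$cz - ref$cz)), 1e-12)
  # zero omega leaves the field untouched; off-grid centres are refused
  f0 <- inject_vortex(zero_field(h), c(16, 16, 16), 8, omega = c(0, 0, 0))
  expect_true(all(f0$u == 0))
  expect_error(inject_vortex(zero_field(h), c(100, 0, 0), 8, c(0, 0, 1)),
               "outside")
})

test_that("two disjoint injections are recovered as two regions", {
  h <- grid_header(c(48, 24, 24))
  f <- inject_vortex(zero_field(h), c(12, 12, 12), 7, c(0, 0, 4))
  f <- inject_vortex(f, c(36, 12, 12), 7, c(0, 0, 3.5))
  regs <- detect_regions(vortex_map(f), threshold = 5)
  expect_length(regs, 2)
  cents <- t(vapply(regs, `[[`, numeric(3), "centroid_mm"))
  expect_lt(min(sqrt(colSums((t(cents) - c(12, 12, 12))^2))), 2)
  expect_lt(min(sqrt(colSums((t(cents) - c(36, 12, 12))^2))), 2)
})

test_that("artifact injection: HU offsets shift means exactly, streaks rasterize as expected", {
  h <- grid_header(c(32, 32, 8))
  im <- image_volume(array(50, h$shape), h$spacing)
  msk <- array(0, h$shape); msk[5:10, 5:10, 2:4] <- 1
  off <- inject_artifact(im, "hu_offset", mask = msk, delta = 100)
  expect_equal(mean(off$values[msk > 0]) - mean(im$values[msk > 0]), 100)
  expect_true(all(off$values[msk == 0] == im$values[msk == 0]))
  same <- inject_artifact(im, "hu_offset", mask = msk, delta = 0)
  expect_identical(same$values, im$values)

  st <- inject_artifact(im, "streak_crosshair", center = c(16, 16, 4),
                        width_vox = 0.5, arm_length_vox = 6, hu = 1000)
  nmod <- sum(st$values != im$values)
  # two 13-voxel arms sharing the centre voxel
  expect_equal(nmod, 13 + 13 - 1)
  expect_true(all(st$values[, , c(1:4, 6:8)] == 50))  # only slice k=5
  expect_error(inject_artifact(im, "swirl"), "unknown artifact")
})

test_that("warping: identity, integer shifts, and approximate inverses", {
  h <- grid_header(c(32, 32, 16), c(1, 1, 2))
  im <- sphere_image(h, c(16, 16, 16), 8, hu = 0, background = -1000,
                     edge_mm = 1)
  w0 <- warp_image(im, zero_field(h))
  expect_equal(w0$values, im$values, tolerance = 1e-12)
  # constant field of exactly 3 voxels along x, nearest interpolation
  z <- array(0, h$shape)
  sh <- vector_field(z + 3, z, z, h$spacing)
  wi <- warp_image(im, sh, "nearest")
  expect_equal(wi$values[1:29, , ], im$values[4:32, , ])
  # warp by f then by its fixed-point inverse: small interior error
  f <- bspline_random_field(h, 10, 1.2, seed = 4)
  w1 <- warp_image(im, f, "linear")
  w2 <- warp_image(w1, invert_field(f, 20), "linear")
  err <- abs(w2$values - im$values)[5:28, 5:28, 4:13]
  expect_lt(mean(err) / 1000, 0.02)  # 2% of the dynamic range
  expect_error(warp_image(image_volume(array(0, c(4, 4, 4))), f),
               "incompatible")
})

test_that("mask dilation grows by the requested Chebyshev radius", {
  h <- grid_header(c(16, 16, 16))
  m <- array(0, h$shape); m[8, 8, 8] <- 1
  d2 <- dilate_mask(image_volume(m), 2)
  expect_equal(sum(d2$values), 5^3)
  expect_equal(d2$values[6, 6, 6], 1)
  expect_equal(d2$values[5, 8, 8], 0)
})
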