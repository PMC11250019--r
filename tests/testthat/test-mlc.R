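jaw50 <- c(-50, 50, -50, 50)
open50 <- fifwbi:::open_aperture(default_mlc_bank(), jaw50)

raster50 <- function() bev_raster(c(-60, 60), c(-60, 60), 1)

set_pixels <- function(raster, x, z) {
  ix <- ceiling((x - raster$xmin) / raster$pixel)
  jx <- ceiling((z - raster$zmin) / raster$pixel)
  raster$values[cbind(ix, jx)] <- TRUE
  raster
}

test_that("the default bank matches the 14 x 2.5 mm + 32 x 5 mm layout", {
  b <- default_mlc_bank()
  w <- diff(b$boundaries)
  expect_equal(b$n_pairs, 46)
  expect_equal(sum(abs(w - 2.5) < 1e-9), 14)
  expect_equal(sum(abs(w - 5) < 1e-9), 32)
  expect_equal(range(b$boundaries), c(-97.5, 97.5))
})

test_that("an empty mask leaves the aperture identical to the open field", {
  fitted <- fit_blocking_aperture(raster50(), open50)
  expect_equal(fitted$x1, open50$x1)
  expect_equal(fitted$x2, open50$x2)
  expect_equal(fitted$jaw, open50$jaw)
})

test_that("a single right-half hotspot pixel advances only the right leaf", {
  r <- set_pixels(raster50(), 30.5, 10.5)   # pixel centred at (+30.5, +10.5)
  fitted <- fit_blocking_aperture(r, open50)
  k <- fifwbi:::pair_of_z(fitted$bank, 10.5)
  expect_lte(fitted$x2[k], 30.5 - 0.5)      # tip at or left of the inner pixel edge
  expect_equal(fitted$x1[k], open50$x1[k])  # left leaf untouched
  expect_equal(fitted$x2[-k], open50$x2[-k])
  # minimality: the advanced tip touches the hotspot edge nearest the centre line
  expect_equal(fitted$x2[k], 30.0)
})

test_that("a centre-crossing row is blocked from the longer side (d1/d2 rule)", {
  # hotspot spanning X_BEV in [-10, +25] at z in one 5 mm band:
  # d_left = 10, d_right = 25 -> the right leaf travels across to -10
  r <- raster50()
  for (x in seq(-9.5, 24.5, by = 1)) r <- set_pixels(r, x, 30.5)
  fitted <- fit_blocking_aperture(r, open50)
  k <- fifwbi:::pair_of_z(fitted$bank, 30.5)
  expect_equal(fitted$x2[k], -10)
  expect_equal(fitted$x1[k], open50$x1[k])
  # brute-force coverage of every hot pixel
  blk <- blocked_region(fitted, open50, r)
  expect_true(all(blk$values[r$values]))
  # mirrored case: longer side on the left -> left leaf advances to +10
  r2 <- raster50()
  for (x in seq(-24.5, 9.5, by = 1)) r2 <- set_pixels(r2, x, 30.5)
  f2 <- fit_blocking_aperture(r2, open50)
  expect_equal(f2$x1[k], 10)
  expect_equal(f2$x2[k], open50$x2[k])
})

test_that("a tie d1 == d2 goes to the configured side", {
  r <- raster50()
  for (x in seq(-14.5, 14.5, by = 1)) r <- set_pixels(r, x, 30.5)
  k <- fifwbi:::pair_of_z(default_mlc_bank(), 30.5)
  f_left <- fit_blocking_aperture(r, open50, tie = "left")
  expect_equal(f_left$x1[k], 15)
  expect_equal(f_left$x2[k], open50$x2[k])
  f_right <- fit_blocking_aperture(r, open50, tie = "right")
  expect_equal(f_right$x2[k], -15)
})

test_that("disjoint runs on opposite sides are covered by their own leaves", {
  r <- raster50()
  for (x in seq(-30.5, -20.5, by = 1)) r <- set_pixels(r, x, 5.5)
  for (x in seq(25.5, 35.5, by = 1)) r <- set_pixels(r, x, 5.5)
  fitted <- fit_blocking_aperture(r, open50)
  k <- fifwbi:::pair_of_z(fitted$bank, 5.5)
  expect_equal(fitted$x1[k], -20)   # left leaf to the inner edge of the left run
  expect_equal(fitted$x2[k], 25)    # right leaf to the inner edge of the right run
  blk <- blocked_region(fitted, open50, r)
  expect_true(all(blk$values[r$values]))
})

test_that("fitting is idempotent and never opens beyond the main field", {
  set.seed(21)
  for (rep in 1:20) {
    r <- random_hot_raster(raster50(), jaw50)
    f1 <- fit_blocking_aperture(r, open50)
    f2 <- fit_blocking_aperture(r, f1)  # refit with the same mask
    expect_equal(f1$x1, f2$x1)
    expect_equal(f1$x2, f2$x2)
    expect_true(all(f1$x1 >= open50$x1 - 1e-9))
    expect_true(all(f1$x2 <= open50$x2 + 1e-9))
    # coverage completeness: no hot pixel stays open
    expect_false(any(aperture_is_open(f1,
      fifwbi:::raster_x_centres(r)[which(r$values, arr.ind = TRUE)[, 1]],
      fifwbi:::raster_z_centres(r)[which(r$values, arr.ind = TRUE)[, 2]])))
  }
})

test_that("blocked_region is empty for identical apertures and exact for one leaf", {
  r <- raster50()
  expect_equal(sum(blocked_region(open50, open50, r)$values), 0)
  ap <- open50
  k <- fifwbi:::pair_of_z(ap$bank, 10.5)
  ap$x2[k] <- 12          # advance one right leaf
  blk <- blocked_region(ap, open50, r)
  hit <- which(blk$values, arr.ind = TRUE)
  xc <- fifwbi:::raster_x_centres(r)[hit[, 1]]
  zc <- fifwbi:::raster_z_centres(r)[hit[, 2]]
  band <- ap$bank$boundaries[c(k, k + 1)]
  # exactly the swept rectangle: x in [12, jaw), z in the pair's band
  expect_true(all(xc >= 12 & xc < 50 & zc >= band[1] & zc <= band[2]))
  g <- expand.grid(x = fifwbi:::raster_x_centres(r), z = fifwbi:::raster_z_centres(r))
  manual <- g$x > 12 & g$x < 50 & g$z > band[1] & g$z < band[2] &
            g$z > -50 & g$z < 50
  expect_equal(as.vector(blk$values), manual)
})

test_that("the isocenter stays unblocked when hotspots sit at the field edges", {
  # peripheral hotspots on both sides of the isocenter row, none crossing
  # the centre line: the leaves close onto the edges, the axis stays open
  r <- raster50()
  for (z in c(-40.5, -0.5, 0.5, 40.5)) {
    for (x in seq(-45.5, -30.5, by = 1)) r <- set_pixels(r, x, z)
    for (x in seq(35.5, 45.5, by = 1)) r <- set_pixels(r, x, z)
  }
  fitted <- fit_blocking_aperture(r, open50)
  expect_true(aperture_is_open(fitted, 0, 0.01))
  expect_true(aperture_is_open(fitted, 0, -0.01))
  blk <- blocked_region(fitted, open50, r)
  expect_true(all(blk$values[r$values]))
})
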