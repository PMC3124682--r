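test_that("cylinder-in-cube has the stated support", {
  ph <- make_cylinder_in_cube(16, height = 6, radius = 4, activity = 2)
  expect_identical(dim(ph), c(16L, 16L, 16L))
  nz <- apply(unclass(ph) > 0, 3, any)
  expect_identical(sum(nz), 6L)
  expect_true(all(diff(which(nz)) == 1))      # consecutive planes
  # support voxel count close to the analytic volume pi r^2 h
  count <- sum(ph > 0)
  vol <- pi * 4^2 * 6
  expect_lt(abs(count - vol) / vol, 2 * pi * 4 * 6 / vol)  # one voxel shell
  expect_true(all(unclass(ph) %in% c(0, 2)))
  expect_equal(sum(make_cylinder_in_cube(16, 6, 4, activity = 0)), 0)
  expect_error(make_cylinder_in_cube(16, height = -1), "height")
})

test_that("nested cubes take exactly three activity levels", {
  ph <- make_nested_cubes()
  expect_identical(dim(ph), c(13L, 13L, 9L))
  expect_identical(sort(unique(as.numeric(ph))), c(0, 1, 3))
  uni <- make_nested_cubes(a_outer = 2, a_inner = 2)
  expect_identical(sort(unique(as.numeric(uni))), c(0, 2))
  ii <- attr(ph, "inner_index")
  expect_true(all(ph[ii$x, ii$y, ii$z] == 3))
})

test_that("thyroid phantom is compact with parameterized nodules", {
  ph <- make_thyroid_2d(512)
  expect_identical(dim(ph), c(512L, 512L))
  expect_true(all(ph[1:10, ] == 0) && all(ph[, 1:10] == 0) &&
                all(ph[503:512, ] == 0) && all(ph[, 503:512] == 0))
  nod <- attr(ph, "nodules")
  expect_gte(nrow(nod), 2)
  expect_true(all(nod$r_px <= 512 / 20))
  for (k in seq_len(nrow(nod))) {
    v <- ph[round(nod$cx_px[k]), round(nod$cy_px[k])]
    expect_equal(v, nod$value[k])
  }
  lobe <- attr(ph, "lobe_activity")
  expect_equal(abs(nod$value - lobe), rep(0.8 * lobe, nrow(nod)))
})

test_that("Shepp-Logan matches an independent per-pixel rasterizer", {
  ph <- make_shepp_logan(64)
  expect_true(all(ph >= 0) && max(ph) <= 1 + 1e-12)
  # independent rasterizer: per-pixel loop over the standard ellipse table
  tab <- scatteremit:::.shepp_logan_table()
  ref <- matrix(0, 64, 64)
  for (i in 1:64) for (j in 1:64) {
    X <- (2 * i - 65) / 64; Y <- (2 * j - 65) / 64
    s <- 0
    for (k in seq_len(nrow(tab))) {
      phi <- tab$phi[k] * pi / 180
      xr <- (X - tab$x0[k]) * cos(phi) + (Y - tab$y0[k]) * sin(phi)
      yr <- -(X - tab$x0[k]) * sin(phi) + (Y - tab$y0[k]) * cos(phi)
      if ((xr / tab$a[k])^2 + (yr / tab$b[k])^2 <= 1) s <- s + tab$A[k]
    }
    ref[i, j] <- max(s, 0)
  }
  expect_equal(unclass(ph), ref, ignore_attr = TRUE)
  # symmetric about the vertical midline once the off-axis ellipses are wiped
  mask <- matrix(TRUE, 64, 64)
  for (k in c(8, 10)) {   # the two laterally offset small ellipses
    ii <- which(abs((2 * seq_len(64) - 65) / 64 - tab$x0[k]) < 3 * tab$a[k])
    mask[ii, ] <- FALSE; mask[65 - ii, ] <- FALSE
  }
  v <- unclass(ph)
  # symmetric up to boundary-pixel discretization of the ellipse indicators
  expect_lt(mean(abs(v[mask] - v[64:1, ][mask[64:1, ]])), 0.02 * mean(v))
})

test_that("Poisson emission noise is seeded and unbiased", {
  ph <- make_cylinder_in_cube(8, 4, 2, activity = 5e9)
  n1 <- add_poisson_noise(ph, dwell = 0.1, seed = 11)
  n2 <- add_poisson_noise(ph, dwell = 0.1, seed = 11)
  expect_identical(unclass(n1), unclass(n2))
  n3 <- add_poisson_noise(ph, dwell = 0.1, seed = 12)
  expect_false(identical(unclass(n1), unclass(n3)))
  # long dwell converges to the input
  nlong <- add_poisson_noise(ph, dwell = 1e5, seed = 1)
  expect_lt(rmse(nlong, ph), 0.5)
  # zero map stays zero
  z <- activity_map(array(0, c(4, 4)), pitch = 1)
  expect_equal(max(add_poisson_noise(z, 0.1, 1)), 0)
  # sample mean of one voxel within 3 sigma of its expectation
  vox_mean <- 5e9
  lam <- vox_mean * 0.1 / 60 * 0.001
  draws <- sapply(1:200, function(s)
    unclass(add_poisson_noise(ph, 0.1, seed = 1000 + s))[4, 4, 4])
  se <- sqrt(lam) / (0.1 / 60 * 0.001) / sqrt(200)
  expect_lt(abs(mean(draws) - vox_mean), 3 * se)
  expect_error(add_poisson_noise(ph, dwell = -1), "dwell")
})
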