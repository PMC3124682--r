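test_that("V-line projector equals the direct double Riemann sum", {
  set.seed(5)
  f <- activity_map(matrix(runif(64), 8, 8), pitch = 1)
  ang <- angle_grid_uniform(0.3, 1.2, 4)
  zeta <- seq(-3.5, 11.5, by = 1)
  p <- fix_params()
  got <- forward_cvlrt(f, ang, zeta = zeta, params = p)$values
  ref <- fix_cvlrt_direct(f, ang, zeta, p)
  expect_lt(max(abs(got - ref)) / max(ref), 1e-10)
})

test_that("V-line projector is linear, nonnegative and translation-equivariant", {
  set.seed(8)
  ang <- angle_grid_uniform(0.2, 1.3, 6)
  f1 <- activity_map(matrix(runif(16 * 16), 16, 16), pitch = 1)
  f2 <- activity_map(matrix(runif(16 * 16), 16, 16), pitch = 1)
  s0 <- forward_cvlrt(activity_map(matrix(0, 16, 16)), ang)
  expect_equal(max(abs(s0$values)), 0)
  s1 <- forward_cvlrt(f1, ang); s2 <- forward_cvlrt(f2, ang)
  s12 <- forward_cvlrt(activity_map(unclass(f1) + unclass(f2)), ang)
  expect_equal(s12$values, s1$values + s2$values, tolerance = 1e-12)
  expect_true(all(s1$values >= 0))
  # integer-pixel shift of f along the detector shifts the sinogram in zeta
  fv <- matrix(0, 24, 12); fv[8:12, 4:8] <- 1
  fs <- fv * 0; fs[11:15, 4:8] <- 1
  zeta <- seq(-9.5, 33.5, by = 1)
  a <- forward_cvlrt(activity_map(fv), ang, zeta = zeta)$values
  b <- forward_cvlrt(activity_map(fs), ang, zeta = zeta)$values
  interior <- 10:35
  expect_equal(b[interior, ], a[interior - 3, ], tolerance = 1e-12)
  # support touching the detector line is rejected
  expect_error(forward_cvlrt(activity_map(fv, origin = c(0.5, -1)), ang),
               "above the detector")
})

test_that("the eta smear matches its closed-form single-row profile", {
  n <- 32
  fv <- matrix(0, n, n); fv[, 20] <- 1    # a single row at y0 = 19.5
  h <- smear_eta(activity_map(fv, pitch = 1))
  y <- (seq_len(n) - 0.5)
  below <- 3:16
  expect_equal(unclass(h)[5, below], 1 / (19.5 - y[below]),
               tolerance = 0.02)
  expect_true(all(unclass(h)[, 21:n] == 0))  # nothing above the source row
  expect_equal(max(abs(unclass(smear_eta(activity_map(matrix(0, 8, 8)))))), 0)
  # linearity on random pairs
  set.seed(2)
  a <- matrix(runif(64), 8, 8); b <- matrix(runif(64), 8, 8)
  expect_equal(unclass(smear_eta(activity_map(a + b))),
               unclass(smear_eta(activity_map(a))) +
                 unclass(smear_eta(activity_map(b))),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("matched deconvolution inverts the smear; analytic symbol is safe", {
  f <- fix_blob2d(64)
  h <- smear_eta(f)
  fr <- deconvolve_eta(h, lambda = 0)
  expect_lt(rmse(attr(fr, "raw"), unclass(f)), 1e-9)
  frt <- deconvolve_eta(h)                    # default Tikhonov weight
  expect_lt(rmse(attr(frt, "raw"), unclass(f)), 0.1)
  expect_equal(max(abs(attr(deconvolve_eta(smear_eta(
    activity_map(matrix(0, 16, 16))), lambda = 0), "raw"))), 0)
  # finite-part symbol magnitude never vanishes off DC
  k <- seq(-0.5, 0.5, by = 1 / 128); k <- k[k != 0]
  expect_true(all(Mod(eta_fourier_symbol(k)) >= pi / 2 - 1e-12))
})

test_that("the VLRT back-projection recovers a smooth field", {
  n <- 128
  x <- seq_len(n)
  hb <- outer(exp(-((x - 64)^2) / 120), exp(-((x - 45)^2) / 90))
  W <- 2 * n
  hw <- matrix(0, W, n); hw[(n / 2 + 1):(3 * n / 2), ] <- hb
  zeta <- seq(0.5, W - 0.5, by = 1)
  ang <- angle_grid_vline(0.005)
  dat <- scatteremit:::.vlrt_forward(hw, 0.5, 1, 0.5, 1, zeta, ang$omegas,
                                     periodic = TRUE)
  sino <- v_sinogram(dat, zeta, ang, pitch = 1, y_origin = 0.5, ny = n)
  attr(sino, "periodic") <- TRUE
  attr(sino, "x_support") <- c(n / 2, 3 * n / 2)
  hrec <- invert_vlrt(sino)
  expect_lt(rmse(hrec[(n / 2 + 1):(3 * n / 2), ], hb), 5)
  # zero sinogram maps to zero
  sino0 <- sino; sino0$values <- sino$values * 0
  expect_equal(max(abs(invert_vlrt(sino0))), 0)
  expect_error(invert_vlrt(v_sinogram(dat[, 1, drop = FALSE], zeta,
                                      scatter_angle_grid(ang$omegas[1], 140),
                                      pitch = 1, y_origin = 0.5, ny = n)),
               "two scattering angles")
})

test_that("reconstruction error decreases monotonically as domega is halved", {
  f <- fix_blob2d(64, cy = 26)
  errs <- sapply(c(0.02, 0.01, 0.005), function(dw) {
    sino <- fix_vline_sino(f, domega = dw)
    rmse(fix_crop(invert_cvlrt(sino), sino, 64), unclass(f))
  })
  expect_true(all(diff(errs) < 0))
})

test_that("analytic two-step inversion and FBP agree on a smooth blob", {
  f <- fix_blob2d(96, cy = 40)
  sino <- fix_vline_sino(f)
  ra <- fix_crop(invert_cvlrt(sino), sino, 96)
  rf <- fix_crop(fbp_cvlrt(sino), sino, 96)
  expect_lt(rmse(ra, unclass(f)), 6)
  expect_lt(100 * sqrt(sum((ra - rf)^2) / sum(ra^2)), 10)
  # scaling: invert(c * sinogram) = c * invert(sinogram)
  s2 <- sino; s2$values <- 2.5 * sino$values
  expect_equal(unclass(invert_cvlrt(s2)), 2.5 * unclass(invert_cvlrt(sino)),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("FBP localizes the large Shepp-Logan structures", {
  ph <- make_shepp_logan(128)
  sino <- fix_vline_sino(ph)
  rec <- fix_crop(fbp_cvlrt(sino), sino, 128)
  tv <- unclass(ph)
  # bright skull ring: peak positions along the two mid-lines within 2 px
  for (prof in list(list(t = tv[65, ], r = rec[65, ]),
                    list(t = tv[, 65], r = rec[, 65]))) {
    for (side in list(1:30, 99:128)) {
      expect_lte(abs(which.max(prof$t[side]) - which.max(prof$r[side])), 2)
    }
  }
  # dark ventricles: local minima near their true centres
  tab <- scatteremit:::.shepp_logan_table()
  for (k in 3:4) {
    cx <- round((tab$x0[k] + 1) * 64 + 0.5)
    cy <- round((tab$y0[k] + 1) * 64 + 0.5)
    xs <- cx + (-8:8); ys <- cy + (-8:8)
    ct <- which(tv[xs, ys] == min(tv[xs, ys]), arr.ind = TRUE)[1, ]
    cr <- which(rec[xs, ys] == min(rec[xs, ys]), arr.ind = TRUE)[1, ]
    expect_lt(sqrt(sum((ct - cr)^2)), 6)
  }
})

test_that("Euler's constant emerges from the regularized 1/eta integral", {
  expect_lt(abs(euler_gamma_from_eta_integral() - 0.57721566), 5e-7)
  expect_lt(abs(euler_gamma_from_eta_integral(k = 1) - 0.57721566), 5e-7)
})
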