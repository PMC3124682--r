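fix_open_det <- function(npix = 6, pitch = 20)
  detector_geometry(c(npix, npix), pitch, standoff = 10, medium_depth = 120,
                    collimated = FALSE)

test_that("open-geometry projector equals the event-level triple loop", {
  set.seed(3)
  ph <- activity_map(array(runif(6^3), c(6, 6, 6)), pitch = c(20, 20, 20))
  det <- fix_open_det()
  p <- fix_params(E0 = 140.1, ne = 3.34e23, mu = 0.002)
  ang <- angle_grid_uniform(20 * pi / 180, 160 * pi / 180, 6)
  a <- forward_gccrt(ph, det, ang, p)
  b <- scatteremit:::.gccrt_triple_loop(ph, det, ang, p)
  expect_lt(sqrt(sum((a$values - b$values)^2) / sum(b$values^2)), 1e-8)
  # zero activity, linearity, nonnegativity
  z <- forward_gccrt(activity_map(array(0, c(6, 6, 6)), pitch = c(20, 20, 20)),
                     det, ang, p)
  expect_equal(max(abs(z$values)), 0)
  ph2 <- activity_map(2 * unclass(ph), pitch = c(20, 20, 20))
  expect_equal(forward_gccrt(ph2, det, ang, p)$values, 2 * a$values,
               tolerance = 1e-12)
  expect_true(all(a$values >= 0))
})

test_that("removing the collimator only adds scattering vertices", {
  ph <- make_nested_cubes()
  pitch <- map_pitch(ph)
  det <- detector_geometry(c(13, 13), pitch[1], standoff = 10,
                           medium_depth = 150, collimated = FALSE)
  ang <- scatter_angle_grid(30 * pi / 180, 140.1,
                            edges = 30 * pi / 180 + c(-0.1, 0.1))
  p <- fix_params(E0 = 140.1, ne = 3.34e23)
  open_data <- forward_gccrt(ph, det, ang, p)$values[, , 1]
  # collimated version: same event weights, vertices restricted to the
  # vertical axis through each pixel (pixel grid aligned with voxel columns)
  geo <- scatteremit:::.gccrt_geometry(dim(ph), pitch, det)
  K <- kinematic_factor(ang$omegas, p)
  edges <- ang$edges
  fv <- as.numeric(ph)
  coll <- matrix(0, 13, 13)
  for (d in seq_len(nrow(geo$pix))) {
    vsel <- which(abs(geo$ver[, 1] - geo$pix[d, 1]) < 1e-9 &
                    abs(geo$ver[, 2] - geo$pix[d, 2]) < 1e-9)
    acc <- 0
    for (nn in vsel) {
      u <- cbind(geo$ver[nn, 1] - geo$src[, 1], geo$ver[nn, 2] - geo$src[, 2],
                 geo$ver[nn, 3] - geo$src[, 3])
      sn2 <- rowSums(u^2)
      v <- c(geo$pix[d, 1] - geo$ver[nn, 1], geo$pix[d, 2] - geo$ver[nn, 2],
             -geo$ver[nn, 3])
      nd2 <- sum(v^2)
      cth <- (u %*% v) / (sqrt(sn2) * sqrt(nd2))
      th <- acos(pmin(1, pmax(-1, cth)))
      ok <- which(th > edges[1] & th <= edges[2] & sn2 > 0 & fv > 0)
      if (length(ok))
        acc <- acc + sum(fv[ok] * geo$volS * geo$volN /
                           (4 * pi * sn2[ok]^1.5) * K / (diff(edges) * nd2))
    }
    coll[(d - 1) %% 13 + 1, (d - 1) %/% 13 + 1] <- acc
  }
  expect_true(all(open_data - coll >= -1e-12 * max(open_data)))
  expect_gt(sum(open_data), 2 * sum(coll))   # strictly more signal overall
})

test_that("open-geometry PSF vertices lie on the inscribed-angle torus", {
  det <- fix_open_det(13, 300 / 13)
  p <- fix_params(E0 = 140.1, ne = 3.34e23)
  src <- c(30, -20, 100)
  img <- psf_gccrt(src, det, 40 * pi / 180, p, domega = 0.06)
  vtx <- attr(img, "vertices")
  expect_gt(nrow(vtx), 0)
  ctr_pix <- c(0, 0, 0)
  for (i in seq_len(nrow(vtx))) {
    a <- src - vtx[i, ]                  # N -> S
    b <- ctr_pix - vtx[i, ]              # N -> D
    ang_snd <- acos(sum(a * b) / sqrt(sum(a^2) * sum(b^2)))
    expect_lt(abs(ang_snd - (pi - 40 * pi / 180)), 0.06 / 2 + 1e-9)
  }
  # shape differs from the collimated geometry: the collimated PSF has an
  # exact hole on the source axis, the open PSF does not
  det49 <- detector_geometry(c(49, 49), 6, standoff = 10, medium_depth = 150,
                             collimated = FALSE)
  img2 <- psf_gccrt(c(0, 0, 100), det49, 50 * pi / 180, p, domega = 0.1)
  expect_gt(img2[25, 25], 0.05 * max(img2))
  detc <- detector_geometry(c(49, 49), 6, standoff = 10, medium_depth = 150)
  imgc <- psf_ccrt(c(0, 0, 170), detc, 50 * pi / 180, p)
  expect_lt(imgc[25, 25], 1e-8 * max(imgc))
})

test_that("the weight matrix reproduces the projector", {
  det <- fix_open_det()
  p <- fix_params(E0 = 140.1, ne = 3.34e23)
  ang <- angle_grid_uniform(20 * pi / 180, 160 * pi / 180, 8)
  W <- build_weight_matrix(c(6, 6, 6), det, ang, p, pitch = c(20, 20, 20))
  expect_true(all(W >= 0))
  set.seed(9)
  fv <- array(runif(216), c(6, 6, 6))
  ph <- activity_map(fv, pitch = c(20, 20, 20))
  direct <- forward_gccrt(ph, det, ang, p)$values
  viaW <- as.numeric(W %*% as.numeric(fv))
  expect_lt(sqrt(sum((viaW - as.numeric(direct))^2) / sum(direct^2)), 1e-10)
  # one column equals the projection of the corresponding unit voxel
  j <- 87
  e <- array(0, c(6, 6, 6)); e[j] <- 1
  expect_equal(as.numeric(W[, j]),
               as.numeric(forward_gccrt(activity_map(e, pitch = c(20, 20, 20)),
                                        det, ang, p)$values),
               tolerance = 1e-12)
  # adjoint identity of the stored linear map
  set.seed(10)
  x <- runif(ncol(W)); y <- runif(nrow(W))
  expect_lt(abs(sum((W %*% x) * y) - sum(x * crossprod(W, y))) /
              abs(sum(x * crossprod(W, y))), 1e-12)
  expect_error(build_weight_matrix(c(100, 100, 100), det,
                                   angle_grid_uniform(0.3, 2.8, 200), p),
               "memory guard")
})

test_that("projected conjugate gradients recovers exact data", {
  det <- fix_open_det()
  p <- fix_params(E0 = 140.1, ne = 3.34e23)
  ang <- angle_grid_uniform(20 * pi / 180, 160 * pi / 180, 16)
  W <- build_weight_matrix(c(6, 6, 6), det, ang, p, pitch = c(20, 20, 20))
  set.seed(11)
  ftrue <- array(runif(216), c(6, 6, 6))
  g <- as.numeric(W %*% as.numeric(ftrue))
  frec <- cg_positive(W, g, max_iter = 500)
  expect_lt(rmse(frec, ftrue), 1)
  expect_true(all(unclass(frec) >= 0))
  # misfit non-increasing over accepted iterates
  expect_true(all(diff(attr(frec, "history")) <= 1e-9 * attr(frec, "history")[1]))
  # zero data returns the zero map
  f0 <- cg_positive(W, numeric(nrow(W)))
  expect_equal(max(abs(f0)), 0)
})
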