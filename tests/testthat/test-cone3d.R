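# common small collimated scene: rings bounded away from 90 degrees so the
# periodic ring kernels and the finite-detector event sums coincide exactly
fix_cone_angles <- function() {
  om <- c(seq(20, 55, length.out = 4), seq(125, 160, length.out = 4)) * pi / 180
  g <- scatter_angle_grid(om, 140)
  g$guard <- 30 * pi / 180
  g
}

test_that("ring-kernel projector equals the brute-force event sum", {
  set.seed(7)
  ph <- activity_map(array(runif(8^3), c(8, 8, 8)), pitch = 1)
  det <- detector_geometry(c(48, 48), 1, standoff = 50, medium_depth = 8)
  p <- fix_params(mu = 0.005)
  ang <- fix_cone_angles()
  s1 <- forward_ccrt(ph, det, ang, p, method = "binned")
  s2 <- brute_force_single_scatter(ph, det, ang, p)
  expect_lt(sqrt(sum((s1$values - s2$values)^2) / sum(s2$values^2)), 1e-8)
  expect_error(brute_force_single_scatter(
    activity_map(array(1, c(33, 4, 4))), det, ang, p), "32")
})

test_that("cone projectors are linear and scale with electron density", {
  det <- detector_geometry(c(32, 32), 1, standoff = 50, medium_depth = 8)
  ang <- fix_cone_angles()
  p <- fix_params()
  z <- forward_ccrt(activity_map(array(0, c(8, 8, 8))), det, ang, p)
  expect_equal(max(abs(z$values)), 0)
  set.seed(1)
  a <- array(runif(512), c(8, 8, 8)); b <- array(runif(512), c(8, 8, 8))
  for (meth in c("binned", "spectral")) {
    sa <- forward_ccrt(activity_map(a), det, ang, p, method = meth)
    sb <- forward_ccrt(activity_map(b), det, ang, p, method = meth)
    sab <- forward_ccrt(activity_map(a + b), det, ang, p, method = meth)
    expect_equal(sab$values, sa$values + sb$values, tolerance = 1e-10)
    # the event-level discretization is exactly nonnegative; the band-exact
    # evaluation may ring slightly negative at sharp ring edges
    neg_tol <- if (meth == "binned") 1e-12 else 5e-3
    expect_true(min(sa$values) > -neg_tol * max(sa$values))
    # doubling n_e doubles the data
    s2 <- forward_ccrt(activity_map(a), det, ang, fix_params(ne = 7e23),
                       method = meth)
    expect_equal(s2$values, 2 * sa$values, tolerance = 1e-12)
  }
})

test_that("single-event contribution matches the closed-form product", {
  # one source voxel, narrow bin: one (S, N) pair at exactly 45 degrees
  fv <- array(0, c(4, 4, 4)); fv[2, 2, 3] <- 1
  ph <- activity_map(fv, pitch = 1)
  det <- detector_geometry(c(16, 16), 1, standoff = 10, medium_depth = 4)
  p <- fix_params()
  ang <- scatter_angle_grid(pi / 4, 140, edges = pi / 4 + c(-0.02, 0.02))
  s <- brute_force_single_scatter(ph, det, ang, p)
  # hand-composed event sum: source at z = 12.5, vertices on 10..14, events
  # are the lattice offsets whose exact scattering angle falls in the bin;
  # each contributes the closed-form product of the two inverse-square legs,
  # the cone-measure factor and the kinematic weight
  edges <- ang$edges
  K <- kinematic_factor(ang$omegas, p)
  tot <- 0
  for (zv in 10:14) for (dx in -8:8) for (dy in -8:8) {
    rho2 <- dx^2 + dy^2
    sgn <- 12.5 - zv
    if (rho2 == 0) next
    th <- if (sgn > 0) atan2(sqrt(rho2), sgn) else pi - atan2(sqrt(rho2), -sgn)
    if (th <= edges[1] || th > edges[2]) next
    SN <- sqrt(rho2 + sgn^2)
    tot <- tot + 1 / (4 * pi * SN^3) / diff(edges) * K / zv^2
  }
  expect_equal(sum(s$values), tot, tolerance = 1e-10)
})

test_that("collimated PSF is a growing off-centre ring with consistent mass", {
  det <- detector_geometry(c(48, 48), 1, standoff = 40, medium_depth = 10)
  p <- fix_params()
  psf <- psf_ccrt(c(0, 0, 55), det, 50 * pi / 180, p)
  # rotational symmetry: quarter-turn invariance on the square grid
  expect_lt(max(abs(psf - t(psf))), 1e-12 * max(psf))
  expect_lt(max(abs(psf - psf[48:1, 48:1])), 1e-12 * max(psf))
  # central dip: the maximum sits off-centre for omega < pi/2
  ctr <- psf[24:25, 24:25]
  expect_lt(max(ctr), max(psf))
  # ring-of-maximum radius grows with source height
  radius_of_max <- function(z) {
    img <- psf_ccrt(c(0, 0, z), det, 50 * pi / 180, p)
    xs <- (seq_len(48) - 24.5)
    R <- sqrt(outer(xs^2, xs^2, `+`))
    R[which.max(img)]
  }
  rr <- sapply(c(53, 56, 59), radius_of_max)
  expect_true(all(diff(rr) > 0))
  # the PSF is the projector's response to a point source: its total mass
  # matches the single-scatter projection of a one-voxel activity map
  # (band-exact ring evaluation; the event-level lattice cannot represent
  # the sub-pixel rings of the nearest vertices and is compared elsewhere)
  det2 <- detector_geometry(c(48, 48), 1, standoff = 10, medium_depth = 4)
  fv <- array(0, c(1, 1, 4)); fv[1, 1, 4] <- 1
  angs <- angle_grid_uniform(10 * pi / 180, 80 * pi / 180, 14)
  sp <- forward_ccrt(activity_map(fv, pitch = 1), det2, angs, p,
                     method = "spectral")
  for (k in c(4, 8, 12)) {
    tot_fw <- sum(sp$values[, , k])
    tot_psf <- sum(psf_ccrt(c(0, 0, 13.5), det2, angs$omegas[k], p))
    expect_lt(abs(tot_psf - tot_fw) / tot_fw, 0.05)
  }
  expect_error(psf_ccrt(c(0, 0, -1), det, 0.5), "above")
})

test_that("analytic inversion recovers a blob centre within one voxel", {
  set.seed(21)
  n <- 12
  cx <- c(5.2, 7.1, 6.4)
  g <- array(0, c(n, n, n))
  for (i in 1:n) for (j in 1:n) for (k in 1:n)
    g[i, j, k] <- exp(-sum((c(i, j, k) - cx)^2) / 6)
  ph <- activity_map(g, pitch = 1)
  det <- detector_geometry(c(36, 36), 1, standoff = 150, medium_depth = n)
  ang <- angle_grid_exp_t(5, 175, n_per_branch = 80)
  p <- fix_params()
  sino <- forward_ccrt(ph, det, ang, p, method = "spectral", z_oversample = 4L)
  rec <- invert_ccrt(sino, p)
  com <- function(v) {
    w <- pmax(as.numeric(v), 0)
    idx <- which(array(TRUE, dim(v)), arr.ind = TRUE)
    colSums(idx * w) / sum(w)
  }
  expect_lt(max(abs(com(unclass(rec)) - com(g))), 1)
  # zero data gives a zero volume
  s0 <- sino; s0$values <- sino$values * 0
  expect_equal(max(abs(invert_ccrt(s0, p))), 0)
})

test_that("a single-hemisphere grid degrades with a warning", {
  ph <- make_cylinder_in_cube(8, 4, 2, activity = 1)
  det <- detector_geometry(c(24, 24), 1, standoff = 100, medium_depth = 8)
  ang <- angle_grid_uniform(0.2, 1.2, 24)
  p <- fix_params()
  sino <- forward_ccrt(ph, det, ang, p, method = "spectral")
  expect_warning(invert_ccrt(sino, p), "hemisphere")
})

test_that("energy binning conserves counts and maps bins to angles", {
  p <- fix_params()
  # raw data on a fine uniform energy grid
  Emin <- p$E0_keV / (1 + 2 * p$epsilon)
  ee <- seq(Emin + 2, p$E0_keV - 2, length.out = 41)
  set.seed(3)
  v <- array(runif(4 * 4 * 40), c(4, 4, 40))
  det <- detector_geometry(c(4, 4), 1, 10, 5)
  sbe <- list(values = v, energy_edges = ee, detector = det)
  s <- energy_binning(sbe, p, dE_keV = 2)
  expect_equal(sum(s$values), sum(v), tolerance = 1e-12)
  # bin centres map back to energies within dE/2
  expect_true(all(abs(scattered_energy(p$E0_keV, s$angles$omegas) -
                        rev(sort(s$angles$energies))) < 1 + 1e-9))
  # two bins when dE is half the band
  band <- (p$E0_keV - 2) - (Emin + 2)
  s2 <- energy_binning(sbe, p, dE_keV = band / 2)
  expect_identical(dim(s2$values)[3], 2L)
  expect_error(energy_binning(sbe, p, dE_keV = 500), "band")
})

test_that("refining the tangent grid improves the cylinder reconstruction", {
  ph <- make_cylinder_in_cube(16, height = 6, radius = 4, activity = 4.84e10)
  det <- detector_geometry(c(48, 48), 1, standoff = 200, medium_depth = 16)
  p <- fix_params(ne = 3.5e23)
  run <- function(ang) {
    s <- forward_ccrt(ph, det, ang, p, method = "spectral", z_oversample = 8L)
    rmse(invert_ccrt(s, p, z_model_oversample = 4L), ph)
  }
  errs <- sapply(c(40, 80, 160), function(npb)
    run(angle_grid_exp_t(5, 175, n_per_branch = npb)))
  expect_true(all(diff(errs) < 0))
  # exponential tangent sampling beats a uniform grid of equal size
  omu <- sort(c(angle_grid_uniform(5 * pi / 180, 89 * pi / 180, 160)$omegas,
                angle_grid_uniform(91 * pi / 180, 175 * pi / 180, 160)$omegas))
  err_u <- run(scatter_angle_grid(omu, 140))
  expect_lt(errs[3], err_u)
})

test_that("doubling the standoff scales the PSF by the exit-leg inverse square", {
  p <- fix_params()
  tot <- sapply(c(200, 400), function(l) {
    det <- detector_geometry(c(64, 64), 1, standoff = l, medium_depth = 8)
    sum(psf_ccrt(c(0, 0, l + 12), det, 50 * pi / 180, p))
  })
  # dominant vertices sit within the 8 mm medium just above the standoff
  expect_lt(abs(tot[2] / tot[1] - (204 / 404)^2) / (204 / 404)^2, 0.1)
})
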