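test_that("Compton energy-angle relations form consistent bijections", {
  p <- fix_params()
  expect_equal(scattered_energy(140, 0), 140)
  eps <- 140 / 510.999
  expect_equal(scattered_energy(140, pi), 140 / (1 + 2 * eps))
  # direct arithmetic at a right angle
  expect_equal(scattered_energy(140, pi / 2), 140 / (1 + eps), tolerance = 1e-12)
  # strictly decreasing in omega
  om <- seq(0, pi, length.out = 400)
  expect_true(all(diff(scattered_energy(140, om)) < 0))
  # energy <-> angle round trip over a dense energy grid
  Emin <- 140 / (1 + 2 * eps)
  E <- seq(Emin, 140, length.out = 300)
  expect_equal(scattered_energy(140, angle_from_energy(140, E)), E,
               tolerance = 1e-9)
  expect_equal(angle_from_energy(140, 140), 0)
  expect_equal(angle_from_energy(140, Emin), pi)
  expect_error(angle_from_energy(140, Emin - 1), "band")
  expect_error(scattered_energy(140, -0.1), "domain")
})

test_that("wavelength and energy forms agree through E = hc/lambda", {
  lam0 <- scatter_constants$hc_keV_cm / 140
  expect_equal(scattered_wavelength(lam0, 0), lam0)
  expect_equal(scattered_wavelength(lam0, pi),
               lam0 + 2 * scatter_constants$compton_wavelength_cm)
  set.seed(42)
  om <- runif(100, 0, pi)
  E_from_lambda <- scatter_constants$hc_keV_cm /
    scattered_wavelength(lam0, om)
  expect_equal(E_from_lambda, scattered_energy(140, om), tolerance = 1e-6)
})

test_that("Klein-Nishina weight has the Thomson limit and forward bias", {
  p <- fix_params()
  om <- seq(1e-3, pi, length.out = 1000)
  expect_true(all(klein_nishina(om, p) > 0))
  # epsilon -> 0: the textbook recoil term vanishes and the Thomson shape
  # 1 + cos^2 remains; the printed form becomes isotropic. Both symmetric
  # about pi/2 in that limit.
  p0 <- physics_params(1e-6, 3.5e23)
  kt <- klein_nishina(om, p0, variant = "textbook")
  shape <- 1 + cos(om)^2
  expect_equal(kt / kt[1], shape / shape[1], tolerance = 1e-4)
  i <- 100
  for (v in c("printed", "textbook"))
    expect_equal(klein_nishina(om[i], p0, variant = v),
                 klein_nishina(pi - om[i], p0, variant = v),
                 tolerance = 1e-4)
  # with epsilon > 0 the forward hemisphere carries more weight
  expect_gt(klein_nishina(pi / 4, p), klein_nishina(3 * pi / 4, p))
  # transcription check at 90 degrees: term-by-term evaluation
  eps <- p$epsilon
  d <- 1 + eps
  byhand <- pi * p$re_cm^2 / (2 * pi) / d^2 * (1 + 0 + 1 / d)
  expect_equal(klein_nishina(pi / 2, p), byhand, tolerance = 1e-14)
  # the two variants are genuinely different expressions at finite epsilon
  expect_gt(abs(klein_nishina(pi / 3, p) /
                  klein_nishina(pi / 3, p, variant = "textbook") - 1), 0.1)
})

test_that("kinematic factor is the electron-density-scaled angular weight", {
  p <- fix_params()
  om <- seq(0.2, 2.9, length.out = 25)
  ratio <- kinematic_factor(om, p) / klein_nishina(om, p)
  expect_equal(ratio, rep(ratio[1], 25))
  p2 <- fix_params(ne = 7e23)
  expect_equal(kinematic_factor(om, p2), 2 * kinematic_factor(om, p))
  # hand-composed product at 30 degrees
  expect_equal(kinematic_factor(pi / 6, p),
               pi * p$re_cm^2 * p$ne_per_cm3 * klein_nishina(pi / 6, p))
})

test_that("physics parameter container validates its invariants", {
  p <- physics_params(140)
  expect_equal(p$epsilon, 140 / 510.999, tolerance = 1e-6)
  expect_error(physics_params(-1), "E0")
  expect_error(physics_params(140, ne_per_cm3 = -2))
})
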