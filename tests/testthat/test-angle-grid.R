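test_that("angle grids are ordered with monotone energies", {
  g <- angle_grid_uniform(0.1, 1.4, 20)
  expect_true(!is.unsorted(g$omegas, strictly = TRUE))
  expect_true(all(diff(g$energies) < 0))
  expect_equal(length(g$ts), length(g$omegas))
  expect_error(scatter_angle_grid(c(0.5, pi / 2, 2)), "pi/2")
  expect_error(scatter_angle_grid(c(1, 0.5)), "increasing")
})

test_that("the reference angular step yields 314 V-line projections", {
  expect_identical(length(angle_grid_vline(0.005)), 314L)
  expect_true(all(angle_grid_vline(0.005)$omegas < pi / 2))
})

test_that("exponential tangent grids are geometric per branch with a guard", {
  g <- angle_grid_exp_t(5, 175, n_per_branch = 40, guard_deg = 1)
  expect_identical(length(g), 80L)
  tf <- g$ts[g$omegas < pi / 2]
  expect_equal(diff(log(tf)), rep(diff(log(tf))[1], length(tf) - 1),
               tolerance = 1e-9)
  expect_true(all(abs(g$omegas - pi / 2) >= (1 - 1e-9) * pi / 180))
  expect_gt(g$guard, 0)
})

test_that("energy-derived grids sample densely near 90 degrees", {
  p <- fix_params()
  g <- angle_grid_from_energy(p, dE_keV = 0.5)
  expect_true(!is.unsorted(g$omegas, strictly = TRUE))
  dom <- diff(g$omegas)
  mid <- which.min(abs(g$omegas[-1] - pi / 2))
  expect_lt(dom[mid], dom[1])       # finer near 90 deg than at the ends
  expect_lt(dom[mid], dom[length(dom)])
  expect_error(angle_grid_from_energy(p, dE_keV = 1000), "band")
})
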