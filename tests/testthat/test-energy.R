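p0 <- model_params()

test_that("membrane bending of any closed vesicle costs 8*pi*kappa_memb", {
  for (R in c(20, 55, 92, 300)) {
    e <- memb_bend_energy(4 * pi * R^2, R, p0)
    expect_equal(e, 8 * pi * 15)
  }
  # hemisphere h = R: closed form 4*pi*kappa*h/R
  expect_equal(memb_bend_energy(2 * pi * 70^2, 70, p0), 4 * pi * 15)
  # near-flat limit at fixed A
  expect_lt(memb_bend_energy(1000, 1e8, p0), 1e-8)
})

test_that("membrane bending depends only on the aspect ratio h/R", {
  caps <- random_caps(100, seed = 7)
  hr <- caps$h / caps$R
  e <- memb_bend_energy(2 * pi * caps$R * caps$h, caps$R, p0)
  expect_equal(e, 4 * pi * p0$kappa_memb * hr, tolerance = 1e-12)
  # two caps sharing h/R at very different sizes
  e1 <- memb_bend_energy(cap_area(30, 12), 30, p0)
  e2 <- memb_bend_energy(cap_area(300, 120), 300, p0)
  expect_equal(e1, e2)
})

test_that("tension energy equals gamma*pi*h^2", {
  expect_equal(memb_tension_energy(4 * pi * 55^2, 55, p0), 0.01 * 4 * pi * 55^2)
  expect_equal(memb_tension_energy(cap_area(100, 10), 100, p0), 0.01 * pi * 100)
  caps <- random_caps(100, seed = 8)
  expect_equal(memb_tension_energy(2 * pi * caps$R * caps$h, caps$R, p0),
               p0$gamma * pi * caps$h^2, tolerance = 1e-12)
})

test_that("clathrin bending vanishes only at the intrinsic radius", {
  expect_equal(clath_bend_energy(1000, 40, p0), 0)
  expect_equal(clath_bend_energy(1000, 20, p0), 1000 * 186.5 * 0.0025)
  # flat-lattice energy density: kappa_clath/2 * (2/R_clath)^2
  expect_equal(clath_bend_energy(1, 1e9, p0), 0.46625, tolerance = 1e-4)
  # strictly increasing in |2/R - 2/R_clath|
  devs <- abs(2 / c(20, 25, 30, 39, 41, 60, 120, 1e5) - 2 / 40)
  es <- clath_bend_energy(1000, c(20, 25, 30, 39, 41, 60, 120, 1e5), p0)
  expect_true(all(diff(es[order(devs)]) > 0))
})

test_that("polymerization energy counts arm-arm interactions", {
  expect_equal(clath_poly_energy(218, p0), -30)
  expect_equal(clath_poly_energy(0, p0), 0)
  expect_equal(clath_poly_energy(218, p0, n_open_arms = 1), 0)
  expect_equal(clath_poly_energy(2180, p0, n_open_arms = 3), -30 * 7)
  expect_error(clath_poly_energy(-1, p0))
})

test_that("total energy is the exact sum of its four terms", {
  eb <- total_energy(218, 40, p0)
  expect_equal(eb$E_clath_bend, 0)
  expect_equal(eb$E_total,
               eb$E_memb_bend + eb$E_memb_tension + eb$E_clath_bend +
                 eb$E_clath_poly)
  caps <- random_caps(1e4, seed = 9)
  A <- 2 * pi * caps$R * caps$h
  eb <- total_energy(A, caps$R, p0)
  expect_identical(eb$E_total,
                   eb$E_memb_bend + eb$E_memb_tension + eb$E_clath_bend +
                     eb$E_clath_poly)
  expect_identical(eb$E_memb_bend, memb_bend_energy(A, caps$R, p0))
  expect_identical(eb$E_clath_poly, clath_poly_energy(A, p0))
  expect_error(total_energy(4 * pi * 100 + 1, 1, p0), "invalid cap")
})

test_that("flat lattices are dominated by stored clathrin bending energy", {
  eb <- total_energy(1e4, 1e4, p0)
  expect_gt(eb$E_clath_bend, 4500)
  expect_equal(eb$E_clath_poly, -30 * 1e4 / 218)
  expect_gt(eb$E_clath_bend, abs(eb$E_clath_poly))
  expect_lt(eb$E_memb_bend + eb$E_memb_tension, 1)
})

test_that("per-arm bending cost rises from zero at R_clath to its flat limit", {
  expect_equal(per_arm_bend_energy(40, p0), 0)
  expect_equal(per_arm_bend_energy(Inf, p0), 218 * 186.5 * 0.05^2)
  expect_equal(per_arm_bend_energy(92, p0), 32.47, tolerance = 1e-3)
  expect_equal(estimate_a_from_Rmean(92, p0), per_arm_bend_energy(92, p0))
  expect_equal(estimate_a_from_Rmean(60, p0), 11.29, tolerance = 1e-3)
  expect_equal(estimate_a_from_Rmean(40, p0), 0)
})

test_that("thin-shell conversion reproduces the coat rigidity calibration", {
  expect_equal(kappa_from_stiffness(0.08), 373, tolerance = 1e-4)
  expect_equal(kappa_from_stiffness(0), 0)
  k1 <- kappa_from_stiffness(0.04)
  expect_equal(kappa_from_stiffness(0.08), 2 * k1)   # linear in k
})

test_that("parameter validation rejects nonphysical values", {
  expect_error(model_params(kappa_memb = -1))
  expect_error(model_params(gamma = 0))
  expect_error(model_params(R_memb = -10))
  expect_s3_class(model_params(R_memb = 200), "model_params")
})
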