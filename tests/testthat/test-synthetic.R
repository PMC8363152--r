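test_that("closed-sphere lattices carry exactly 12 pentagons (Euler)", {
  for (edge in c(12, 18, 25)) {
    mesh <- build_cap_lattice(spherical_cap(R = 60, h = 120),
                              edge_length = edge, seed = 1)
    expect_equal(attr(mesh, "pentagon_count"), 12)
    expect_equal(sum(lengths(mesh$faces) == 5), 12)
    expect_true(all(lengths(mesh$faces) %in% c(5, 6)))
    # V - E + F = 2 on the closed polyhedron
    expect_equal(nrow(mesh$vertices) - nrow(mesh$edges) +
                   length(mesh$faces), 2)
    expect_true(all(mesh$degree == 3))
  }
})

test_that("near-flat caps are hexagon-dominant", {
  mesh <- build_cap_lattice(spherical_cap(R = 300, h = 15), seed = 3)
  expect_gte(mean(lengths(mesh$faces) == 6), 0.95)
  f6 <- polygon_angle_histogram(mesh, 6)
  expect_equal(f6$mean, 120, tolerance = 2)
})

test_that("mesh generation is deterministic per seed", {
  cap <- spherical_cap(R = 90, h = 80)
  m1 <- build_cap_lattice(cap, seed = 11)
  m2 <- build_cap_lattice(cap, seed = 11)
  m3 <- build_cap_lattice(cap, seed = 12)
  expect_identical(m1$vertices, m2$vertices)
  expect_false(isTRUE(all.equal(m1$vertices, m3$vertices)))
  expect_error(build_cap_lattice(cap, edge_length = 50), "\\[10, 30\\]")
})

test_that("rendering reproduces the cap apex and dominates under dilation", {
  cap <- spherical_cap(R = 100, h = 40)
  t0 <- render_topograph(synthetic_truth(cap, NULL, ridge_height = 0,
                                         r_tip = 0, noise_sd = 0, seed = 1))
  expect_equal(max(t0$heights), 40, tolerance = 1e-6)
  t1 <- render_topograph(synthetic_truth(cap, NULL, ridge_height = 0,
                                         r_tip = 2, noise_sd = 0, seed = 1))
  expect_true(all(t1$heights >= t0$heights - 1e-12))
  # dilation widens the apparent footprint
  expect_gt(sum(t1$heights > 0.5), sum(t0$heights > 0.5))
  # oversize cap rejected
  big <- spherical_cap(R = 400, h = 400)
  expect_error(render_topograph(synthetic_truth(big, NULL, seed = 1)),
               "footprint")
})

test_that("render noise is seeded and reproducible", {
  cap <- spherical_cap(R = 80, h = 40)
  tr <- synthetic_truth(cap, NULL, seed = 5)
  a <- render_topograph(tr)
  b <- render_topograph(tr)
  expect_identical(a$heights, b$heights)
  tr2 <- synthetic_truth(cap, NULL, seed = 6)
  expect_false(identical(render_topograph(tr2)$heights, a$heights))
})

test_that("population sampling follows the landscape", {
  # zero-temperature limit collapses onto the constrained minimum
  caps <- sample_population(n = 60, T_eff = 1e-9, seed = 4)
  m <- minimize_energy()
  R <- vapply(caps, `[[`, numeric(1), "R")
  A <- vapply(caps, `[[`, numeric(1), "A")
  expect_lt(max(abs(R - m$R) / m$R), 0.05)
  expect_lt(max(abs(A - m$A) / m$A), 0.12)
  # determinism contract
  c1 <- sample_population(n = 20, T_eff = 300, seed = 9)
  c2 <- sample_population(n = 20, T_eff = 300, seed = 9)
  c3 <- sample_population(n = 20, T_eff = 300, seed = 10)
  expect_identical(vapply(c1, `[[`, numeric(1), "R"),
                   vapply(c2, `[[`, numeric(1), "R"))
  expect_false(identical(vapply(c1, `[[`, numeric(1), "R"),
                         vapply(c3, `[[`, numeric(1), "R")))
  expect_error(sample_population(n = 5, T_eff = 0, seed = 1), "T_eff")
})

test_that("a sampled population peaks near the energy minimum", {
  caps <- sample_population(n = 2000, T_eff = 5, seed = 3)
  ar <- area_radius_distribution(caps)
  m <- minimize_energy()
  expect_lt(abs(ar$mode["R_nm"] - m$R) / m$R, 0.05)
  expect_lt(abs(ar$mode["A_nm2"] - m$A) / m$A, 0.10)
  # moderate temperature: population spans tens-of-nm radii
  caps2 <- sample_population(n = 128, T_eff = 300, seed = 5)
  R2 <- vapply(caps2, `[[`, numeric(1), "R")
  expect_gt(mean(R2), 30)
  expect_lt(mean(R2), 250)
})

test_that("nanodissection splits relax toward the intrinsic curvature", {
  mesh <- hex_patch_mesh(rings = 3, edge = 18)
  truth <- synthetic_truth(cap = NULL, mesh = mesh, seed = 1)
  v <- mesh$vertices
  cutters <- which((v[mesh$edges[, 1], 1] - 1) *
                     (v[mesh$edges[, 2], 1] - 1) < 0)
  res <- simulate_nanodissection(truth, cutters)
  expect_equal(nrow(res), 2)
  expect_true(all(is.infinite(res$R_before_nm)))
  expect_true(all(res$R_after_nm < 50))
  expect_equal(res$R_after_nm, relax_at_constant_area(res$A_nm2),
               tolerance = 1e-9)
  expect_true(all(res$dE_elastic_kBT <= 0))
  expect_equal(sum(res$n_faces), length(mesh$faces))
})

test_that("cuts that release no constraint change nothing", {
  # add a dangling open arm to a honeycomb and sever it
  mesh <- hex_patch_mesh(rings = 1, edge = 18)
  nv <- nrow(mesh$vertices)
  mesh2 <- lattice_skeleton(
    rbind(mesh$vertices, mesh$vertices[1, ] + c(18, 0, 0)),
    rbind(mesh$edges, c(1L, nv + 1L)), mesh$faces)
  truth <- synthetic_truth(cap = spherical_cap(R = 200, h = 30),
                           mesh = mesh2, seed = 2)
  cut <- which(mesh2$edges[, 1] == 1L & mesh2$edges[, 2] == nv + 1L)
  res <- simulate_nanodissection(truth, cut)
  expect_equal(nrow(res), 1)
  expect_equal(res$R_after_nm, res$R_before_nm)
  expect_equal(res$dE_elastic_kBT, 0)
  expect_error(simulate_nanodissection(truth, 9999), "nonexistent")
})

test_that("dissection never increases total elastic energy", {
  withr::with_seed(21, {
    mesh <- hex_patch_mesh(rings = 2, edge = 18)
    truth <- synthetic_truth(cap = NULL, mesh = mesh, seed = 1)
    for (rep in 1:10) {
      cuts <- sample(nrow(mesh$edges), sample(3:10, 1))
      res <- simulate_nanodissection(truth, cuts)
      before <- sum(res$E_elastic_before_kBT)
      after <- sum(res$E_elastic_after_kBT)
      expect_lte(after, before + 1e-9)
    }
  })
})
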