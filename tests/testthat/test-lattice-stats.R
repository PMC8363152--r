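test_that("hub angles reproduce canonical 3D geometries", {
  # planar 120-degree hub
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(-0.5, sqrt(3) / 2, 0),
             c(-0.5, -sqrt(3) / 2, 0))
  sk <- lattice_skeleton(v, rbind(c(1, 2), c(1, 3), c(1, 4)))
  h <- hub_angles(sk, 1)
  expect_equal(c(h$alpha, h$beta, h$gamma_angle), c(120, 120, 120))
  expect_equal(h$angle_sum, 360)
  expect_equal(h$class, "flat")
  # mutually orthogonal arms (cube corner)
  v2 <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  h2 <- hub_angles(lattice_skeleton(v2, rbind(c(1, 2), c(1, 3), c(1, 4))), 1)
  expect_equal(h2$angle_sum, 270)
  expect_equal(h2$class, "convex")
  # tetrahedral arms: three of the four vertex directions
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  v3 <- rbind(c(0, 0, 0), tet[2:4, ])
  h3 <- hub_angles(lattice_skeleton(v3, rbind(c(1, 2), c(1, 3), c(1, 4))), 1)
  expect_equal(h3$alpha, acos(-1 / 3) * 180 / pi, tolerance = 1e-9)
  expect_equal(h3$angle_sum, 3 * acos(-1 / 3) * 180 / pi, tolerance = 1e-9)
  # non-hub vertices are skipped with a warning
  expect_warning(out <- hub_angles(sk, 2), "degree")
  expect_null(out)
})

test_that("hub angles are invariant under rigid motion", {
  mesh <- build_cap_lattice(spherical_cap(R = 70, h = 60), seed = 5)
  ht <- skeleton_hub_table(mesh)
  th <- 0.7
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- mesh
  moved$vertices <- mesh$vertices %*% t(Rz) +
    matrix(c(13, -40, 7), nrow(mesh$vertices), 3, byrow = TRUE)
  ht2 <- skeleton_hub_table(moved)
  expect_equal(ht2$angle_sum, ht$angle_sum, tolerance = 1e-9)
  expect_equal(ht2$alpha, ht$alpha, tolerance = 1e-9)
})

test_that("conformation classes partition all hubs", {
  expect_equal(classify_conformation(336), "convex")
  expect_equal(classify_conformation(360), "flat")
  expect_equal(classify_conformation(365, tolerance = 2), "concave")
  expect_equal(classify_conformation(356, tolerance = 5), "flat")
  sums <- seq(250, 400, by = 0.5)
  cls <- classify_conformation(sums)
  expect_true(all(cls %in% c("convex", "flat", "concave")))
  expect_equal(length(cls), length(sums))
  mesh <- build_cap_lattice(spherical_cap(R = 50, h = 60), seed = 2)
  ht <- skeleton_hub_table(mesh)
  expect_equal(sum(table(ht$class)), nrow(ht))
})

test_that("angle fits collapse onto the regular interior angle for exact tilings", {
  flat <- hex_patch_mesh(rings = 2, edge = 18)
  fit <- polygon_angle_histogram(flat, 6)
  expect_equal(fit$mean, 120, tolerance = 1e-6)
  expect_lt(fit$sd, 1e-6)
  expect_equal(fit$n, 19 * 6)
  # dodecahedral cage: regular pentagons
  dodeca <- build_cap_lattice(spherical_cap(R = 40, h = 80), seed = 1)
  f5 <- polygon_angle_histogram(dodeca, 5)
  expect_equal(f5$mean, 108, tolerance = 0.5)
  # insufficient sample: no fit
  f7 <- polygon_angle_histogram(flat, 7)
  expect_true(is.na(f7$mean))
  expect_equal(f7$n, 0)
})

test_that("normal fit recovers the center of perturbed lattice angles", {
  # many jittered honeycombs: angles scatter around 120 degrees
  skels <- withr::with_seed(6, lapply(1:20, function(i) {
    sk <- hex_patch_mesh(rings = 2, edge = 18)
    sk$vertices <- sk$vertices + matrix(rnorm(length(sk$vertices), 0, 1),
                                        nrow(sk$vertices))
    sk
  }))
  fit <- polygon_angle_histogram(skels, 6)
  expect_equal(fit$n, 20 * 19 * 6)
  expect_lt(abs(fit$mean - 120), 1)
  expect_gt(fit$sd, 1)
  expect_equal(sum(fit$histogram$count), fit$n)
})

test_that("angle sums increase with cap radius on draped lattices", {
  rows <- do.call(rbind, lapply(c(50, 100, 200), function(R) {
    mesh <- build_cap_lattice(spherical_cap(R = R, h = R), seed = 7)
    ht <- skeleton_hub_table(mesh)
    data.frame(R_nm = R, angle_sum_deg = ht$angle_sum)
  }))
  av <- anglesum_vs_radius(rows, n_bins = 3)
  expect_equal(nrow(av$bins), 3)
  expect_true(all(diff(av$bins$mean_sum_deg) > 0))
  expect_gt(av$spearman_rho, 0)
  # flat lattices: all bins at 360
  flat_rows <- do.call(rbind, lapply(c(100, 200), function(R)
    data.frame(R_nm = R,
               angle_sum_deg = skeleton_hub_table(
                 hex_patch_mesh(1, 18))$angle_sum)))
  avf <- anglesum_vs_radius(flat_rows, n_bins = 2)
  expect_equal(avf$bins$mean_sum_deg, c(360, 360), tolerance = 1e-9)
  # closed cage sums are below flat-sheet sums
  cage <- skeleton_hub_table(build_cap_lattice(spherical_cap(40, 80), seed = 1))
  sheet <- skeleton_hub_table(hex_patch_mesh(2, 18))
  expect_lt(mean(cage$angle_sum), mean(sheet$angle_sum))
})

test_that("area-radius distributions expose means, mode and sphere locus", {
  two <- data.frame(A_nm2 = c(1000, 3000), R_nm = c(50, 150))
  expect_error(area_radius_distribution(two), "at least 3")
  three <- data.frame(A_nm2 = c(1000, 2000, 3000), R_nm = c(50, 100, 150))
  ar <- area_radius_distribution(three)
  expect_equal(ar$mean_A, 2000)
  expect_equal(ar$mean_R, 100)
  # all-spherical population sits on the A = 4*pi*R^2 locus
  R <- c(40, 55, 70, 90)
  caps <- lapply(R, function(r) spherical_cap(R = r, h = 2 * r))
  ar2 <- area_radius_distribution(caps)
  expect_equal(ar2$table$A_nm2, 4 * pi * R^2)
  p <- plot(ar2)
  expect_s3_class(p, "ggplot")
})
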