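test_that("ridge detection is quiet on a featureless plane", {
  noise <- topograph(withr::with_seed(1,
    matrix(rnorm(200 * 200, 0, 0.1), 200, 200)), 2)
  noise <- level_background(noise)
  mask <- detect_lattice(noise)
  expect_lt(mean(mask), 0.005)
})

test_that("ridge detection commutes with 90-degree rotation", {
  hc <- honeycomb_fixture()
  mask <- detect_lattice(hc$topo)
  rot <- hc$topo
  rot$heights <- t(hc$topo$heights)
  mask_rot <- detect_lattice(rot)
  expect_equal(mask_rot, t(mask))
})

test_that("ridge mask covers the true lattice on a clean fixture", {
  mesh <- hex_patch_mesh(rings = 2, edge = 18)
  tr <- synthetic_truth(cap = NULL, mesh = mesh, r_tip = 0, noise_sd = 0,
                        seed = 1)
  topo <- level_background(render_topograph(tr))
  mask <- detect_lattice(topo)
  # every rendered ridge pixel (height ~ ridge) within 1 px of the mask
  ridge_px <- which(topo$heights > 1)
  grown <- EBImage::dilate(matrix(as.numeric(mask), nrow(mask)),
                           EBImage::makeBrush(3, "box"))
  expect_gte(mean(grown[ridge_px] > 0), 0.95)
})

test_that("the 19-hexagon patch is recovered as a hexagonal skeleton", {
  hc <- honeycomb_fixture()
  sk <- build_skeleton(detect_lattice(hc$topo), hc$topo)
  sizes <- lengths(sk$faces)
  n_true <- length(hc$mesh$faces)           # 19
  expect_gte(sum(sizes == 6), 0.9 * n_true)
  expect_gte(mean(sizes == 6), 0.9)
  expect_equal(sum(sk$is_hub), sum(hc$mesh$is_hub), tolerance = 0.06)
  expect_lt(abs(nrow(sk$vertices) - nrow(hc$mesh$vertices)) /
              nrow(hc$mesh$vertices), 0.12)
  # hub positions coincide with true hubs
  tv <- hc$mesh$vertices[hc$mesh$is_hub, 1:2]
  tv <- tv + 299                            # frame centering
  rv <- sk$vertices[sk$is_hub, 1:2]
  dm <- as.matrix(stats::dist(rbind(tv, rv)))
  nn <- apply(dm[seq_len(nrow(tv)), nrow(tv) + seq_len(nrow(rv))], 1, min)
  expect_lt(median(nn), 5)
})

test_that("arm counts satisfy the polymerization bookkeeping identity", {
  hc <- honeycomb_fixture()
  sk <- build_skeleton(detect_lattice(hc$topo), hc$topo)
  expect_equal(sk$N_poly_arms, sk$N_total - sk$N_open_arms)
  expect_equal(hc$mesh$N_poly_arms, hc$mesh$N_total - hc$mesh$N_open_arms)
  skels <- list(sk, hc$mesh, hex_patch_mesh(1, 20),
                build_cap_lattice(spherical_cap(R = 60, h = 80), seed = 3))
  for (s in skels) expect_equal(s$N_poly_arms, s$N_total - s$N_open_arms)
})

test_that("a single straight ridge yields open arms and no hubs", {
  n <- 100
  h <- matrix(0, n, n)
  h[50, 20:80] <- 2
  topo <- topograph(h, 2)
  sk <- build_skeleton(detect_lattice(topo, min_prominence = 0.3), topo)
  expect_equal(sum(sk$is_hub), 0)
  expect_equal(length(sk$faces), 0)
  expect_gte(sk$N_total, 1)
  expect_equal(sk$N_open_arms, sk$N_total)
})

test_that("a closed triangular ridge yields one 3-cycle face", {
  n <- 120
  h <- matrix(0, n, n)
  # rasterize a triangle with ~40 px sides
  verts <- rbind(c(30, 30), c(90, 35), c(55, 85))
  for (i in 1:3) {
    a <- verts[i, ]; b <- verts[(i %% 3) + 1, ]
    ts <- seq(0, 1, length.out = 200)
    rr <- round(a[1] + (b[1] - a[1]) * ts)
    cc <- round(a[2] + (b[2] - a[2]) * ts)
    h[cbind(rr, cc)] <- 2
  }
  topo <- topograph(h, 2)
  sk <- build_skeleton(detect_lattice(topo, min_prominence = 0.3), topo)
  expect_equal(length(sk$faces), 1)
  expect_equal(sk$N_open_arms, 0)
  expect_equal(sum(sk$is_hub), 0)
  # every true corner lies on the recovered cycle (sharp corners may be
  # represented by two nearby bends after thinning)
  face_xy <- sk$vertices[sk$faces[[1]], 1:2]
  for (i in 1:3) {
    corner <- rev(verts[i, ] - 1) * 2      # (row, col) -> (x, y) nm
    expect_lt(min(sqrt(rowSums((face_xy -
      matrix(corner, nrow(face_xy), 2, byrow = TRUE))^2))), 15)
  }
})

test_that("skeleton JSON round-trips losslessly", {
  mesh <- build_cap_lattice(spherical_cap(R = 80, h = 60), seed = 9)
  tdir <- withr::local_tempdir()
  path <- file.path(tdir, "skel.json")
  write_skeleton(mesh, path)
  back <- read_skeleton(path)
  expect_equal(back$vertices, unname(as.matrix(mesh$vertices)))
  expect_equal(back$edges, mesh$edges)
  expect_equal(lapply(back$faces, as.integer), lapply(mesh$faces, as.integer))
  expect_equal(back$N_open_arms, mesh$N_open_arms)
})
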