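test_that("topograph round-trips through TIFF and CSV with sidecars", {
  m <- matrix(rnorm(30 * 40, mean = 5, sd = 3), 30, 40)
  t0 <- topograph(m, pixel_size = 2, zero_level = 1.5)
  tdir <- withr::local_tempdir()
  pt <- file.path(tdir, "t.tif")
  write_topograph(t0, pt)
  t1 <- read_topograph(pt)
  expect_equal(t1$heights, t0$heights, tolerance = 1e-6)
  expect_equal(t1$pixel_size, 2)
  expect_equal(t1$zero_level, 1.5)
  pc <- file.path(tdir, "t.csv")
  write_topograph(t0, pc)
  t2 <- read_topograph(pc)
  expect_equal(t2$heights, t0$heights, tolerance = 1e-12)
  expect_error(read_topograph(file.path(tdir, "missing.tif")), "sidecar")
  expect_error(topograph(m[1:4, ], 2), "16 x 16")
  expect_error(topograph(m, 0), "positive")
})

test_that("background leveling finds the membrane height robustly", {
  fx <- cap_fixture(R = 100, h = 40, noise_sd = 0.1, seed = 3)
  # the lowest-quartile median sits near the 12.5th background percentile,
  # about -1.15 noise sd below the true level
  expect_lt(abs(fx$topo$zero_level), 1.5 * 0.1)
  shifted <- fx$topo
  shifted$heights <- shifted$heights + 5
  shifted <- level_background(shifted)
  expect_lt(abs(shifted$zero_level - 5), 1.5 * 0.1)
  # pure noise: estimator sits at the median of the lowest quartile
  noise <- topograph(matrix(rnorm(300 * 300, 0, 0.1), 300, 300), 2)
  noise <- level_background(noise)
  expect_lt(abs(noise$zero_level - qnorm(0.125, 0, 0.1)), 0.01)
  flat <- level_background(topograph(matrix(2.5, 20, 20), 1))
  expect_equal(flat$zero_level, 2.5)
})

test_that("frame registration recovers integer drifts", {
  fx <- cap_fixture(R = 80, h = 60, noise_sd = 0, r_tip = 0,
                    n_pixels = 100, seed = 2)
  t1 <- fx$topo
  t2 <- t1
  t2$heights <- pitscape:::.shift_matrix(t1$heights, 3, -2, fill = 0)
  out <- register_frames(list(t1, t2))
  expect_equal(attr(out, "shifts")[2, ], c(-3, 2))
  expect_equal(out[[2]]$heights[10:90, 10:90], t1$heights[10:90, 10:90])
  # identical frames: zero shift
  out2 <- register_frames(list(t1, t1))
  expect_equal(attr(out2, "shifts")[2, ], c(0, 0))
  # robust to pixel noise
  t3 <- t2
  t3$heights <- t3$heights + withr::with_seed(4,
    matrix(rnorm(length(t3$heights), 0, 0.1), nrow(t3$heights)))
  out3 <- register_frames(list(t1, t3))
  expect_equal(attr(out3, "shifts")[2, ], c(-3, 2))
  # featureless frames fall back to identity with a warning
  f1 <- topograph(matrix(1, 32, 32), 1)
  expect_warning(register_frames(list(f1, f1)), "featureless")
})

test_that("section profiles recover local curvature", {
  fx <- cap_fixture(R = 100, h = 60, noise_sd = 0, r_tip = 0, seed = 1)
  ctr <- fx$center[1]
  pr <- section_profile(fx$topo, c(ctr - 200, ctr), c(ctr + 200, ctr),
                        window = 21)
  apex <- which.max(pr$height_nm)
  expect_equal(pr$radius_nm[apex], 100, tolerance = 0.02)
  # flat region: negligible curvature
  flat <- section_profile(fx$topo, c(2, 2), c(120, 2), window = 21)
  expect_true(all(abs(flat$curvature_inm[!is.na(flat$curvature_inm)]) < 1e-4))
  expect_error(section_profile(fx$topo, c(10, 10), c(10, 10)), "zero-length")
})

test_that("a section across two abutting caps shows two curvature maxima", {
  n <- 300; px <- 2
  xs <- (seq_len(n) - 1) * px
  cap_z <- function(x, x0, R, h) {
    d2 <- (x - x0)^2
    z <- (h - R) + sqrt(pmax(R^2 - d2, 0))
    ifelse(d2 <= R^2, pmax(z, 0), 0)
  }
  prof <- pmax(cap_z(xs, 220, 80, 50), cap_z(xs, 380, 80, 50))
  topo <- topograph(matrix(prof, n, n, byrow = TRUE), px)
  pr <- section_profile(topo, c(0, 300), c((n - 1) * px, 300), window = 15)
  curv <- pr$curvature_inm
  i1 <- which.min(abs(pr$s_nm - 220))
  i2 <- which.min(abs(pr$s_nm - 380))
  imid <- which.min(abs(pr$s_nm - 300))
  expect_gt(curv[i1], 0.9 / 80)
  expect_gt(curv[i2], 0.9 / 80)
  expect_lt(curv[imid], 0)    # saddle between the two pits
})
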