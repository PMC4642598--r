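test_that("hessian eigenvalues are zero on constant images and match the quadratic", {
  ev <- hessian_eigenvalues(matrix(7, 32, 32), 2)
  expect_equal(max(abs(ev$lambda1)), 0, tolerance = 1e-9)
  expect_equal(max(abs(ev$lambda2)), 0, tolerance = 1e-9)

  # I(x, y) = x^2 + 2 y^2 with x = column, y = row: Hessian diag(2, 4).
  n <- 41
  img <- outer(0:(n - 1), 0:(n - 1), function(r, c) c^2 + 2 * r^2)
  ev <- hessian_eigenvalues(img, 1)
  mid <- 15:25
  expect_equal(ev$lambda1[mid, mid], matrix(2, 11, 11), tolerance = 1e-8)
  expect_equal(ev$lambda2[mid, mid], matrix(4, 11, 11), tolerance = 1e-8)
  expect_true(all(abs(ev$lambda1) <= abs(ev$lambda2) + 1e-12))
  # scale normalisation multiplies by sigma^2
  ev2 <- hessian_eigenvalues(img, 2)
  expect_equal(ev2$lambda2[mid, mid], matrix(16, 11, 11), tolerance = 1e-6)
  expect_error(hessian_eigenvalues(img, 0), "sigma")
})

test_that("a dark bar yields positive lambda2 at its centre, matching an independent oracle", {
  img <- matrix(200, 50, 50)
  img[24:28, ] <- 50  # dark horizontal bar
  sigma <- 2
  ev <- hessian_eigenvalues(img, sigma)
  expect_true(all(ev$lambda2[26, 10:40] > 0))
  # independent smoothing + finite differences
  b <- oracle_blur(img, sigma)
  iyy <- sigma^2 * (b[27, 25] - 2 * b[26, 25] + b[25, 25])
  expect_equal(ev$lambda2[26, 25], iyy, tolerance = 1e-6)
})

test_that("vesselness follows the eigenvalue response formula", {
  v <- vesselness(matrix(100, 40, 40))
  expect_equal(max(v$values), 0)
  # negative lambda2 branch is zeroed
  expect_equal(vesselness_response(5, -30, 1, 10), 0)
  # direct substitution: lambda1 = 0, lambda2 = 30, beta = 1, c = 10
  expect_equal(vesselness_response(0, 30, 1, 10), 1 - exp(-900 / 200),
               tolerance = 1e-12)
  expect_error(vesselness_params(scales = numeric(0)), "scales")
  expect_error(vesselness_params(beta = 0), "beta")
})

test_that("vesselness is invariant to adding a constant and bounded in [0,1]", {
  set.seed(5)
  img <- matrix(stats::runif(64 * 64, 0, 200), 64, 64)
  v1 <- vesselness(img)
  v2 <- vesselness(img + 37)
  expect_equal(v1$values, v2$values, tolerance = 1e-9)
  expect_true(all(v1$values >= 0 & v1$values <= 1))
})

test_that("dip image reproduces the hand-computed window rule", {
  # 0-based rows: 7..10 = 127.5, 11..19 = 40, 20..23 = 140 -> for the
  # centre x = 15, v = 8: a = 120, b = 110, c = 40, candidate min(80, 70).
  col <- c(rep(127.5, 11), rep(40, 9), rep(140, 10))
  img <- matrix(col, 30, 3)
  # stride 2 from v_min 8 tests exactly the single width v = 8
  p <- dip_params(v_min = 8, v_max = 9, stride = 2, blur_sigma = 0)
  d <- dip_image(img, p)
  expect_equal(unname(d[12:20, 2]), rep(70, 9))
  expect_identical(unclass(d), dip_oracle(img, 8, 9, stride = 2))
  # constant column produces no dips at all
  expect_equal(max(dip_image(matrix(80, 40, 4), small_dip_params())), 0)
  expect_error(dip_image(matrix(0, 10, 4), dip_params(v_min = 8, v_max = 12)),
               "height")
})

test_that("dip image equals the exhaustive brute-force scan on random images", {
  set.seed(21)
  for (i in 1:5) {
    img <- matrix(sample(0:255, 64 * 64, replace = TRUE), 64, 64)
    p <- small_dip_params()
    expect_identical(unclass(dip_image(img, p)), dip_oracle(img, 8, 16))
  }
})

test_that("dip response is translation-covariant along columns and bounded", {
  set.seed(9)
  base <- rep(150, 96)
  base[30:45] <- 20          # one clear trough
  img <- matrix(base, 96, 2)
  shifted <- matrix(c(rep(150, 10), base)[1:96], 96, 2)
  p <- small_dip_params()
  d1 <- unclass(dip_image(img, p))[, 1]
  d2 <- unclass(dip_image(shifted, p))[, 1]
  expect_equal(d2[(1 + 10):80], d1[1:70], tolerance = 1e-12)
  expect_true(max(d1) <= diff(range(img)) + 1e-12)
})

test_that("pyramid dip: degenerate level is identical, seeds match full search, and it is faster", {
  ph <- make_phantom(phantom_preset("single_tube", speckle_sigma = 6, seed = 3))
  img <- render_frame(ph, transverse_probe_pose(70), calibration_spec(c(0.1, 0.1)),
                      c(640, 480), 1)
  p1 <- dip_params(pyramid_levels = 1)
  p2 <- dip_params(pyramid_levels = 2)
  full <- dip_image(img, p1)
  expect_identical(unclass(dip_image_pyramid(img, p1)), unclass(full))
  pyr <- dip_image_pyramid(img, p2)
  # thresholded seed sets agree at the T_d used downstream
  thr <- 0.5 * max(full)
  expect_identical(unclass(pyr) >= thr, unclass(full) >= thr)
  t_full <- min(replicate(3, system.time(dip_image(img, p1))[["elapsed"]]))
  t_pyr <- min(replicate(3, system.time(dip_image_pyramid(img, p2))[["elapsed"]]))
  expect_lt(t_pyr, t_full)
})

test_that("vesselness and dip maxima localise a rendered tube centre line", {
  # 6.5 mm tube at 0.5 mm/px: a 13 px diameter, matched to the default
  # scale set (sigma of order d/2) and a 8..20 px dip width range
  ph <- make_phantom(phantom_preset("single_tube", speckle_sigma = 0, seed = 1))
  calib <- calibration_spec(c(0.5, 0.5))
  img <- render_frame(ph, transverse_probe_pose(50), calib, c(128, 128), 0)
  # true centre: world (50, 24, 24) -> pixel (48, 48) -> R index [49, 49]
  d <- unclass(dip_image(img, dip_params(v_min = 8, v_max = 20, stride = 1)))
  peak <- which(d == max(d), arr.ind = TRUE)
  expect_lt(min(abs(peak[, 1] - 49)), 2 + 1e-9)
  expect_lt(min(abs(peak[, 2] - 49)), 2 + 1e-9)
  # vesselness is a line filter: image the tube longitudinally so it is a
  # line structure (horizontal band through the axis, centre row 49)
  pose <- rigid_transform(cbind(c(1, 0, 0), c(0, 0, 1), c(0, -1, 0)),
                          c(0, 24, 0))
  band <- render_frame(ph, pose, calib, c(128, 128), 0)
  v <- vesselness(band, vesselness_params(scales = c(5, 6.5, 8)))$values
  vpeak <- which(v == max(v), arr.ind = TRUE)
  expect_lte(max(abs(vpeak[, 1] - 49)), 2)
})
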