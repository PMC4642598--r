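test_that("phantom construction yields the expected graphs and bifurcations", {
  ph1 <- make_phantom(phantom_preset("single_tube"))
  expect_equal(length(ph1$graph$edges), 1)
  expect_equal(nrow(bifurcations(ph1$graph)), 0)

  phy <- make_phantom(phantom_preset("y_branch"))
  bf <- bifurcations(phy$graph)
  expect_equal(nrow(bf), 1)
  expect_equal(bf$degree, 3)

  phl <- make_phantom(phantom_preset("liver"))
  expect_equal(nrow(bifurcations(phl$graph)), 8)

  expect_error(phantom_spec(list(list(points = rbind(c(0, 0, 0)),
                                      diameter = 5))), ">= 2")
  expect_error(phantom_spec(list(list(points = rbind(c(0, 0, 0), c(1, 0, 0)),
                                      diameter = 5)),
                            lumen_intensity = 150), "hypoechoic")
})

test_that("a perpendicular cut renders a disc of the true diameter", {
  ph <- make_phantom(phantom_preset("single_tube", speckle_sigma = 0, seed = 1))
  calib <- calibration_spec(c(0.1, 0.1))
  img <- render_frame(ph, transverse_probe_pose(50), calib, c(640, 480), 0)
  expect_setequal(unique(as.vector(img)), c(30, 120))
  # lumen span across the centre row: 6.5 mm / 0.1 mm/px = 65 px within 1 px
  dark_cols <- which(img[241, ] < 75)
  dark_rows <- which(img[, 241] < 75)
  expect_lt(abs(length(dark_cols) - 65), 1 + 1e-9)
  expect_lt(abs(length(dark_rows) - 65), 1 + 1e-9)
  expect_equal(mean(range(dark_cols)) - 1, 240, tolerance = 1)
  # a plane that misses the phantom entirely renders pure background
  far <- render_frame(ph, transverse_probe_pose(500), calib, c(64, 64), 0)
  expect_equal(unique(as.vector(far)), 120)
})

test_that("an in-plane tube renders an elongated band, and shadows darken columns", {
  ph <- make_phantom(phantom_preset("single_tube", speckle_sigma = 0, seed = 1))
  calib <- calibration_spec(c(0.1, 0.1))
  # plane containing the tube axis: rows along world x, normal along y
  r <- cbind(c(1, 0, 0), c(0, 0, 1), c(0, -1, 0))
  pose <- rigid_transform(r, c(0, 24, 0))
  img <- render_frame(ph, pose, calib, c(640, 480), 0)
  dark <- img < 75
  expect_gt(sum(dark), 65 * 400)        # long band, not a disc
  rng <- range(which(colSums(dark) > 0))
  expect_gt(diff(rng), 500)

  phs <- make_phantom(phantom_preset("single_tube", speckle_sigma = 0,
                                     shadow_probability = 1, seed = 3))
  img2 <- render_frame(phs, transverse_probe_pose(50), calib, c(640, 480), 1)
  expect_true(any(img2 < 120 & img2 > 40))  # attenuated background exists
})

test_that("rendering and sweeps are deterministic given seeds", {
  ph <- make_phantom(phantom_preset("single_tube", speckle_sigma = 8, seed = 9))
  calib <- calibration_spec(c(0.1, 0.1))
  a <- render_frame(ph, transverse_probe_pose(30), calib, c(64, 64), 5)
  b <- render_frame(ph, transverse_probe_pose(30), calib, c(64, 64), 5)
  expect_identical(a, b)
  c1 <- render_frame(ph, transverse_probe_pose(30), calib, c(64, 64), 6)
  expect_false(identical(a, c1))

  sw <- sweep_spec(5, transverse_probe_pose(10), transverse_probe_pose(50),
                   frame_size = c(64, 64), calib = calib, seed = 2)
  s1 <- simulate_sweep(ph, sw)
  s2 <- simulate_sweep(ph, sw)
  expect_identical(s1$frames, s2$frames)
  expect_equal(s1$truth, s2$truth)
})

test_that("sweep poses interpolate the path and jitter only when asked", {
  ph <- make_phantom(phantom_preset("single_tube", speckle_sigma = 0, seed = 1))
  calib <- calibration_spec(c(0.1, 0.1))
  sw0 <- sweep_spec(5, transverse_probe_pose(10), transverse_probe_pose(50),
                    jitter_translation_mm = 0, jitter_rotation_deg = 0,
                    frame_size = c(64, 64), calib = calib, seed = 1)
  s <- simulate_sweep(ph, sw0)
  xs <- vapply(s$poses, function(p) p$translation[1], numeric(1))
  expect_equal(xs, seq(10, 50, by = 10), tolerance = 1e-12)
  one <- simulate_sweep(ph, sweep_spec(1, transverse_probe_pose(10),
                                       transverse_probe_pose(50),
                                       frame_size = c(64, 64), calib = calib))
  expect_length(one$frames, 1)
})

test_that("ground-truth 2D centres reproject onto the true centre lines", {
  ph <- make_phantom(phantom_preset("multi_tube", speckle_sigma = 5, seed = 11))
  calib <- calibration_spec(c(0.1, 0.1))
  sw <- sweep_spec(8, transverse_probe_pose(15), transverse_probe_pose(85),
                   calib = calib, seed = 3)
  s <- simulate_sweep(ph, sw)
  expect_gt(nrow(s$truth), 0)
  for (i in seq_len(nrow(s$truth))) {
    w <- pixel_to_world(as.numeric(s$truth[i, c("column", "row")]), calib,
                        s$poses[[s$truth$frame[i]]])
    expect_lt(max(abs(w - as.numeric(s$truth[i, c("x", "y", "z")]))), 1e-6)
    expect_lt(closest_point(ph$graph, w)$distance, 1e-6)
  }
})

test_that("perturb_model is seeded, rigid at zero amplitude, and bounded", {
  g <- liver_graph()
  t1 <- rigid_transform(rotation_about("z", 10), c(5, -3, 2))
  rigid_only <- perturb_model(g, t1, smooth_amplitude = 0)
  expect_equal(rigid_only$nodes, rt_apply(t1, g$nodes), tolerance = 1e-12)

  d1 <- perturb_model(g, t1, smooth_amplitude = 5, smooth_scale = 80, seed = 4)
  d2 <- perturb_model(g, t1, smooth_amplitude = 5, smooth_scale = 80, seed = 4)
  expect_identical(d1$nodes, d2$nodes)
  d3 <- perturb_model(g, t1, smooth_amplitude = 5, smooth_scale = 80, seed = 5)
  expect_false(identical(d1$nodes, d3$nodes))
  # displacement magnitude never exceeds the requested peak amplitude
  disp <- sqrt(rowSums((d1$nodes - rigid_only$nodes)^2))
  expect_lte(max(disp), 5 + 1e-9)
  expect_gt(max(disp), 0.5)  # and the field is not degenerate
})
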