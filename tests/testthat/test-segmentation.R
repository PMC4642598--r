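make_ves <- function(values) {
  structure(list(values = values, scale_of_max = values * 0 + 2),
            class = "vesselness_image")
}

test_that("seed mask keeps pixels passing both thresholds", {
  p <- segmentation_params(T_e = 0.5, T_d_fraction = 0.5)
  v <- matrix(0, 8, 8); v[2:4, 2:4] <- 0.9; v[6:7, 6:7] <- 0.9
  d <- matrix(0, 8, 8); d[3:5, 3:5] <- 140; d[1, 1] <- 60
  m <- candidate_seed_mask(make_ves(v), structure(d, class = c("dip_image", "matrix")), p)
  expected <- (v >= 0.5) & (d >= 70)   # dip max 140 -> threshold 70
  expect_identical(m, expected)
  expect_true(m[3, 3] && !m[6, 6] && !m[1, 1])
  # all-zero dip image -> empty mask, not all-true
  expect_false(any(candidate_seed_mask(make_ves(v), d * 0, p)))
  expect_error(candidate_seed_mask(make_ves(v[1:4, ]), d, p), "shape")
})

test_that("connected component labelling is 8-connected", {
  m <- matrix(FALSE, 5, 5)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE  # diagonal neighbours
  lab <- label_components(m)
  expect_equal(max(lab), 1L)
  m[5, 5] <- TRUE
  expect_equal(max(label_components(m)), 2L)
})

test_that("intensity prior keeps hypoechoic regions and drops bright ones", {
  img <- matrix(120, 40, 40)
  img[10:20, 10:20] <- 35    # dark tube-like region
  img[30:35, 5:35] <- 200    # bright band
  labels <- matrix(0L, 40, 40)
  labels[10:20, 10:20] <- 1L
  labels[30:35, 5:35] <- 2L
  p <- segmentation_params(intensity_prior = c(0, 80))
  expect_identical(intensity_prior_filter(labels, img, p), 1L)
})

test_that("contours trace seeded components only and approximate the region boundary", {
  v <- matrix(0, 80, 80)
  rr <- row(v); cc <- col(v)
  disc <- (rr - 40)^2 + (cc - 40)^2 <= 20^2
  disc2 <- (rr - 15)^2 + (cc - 15)^2 <= 8^2
  v[disc | disc2] <- 0.8
  img <- matrix(120, 80, 80); img[disc | disc2] <- 40
  seeds <- matrix(FALSE, 80, 80); seeds[40, 40] <- TRUE   # only big disc seeded
  p <- segmentation_params(T_e = 0.5)
  cts <- extract_contours(make_ves(v), seeds, img, p)
  expect_length(cts, 1)
  poly <- cts[[1]]$pixels
  # shoelace area within 5% of the disc area
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  area <- abs(sum(xs * ys[c(2:n, 1)] - xs[c(2:n, 1)] * ys)) / 2
  expect_lt(abs(area - pi * 20^2) / (pi * 20^2), 0.05)
  # empty seed mask -> no contours
  expect_length(extract_contours(make_ves(v), seeds & FALSE, img, p), 0)
})

test_that("ellipse fitting recovers circles and ellipses and flags degeneracy", {
  th <- seq(0, 2 * pi, length.out = 73)[-73]
  circ <- cbind(50 + 10 * cos(th), 60 + 10 * sin(th))
  f <- fit_ellipse(circ)
  expect_equal(f$centre, c(50, 60), tolerance = 0.1)
  expect_equal(f$semi_major, 10, tolerance = 0.1)
  expect_equal(f$semi_minor, 10, tolerance = 0.1)

  ell <- cbind(120 + 30 * cos(th), 90 + 12 * sin(th))
  f2 <- fit_ellipse(ell)
  expect_equal(f2$centre, c(120, 90), tolerance = 0.5)
  expect_equal(f2$semi_major, 30, tolerance = 0.5)
  expect_equal(f2$semi_minor, 12, tolerance = 0.5)
  expect_lt(min(abs(c(f2$angle, f2$angle - pi))), 0.05)

  # rotated ellipse
  rot <- 0.7
  rpts <- cbind(cos(rot) * 30 * cos(th) - sin(rot) * 12 * sin(th) + 10,
                sin(rot) * 30 * cos(th) + cos(rot) * 12 * sin(th) - 5)
  f3 <- fit_ellipse(rpts)
  expect_equal(f3$semi_major, 30, tolerance = 0.5)
  expect_equal(f3$angle, rot, tolerance = 0.05)

  expect_equal(fit_ellipse(circ[1:4, ])$rejection_reason, "fit_degenerate")
  line <- cbind(1:20, 2 * (1:20) + 3)
  expect_equal(fit_ellipse(line)$rejection_reason, "fit_degenerate")
})

test_that("ellipse acceptance applies short-axis then ratio rules", {
  p <- segmentation_params(v_min = 40, v_max = 100)
  mk <- function(minor, major) {
    structure(list(centre = c(0, 0), semi_major = major, semi_minor = minor,
                   angle = 0, accepted = NA, rejection_reason = "none"),
              class = "ellipse_fit")
  }
  # axis ratio 0.4 with in-range short axis -> ratio rejection
  e <- accept_ellipse(mk(24, 60), p)
  expect_false(e$accepted); expect_equal(e$rejection_reason, "axis_ratio")
  # short axis diameter 120 above v_max; short-axis rule fires first
  e2 <- accept_ellipse(mk(60, 200), p)
  expect_false(e2$accepted); expect_equal(e2$rejection_reason, "short_axis_range")
  # circle of diameter 60 passes everything
  e3 <- accept_ellipse(mk(30, 30), p)
  expect_true(e3$accepted); expect_equal(e3$rejection_reason, "none")
})

test_that("segment_frame finds the rendered tube and rejects oblique cuts", {
  expect_length(segment_frame(matrix(100, 200, 200),
                              dparams = dip_params(v_max = 100))$ellipses, 0)

  ph <- make_phantom(phantom_preset("single_tube", speckle_sigma = 8, seed = 2))
  calib <- calibration_spec(c(0.1, 0.1))
  img <- render_frame(ph, transverse_probe_pose(40), calib, c(640, 480), 3)
  s <- segment_frame(img)
  expect_equal(nrow(s$centres), 1)
  expect_lt(max(abs(s$centres[1, ] - c(240, 240))), 2)

  # oblique plane: rotate the probe 65 degrees about the image row axis so
  # the cut ellipse has axis ratio < 0.5 -> the centre must be rejected
  pose <- rigid_transform(
    transverse_probe_pose(50)$rotation %*% rotation_about("y", 65),
    c(50, 0, 0))
  img2 <- render_frame(ph, pose, calib, c(640, 480), 4)
  s2 <- segment_frame(img2)
  expect_equal(nrow(s2$centres), 0)
  reasons <- vapply(s2$ellipses, function(e) e$rejection_reason, character(1))
  expect_true(any(reasons %in% c("axis_ratio", "short_axis_range")))
})

test_that("accepted centres lie inside their contour bounding boxes", {
  ph <- make_phantom(phantom_preset("multi_tube", speckle_sigma = 8, seed = 4))
  img <- render_frame(ph, transverse_probe_pose(75), calibration_spec(c(0.1, 0.1)),
                      c(640, 480), 5)
  s <- segment_frame(img)
  expect_gt(length(s$ellipses), 0)
  for (k in seq_along(s$ellipses)) {
    e <- s$ellipses[[k]]
    if (!isTRUE(e$accepted)) next
    px <- s$contours[[k]]$pixels
    expect_true(e$centre[1] >= min(px[, 1]) && e$centre[1] <= max(px[, 1]))
    expect_true(e$centre[2] >= min(px[, 2]) && e$centre[2] <= max(px[, 2]))
  }
})

test_that("raising thresholds never adds contours or seeds", {
  ph <- make_phantom(phantom_preset("multi_tube", speckle_sigma = 10, seed = 6))
  img <- render_frame(ph, transverse_probe_pose(60), calibration_spec(c(0.1, 0.1)),
                      c(640, 480), 6)
  dp <- dip_params()
  blurred <- vesselreg:::blur_for_dip(img, dp)
  ves <- vesselness(blurred)
  dnb <- dp; dnb$blur_sigma <- 0
  dip <- dip_image(blurred, dnb)
  n_contours <- c(); n_seeds <- c()
  for (te in c(0.05, 0.12, 0.3, 0.6)) {
    p <- segmentation_params(T_e = te)
    seeds <- candidate_seed_mask(ves, dip, p)
    n_contours <- c(n_contours, length(extract_contours(ves, seeds, img, p)))
  }
  expect_true(all(diff(n_contours) <= 0))
  for (td in c(0.3, 0.5, 0.7, 0.9)) {
    p <- segmentation_params(T_d_fraction = td)
    n_seeds <- c(n_seeds, sum(candidate_seed_mask(ves, dip, p)))
  }
  expect_true(all(diff(n_seeds) <= 0))
})

test_that("reconstruction maps centres through calibration and poses", {
  empty <- reconstruct_centres(list(matrix(numeric(0), 0, 2)),
                               calibration_spec(), list(rt_identity()))
  expect_equal(nrow(empty$points), 0)

  rec <- reconstruct_centres(list(matrix(c(10, 20), 1, 2)),
                             calibration_spec(c(0.1, 0.1)),
                             list(rt_identity()))
  expect_equal(rec$points[1, ], c(1, 2, 0), tolerance = 1e-12)

  # global pose translation shifts the whole cloud by exactly t
  set.seed(10)
  centres <- replicate(4, matrix(stats::runif(6, 0, 400), 3, 2),
                       simplify = FALSE)
  poses <- replicate(4, random_rigid(), simplify = FALSE)
  calib <- calibration_spec(c(0.1, 0.2))
  base <- reconstruct_centres(centres, calib, poses)
  shift <- rigid_transform(diag(3), c(4, 5, 6))
  moved <- reconstruct_centres(centres, calib,
                               lapply(poses, function(p) rt_compose(shift, p)))
  expect_equal(moved$points, sweep(base$points, 2, c(4, 5, 6), "+"),
               tolerance = 1e-9)
  expect_equal(base$frame, rep(1:4, each = 3))
  expect_error(reconstruct_centres(centres, calib, poses[1:3]), "pose")
})
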