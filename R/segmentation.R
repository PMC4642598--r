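#' Segmentation parameters
#'
#' Controls the conversion of the two feature images into accepted vessel
#' centre points: the vesselness threshold `T_e` (suppresses background
#' noise), the dip threshold expressed as a fraction of the dip image
#' maximum (half of the maximum by construction of the method), the lumen
#' intensity prior, and the geometric ellipse acceptance rules.
#'
#' @param T_e vesselness threshold in `[0, 1]`. The default was calibrated
#'   once on a noiseless synthetic tube so the thresholded enhanced region
#'   reproduces the true lumen diameter; it depends on the imaging
#'   contrast and should be re-calibrated for other B-mode settings.
#' @param T_d_fraction dip threshold as a fraction of the dip maximum,
#'   in `(0, 1)`; default 0.5.
#' @param intensity_prior `[low, high]` grayscale range a vessel lumen is
#'   expected to occupy (default `c(0, 80)` of 255, hypoechoic).
#' @param v_min,v_max admissible vessel diameter range in pixels; also the
#'   bounds for the ellipse short-axis rule.
#' @param min_axis_ratio minimum `semi_minor / semi_major`; below it the
#'   vessel was cut at under ~30 degrees to its axis and the centre is
#'   unreliable. Default 0.5.
#' @param min_contour_pixels minimum number of contour vertices for a
#'   component to be considered (default 5, the ellipse-fit minimum).
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(T_e = 0.12, T_d_fraction = 0.5,
                                intensity_prior = c(0, 80),
                                v_min = 40, v_max = 100,
                                min_axis_ratio = 0.5,
                                min_contour_pixels = 5) {
  if (!(T_e >= 0 && T_e <= 1)) stop("T_e must lie in [0, 1]", call. = FALSE)
  if (!(T_d_fraction > 0 && T_d_fraction < 1)) {
    stop("T_d_fraction must lie in (0, 1)", call. = FALSE)
  }
  intensity_prior <- as.numeric(intensity_prior)
  if (length(intensity_prior) != 2L ||
      intensity_prior[1] >= intensity_prior[2]) {
    stop("intensity_prior must be [low, high] with low < high", call. = FALSE)
  }
  if (!(min_axis_ratio > 0 && min_axis_ratio <= 1)) {
    stop("min_axis_ratio must lie in (0, 1]", call. = FALSE)
  }
  structure(list(T_e = T_e, T_d_fraction = T_d_fraction,
                 intensity_prior = intensity_prior,
                 v_min = v_min, v_max = v_max,
                 min_axis_ratio = min_axis_ratio,
                 min_contour_pixels = as.integer(min_contour_pixels)),
            class = "segmentation_params")
}

#' Candidate vessel seed mask
#'
#' Pixels that pass both feature thresholds: vesselness `>= T_e` and dip
#' `>= T_d_fraction * max(dip)`. Regions appearing on both images are
#' kept. An all-zero dip image yields an empty mask (no trough evidence).
#'
#' @param ves a `vesselness_image`.
#' @param dip a `dip_image` (same shape).
#' @param params a `segmentation_params`.
#' @return Logical matrix.
#' @export
candidate_seed_mask <- function(ves, dip, params = segmentation_params()) {
  stopifnot(inherits(ves, "vesselness_image"),
            inherits(params, "segmentation_params"))
  v <- ves$values
  d <- unclass(dip)
  if (!all(dim(v) == dim(d))) {
    stop("vesselness and dip images have different shapes", call. = FALSE)
  }
  dmax <- max(d)
  if (dmax <= 0) return(matrix(FALSE, nrow(v), ncol(v)))
  (v >= params$T_e) & (d >= params$T_d_fraction * dmax)
}

#' Label connected components (8-connectivity)
#' @param mask logical matrix.
#' @return Integer matrix; 0 = background, components numbered from 1.
#' @export
label_components <- function(mask) {
  cpp_label8(mask)
}

#' Filter labelled regions by the lumen intensity prior
#'
#' A region survives iff the median raw intensity of its pixels lies in
#' `intensity_prior` — vessels are hypoechoic, so bright regions (bone,
#' specular artefacts) picked up by the enhancement filter are removed.
#'
#' @param labels integer label matrix (components of the thresholded
#'   vesselness image).
#' @param image the raw grayscale frame, same shape.
#' @param params a `segmentation_params`.
#' @return Integer vector of surviving label ids (possibly empty).
#' @export
intensity_prior_filter <- function(labels, image,
                                   params = segmentation_params()) {
  ids <- setdiff(sort(unique(as.vector(labels))), 0L)
  if (length(ids) == 0L) return(integer(0))
  meds <- vapply(ids, function(l) stats::median(image[labels == l]), numeric(1))
  ids[meds >= params$intensity_prior[1] & meds <= params$intensity_prior[2]]
}

#' Extract vessel contours
#'
#' Connected components of the thresholded vesselness image that contain
#' at least one candidate seed and survive the intensity prior are
#' identified as vessels; the outer boundary of each is returned as a
#' closed pixel polygon. Components without seeds are dropped.
#'
#' @param ves a `vesselness_image`.
#' @param seeds logical seed mask from [candidate_seed_mask()].
#' @param image raw grayscale frame (for the intensity prior).
#' @param params a `segmentation_params`.
#' @return List of `vessel_contour` objects: `pixels` (n x 2 matrix of
#'   0-based `(column, row)` vertices) and `seed_count`.
#' @export
extract_contours <- function(ves, seeds, image,
                             params = segmentation_params()) {
  stopifnot(inherits(ves, "vesselness_image"))
  th <- ves$values >= params$T_e
  if (!any(th) || !any(seeds)) return(list())
  labels <- label_components(th)
  seeded <- setdiff(sort(unique(labels[seeds])), 0L)
  if (length(seeded) == 0L) return(list())
  keep <- intersect(seeded, intensity_prior_filter(labels, image, params))
  out <- list()
  for (l in keep) {
    comp <- labels == l
    oc <- EBImage::ocontour(EBImage::Image(t(comp)))
    if (length(oc) == 0L) next
    poly <- oc[[1]]  # (x = col, y = row), 0-based
    if (nrow(poly) < params$min_contour_pixels) next
    out[[length(out) + 1L]] <- structure(
      list(pixels = unname(poly), seed_count = sum(seeds & comp)),
      class = "vessel_contour")
  }
  out
}

#' Direct least-squares ellipse fit to a contour
#'
#' Fits a conic constrained to be an ellipse (Halir-Flusser normalisation
#' of the direct least-squares method) and converts it to geometric
#' parameters. Fewer than 5 points or a degenerate (collinear) contour
#' yields `rejection_reason = "fit_degenerate"`.
#'
#' @param contour a `vessel_contour`, or an n x 2 matrix of `(column, row)`
#'   points.
#' @return An `ellipse_fit`: list with `centre` (length-2, subpixel
#'   `(column, row)`), `semi_major`, `semi_minor` (px, major >= minor),
#'   `angle` (radians, major-axis direction), `accepted` (NA until
#'   [accept_ellipse()]), `rejection_reason`.
#' @export
fit_ellipse <- function(contour) {
  pts <- if (inherits(contour, "vessel_contour")) contour$pixels else
    as.matrix(contour)
  bad <- function() {
    structure(list(centre = c(NA_real_, NA_real_), semi_major = NA_real_,
                   semi_minor = NA_real_, angle = NA_real_, accepted = FALSE,
                   rejection_reason = "fit_degenerate"),
              class = "ellipse_fit")
  }
  if (nrow(pts) < 5L) return(bad())
  x <- pts[, 1] - mean(pts[, 1])
  y <- pts[, 2] - mean(pts[, 2])
  d1 <- cbind(x^2, x * y, y^2)
  d2 <- cbind(x, y, 1)
  s1 <- crossprod(d1)
  s2 <- crossprod(d1, d2)
  s3 <- crossprod(d2)
  t3 <- tryCatch(-solve(s3, t(s2)), error = function(e) NULL)
  if (is.null(t3)) return(bad())
  m <- s1 + s2 %*% t3
  m <- rbind(m[3, ] / 2, -m[2, ], m[1, ] / 2)
  eg <- eigen(m)
  evec <- Re(eg$vectors)
  cond <- 4 * evec[1, ] * evec[3, ] - evec[2, ]^2
  ok <- which(cond > 0)
  if (length(ok) == 0L) return(bad())
  a1 <- evec[, ok[1]]
  coef <- c(a1, as.numeric(t3 %*% a1))  # A B C D E F on centred coords
  names(coef) <- c("A", "B", "C", "D", "E", "F")
  A <- unname(coef["A"]); B <- unname(coef["B"]) / 2; C <- unname(coef["C"])
  D <- unname(coef["D"]) / 2; E <- unname(coef["E"]) / 2; F <- unname(coef["F"])
  den <- A * C - B^2
  if (abs(den) < 1e-12) return(bad())
  cx <- (B * E - C * D) / den
  cy <- (B * D - A * E) / den
  # centred conic: [x y] M2 [x y]' = V; semi-axis along eigenvector i has
  # length sqrt(V / lambda_i), the major axis on the smaller eigenvalue
  V <- -(A * cx^2 + 2 * B * cx * cy + C * cy^2 + 2 * D * cx + 2 * E * cy + F)
  m2 <- matrix(c(A, B, B, C), 2, 2)
  if (V < 0) {
    V <- -V
    m2 <- -m2
  }
  eg2 <- eigen(m2, symmetric = TRUE)   # eigenvalues decreasing
  if (any(eg2$values <= 0) || V <= 0) return(bad())
  semi_minor <- sqrt(V / eg2$values[1])
  semi_major <- sqrt(V / eg2$values[2])
  theta <- atan2(eg2$vectors[2, 2], eg2$vectors[1, 2])
  structure(list(centre = as.numeric(c(cx + mean(pts[, 1]),
                                       cy + mean(pts[, 2]))),
                 semi_major = as.numeric(semi_major),
                 semi_minor = as.numeric(semi_minor),
                 angle = as.numeric(theta) %% pi,
                 accepted = NA, rejection_reason = "none"),
            class = "ellipse_fit")
}

#' Apply the geometric acceptance rules to a fitted ellipse
#'
#' Accepted iff the short-axis diameter `2 * semi_minor` lies in
#' `[v_min, v_max]` and the axis ratio `semi_minor / semi_major` exceeds
#' `min_axis_ratio`. A ratio at or below 0.5 means the vessel was scanned
#' at under ~30 degrees to its centre-line, which does not produce a
#' reliable centre. The short-axis rule is checked first, so
#' `rejection_reason` is deterministic.
#'
#' @param e an `ellipse_fit` (fit must have succeeded).
#' @param params a `segmentation_params`.
#' @return The `ellipse_fit` with `accepted` and `rejection_reason` set.
#' @export
accept_ellipse <- function(e, params = segmentation_params()) {
  stopifnot(inherits(e, "ellipse_fit"))
  if (identical(e$rejection_reason, "fit_degenerate")) return(e)
  short_d <- 2 * e$semi_minor
  if (short_d < params$v_min || short_d > params$v_max) {
    e$accepted <- FALSE
    e$rejection_reason <- "short_axis_range"
  } else if (e$semi_minor / e$semi_major <= params$min_axis_ratio) {
    e$accepted <- FALSE
    e$rejection_reason <- "axis_ratio"
  } else {
    e$accepted <- TRUE
    e$rejection_reason <- "none"
  }
  e
}

#' Segment one B-mode frame into vessel centre points
#'
#' Deterministic composition of the whole per-frame chain: vesselness,
#' dip image, seed mask, intensity prior, contour extraction, ellipse
#' fitting and geometric acceptance. Stateless per frame.
#'
#' @param image numeric matrix `[row, col]`, intensities 0..255 (or an
#'   `ultrasound_frame`, whose image is used).
#' @param params a `segmentation_params`.
#' @param vparams a `vesselness_params`.
#' @param dparams a `dip_params`.
#' @param keep_intermediates if TRUE, the feature images and mask are
#'   returned for inspection.
#' @return List with `centres` (n x 2 matrix of accepted subpixel
#'   `(column, row)` centres), `ellipses` (all fits, accepted or not),
#'   `contours`, and optionally `vesselness`, `dip`, `seeds`.
#' @export
segment_frame <- function(image, params = segmentation_params(),
                          vparams = vesselness_params(),
                          dparams = dip_params(),
                          keep_intermediates = FALSE) {
  if (inherits(image, "ultrasound_frame")) image <- image$image
  image <- as.matrix(image)
  # one shared pre-blur: both feature images work on the denoised frame
  blurred <- blur_for_dip(image, dparams)
  ves <- vesselness(blurred, vparams)
  dnb <- dparams
  dnb$blur_sigma <- 0
  dip <- if (dparams$pyramid_levels > 1L) dip_image_pyramid(blurred, dnb)
         else dip_image(blurred, dnb)
  seeds <- candidate_seed_mask(ves, dip, params)
  contours <- extract_contours(ves, seeds, image, params)
  ellipses <- lapply(contours, function(cc) accept_ellipse(fit_ellipse(cc),
                                                           params))
  acc <- vapply(ellipses, function(e) isTRUE(e$accepted), logical(1))
  centres <- if (any(acc)) {
    do.call(rbind, lapply(ellipses[acc], function(e) e$centre))
  } else matrix(numeric(0), 0L, 2L)
  out <- list(centres = centres, ellipses = ellipses, contours = contours)
  if (keep_intermediates) {
    out$vesselness <- ves
    out$dip <- dip
    out$seeds <- seeds
  }
  out
}

#' Tracked ultrasound frame
#' @param image numeric matrix `[row, col]`, 0..255.
#' @param pose `rigid_transform` (sensor to tracker) or NULL.
#' @param timestamp acquisition time in seconds.
#' @return An `ultrasound_frame`.
#' @export
ultrasound_frame <- function(image, pose = NULL, timestamp = NA_real_) {
  structure(list(image = as.matrix(image), pose = pose, timestamp = timestamp),
            class = "ultrasound_frame")
}

#' Reconstruct per-frame centres into a 3D point cloud
#'
#' Applies [pixel_to_world()] to every accepted centre; output rows keep
#' `(frame, detection)` order.
#'
#' @param centres list with one n_i x 2 matrix of `(column, row)` centres
#'   per frame (possibly 0-row).
#' @param calib a `calibration_spec`.
#' @param poses list of `rigid_transform`, one per frame.
#' @return List with `points` (n x 3 matrix, mm) and `frame` (integer
#'   vector mapping each point to its source frame).
#' @export
reconstruct_centres <- function(centres, calib, poses) {
  if (length(centres) != length(poses)) {
    stop("need exactly one pose per frame", call. = FALSE)
  }
  pts <- list(); frame <- list()
  for (i in seq_along(centres)) {
    ci <- centres[[i]]
    if (is.null(ci) || nrow(ci) == 0L) next
    if (is.null(poses[[i]])) {
      stop(sprintf("frame %d has centres but no pose", i), call. = FALSE)
    }
    pts[[length(pts) + 1L]] <- pixel_to_world(ci, calib, poses[[i]])
    frame[[length(frame) + 1L]] <- rep(i, nrow(ci))
  }
  if (length(pts) == 0L) {
    return(list(points = matrix(numeric(0), 0L, 3L), frame = integer(0)))
  }
  list(points = do.call(rbind, pts), frame = unlist(frame))
}
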