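#' Rigid transform in 3D
#'
#' A rigid transform is stored as a 3x3 rotation matrix plus a translation
#' vector in millimetres. It represents the map `x -> R x + t`. Validation
#' enforces orthonormality (`t(R) R = I` and `det(R) = +1`, both within
#' 1e-9), so reflections and scalings are rejected.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation numeric length-3 vector (mm).
#' @return An object of class `rigid_transform` with elements `rotation`
#'   and `translation`.
#' @examples
#' t1 <- rigid_transform(rotation_about("z", 90), c(1, 0, 0))
#' rt_apply(t1, c(0, 0, 0))
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L)) || !all(is.finite(rotation))) {
    stop("rotation must be a finite 3x3 matrix", call. = FALSE)
  }
  if (length(translation) != 3L || !all(is.finite(translation))) {
    stop("translation must be a finite length-3 vector", call. = FALSE)
  }
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9) {
    stop("rotation is not orthonormal within 1e-9", call. = FALSE)
  }
  if (abs(det(rotation) - 1) > 1e-9) {
    stop("rotation determinant is not +1 within 1e-9 (improper rotation)",
         call. = FALSE)
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n")
  cat(sprintf("  rotation angle: %.4f deg\n", rotation_angle(x$rotation)))
  cat(sprintf("  translation   : [%.4f, %.4f, %.4f] mm\n",
              x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Identity rigid transform
#' @return A `rigid_transform` with identity rotation and zero translation.
#' @export
rt_identity <- function() rigid_transform(diag(3), c(0, 0, 0))

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying `b` first, then `a`, i.e.
#' `(a %then% b)(x) = a(b(x))`.
#'
#' @param a,b `rigid_transform` objects.
#' @return The composed `rigid_transform`.
#' @export
rt_compose <- function(a, b) {
  stopifnot(inherits(a, "rigid_transform"), inherits(b, "rigid_transform"))
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param t a `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
rt_inverse <- function(t) {
  stopifnot(inherits(t, "rigid_transform"))
  rigid_transform(t(t$rotation), as.numeric(-t(t$rotation) %*% t$translation))
}

#' Apply a rigid transform to points
#'
#' @param t a `rigid_transform`.
#' @param points length-3 vector or n x 3 matrix of points (mm).
#' @return Transformed points, same shape as the input.
#' @export
rt_apply <- function(t, points) {
  stopifnot(inherits(t, "rigid_transform"))
  if (is.null(dim(points))) {
    return(as.numeric(t$rotation %*% points) + t$translation)
  }
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3L)
  sweep(points %*% t(t$rotation), 2L, t$translation, "+")
}

#' Rotation matrix about a coordinate axis
#' @param axis one of `"x"`, `"y"`, `"z"`.
#' @param angle_deg rotation angle in degrees (right-handed).
#' @return 3x3 rotation matrix.
#' @export
rotation_about <- function(axis = c("x", "y", "z"), angle_deg) {
  axis <- match.arg(axis)
  a <- angle_deg * pi / 180
  ca <- cos(a); sa <- sin(a)
  switch(axis,
    x = matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3, 3),
    y = matrix(c(ca, 0, -sa, 0, 1, 0, sa, 0, ca), 3, 3),
    z = matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3))
}

#' Rotation matrix from an axis and angle
#' @param axis length-3 direction (need not be unit).
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 rotation matrix (Rodrigues formula).
#' @export
axis_angle_rotation <- function(axis, angle_deg) {
  n <- axis / sqrt(sum(axis^2))
  a <- angle_deg * pi / 180
  k <- matrix(c(0, n[3], -n[2], -n[3], 0, n[1], n[2], -n[1], 0), 3, 3)
  diag(3) + sin(a) * k + (1 - cos(a)) * (k %*% k)
}

#' Rotation angle of a rotation matrix
#' @param r 3x3 rotation matrix.
#' @return Angle in degrees in `[0, 180]`.
#' @export
rotation_angle <- function(r) {
  ct <- (sum(diag(r)) - 1) / 2
  acos(min(1, max(-1, ct))) * 180 / pi
}

#' Convert a rigid transform to/from a 4x4 homogeneous matrix
#' @param t a `rigid_transform`.
#' @return `rt_to_matrix`: a 4x4 matrix; `rt_from_matrix`: a `rigid_transform`.
#' @export
rt_to_matrix <- function(t) {
  stopifnot(inherits(t, "rigid_transform"))
  m <- diag(4)
  m[1:3, 1:3] <- t$rotation
  m[1:3, 4] <- t$translation
  m
}

#' @rdname rt_to_matrix
#' @param m a 4x4 homogeneous matrix with last row (0,0,0,1).
#' @export
rt_from_matrix <- function(m) {
  m <- as.matrix(m)
  stopifnot(all(dim(m) == c(4L, 4L)))
  if (max(abs(m[4, ] - c(0, 0, 0, 1))) > 1e-9) {
    stop("last row of a homogeneous rigid matrix must be (0, 0, 0, 1)",
         call. = FALSE)
  }
  rigid_transform(m[1:3, 1:3], m[1:3, 4])
}

#' Ultrasound probe calibration
#'
#' Bundles the in-plane pixel scale with the image-plane-to-sensor rigid
#' transform. Pixel coordinates are 0-based, `column` increasing left to
#' right and `row` top to down; the in-plane point for pixel `(column, row)`
#' is `(column * scale_x, row * scale_y, 0)` in millimetres.
#'
#' @param pixel_scale length-2 positive vector: mm/pixel along the column
#'   and row axes.
#' @param image_to_sensor `rigid_transform` mapping the scaled image plane
#'   into the tracked-sensor frame.
#' @return An object of class `calibration_spec`.
#' @export
calibration_spec <- function(pixel_scale = c(0.1, 0.1),
                             image_to_sensor = rt_identity()) {
  pixel_scale <- as.numeric(pixel_scale)
  if (length(pixel_scale) != 2L || any(!is.finite(pixel_scale)) ||
      any(pixel_scale <= 0)) {
    stop("pixel_scale must be two positive finite numbers (mm/pixel)",
         call. = FALSE)
  }
  stopifnot(inherits(image_to_sensor, "rigid_transform"))
  structure(list(pixel_scale = pixel_scale, image_to_sensor = image_to_sensor),
            class = "calibration_spec")
}

#' Reconstruct pixels into tracker (world) coordinates
#'
#' Maps 2D pixel coordinates through the ultrasound calibration and the
#' frame's tracking pose: scale to millimetres in the image plane (z = 0),
#' apply `image_to_sensor`, then the sensor-to-tracker pose.
#'
#' @param pixels length-2 vector `(column, row)` or n x 2 matrix, 0-based.
#' @param calib a `calibration_spec`.
#' @param pose `rigid_transform`, sensor to tracker.
#' @return n x 3 matrix (or length-3 vector) of world points in mm.
#' @export
pixel_to_world <- function(pixels, calib, pose) {
  stopifnot(inherits(calib, "calibration_spec"),
            inherits(pose, "rigid_transform"))
  vec <- is.null(dim(pixels))
  p <- if (vec) matrix(as.numeric(pixels), 1L, 2L) else as.matrix(pixels)
  stopifnot(ncol(p) == 2L)
  plane <- cbind(p[, 1] * calib$pixel_scale[1], p[, 2] * calib$pixel_scale[2], 0)
  world <- rt_apply(rt_compose(pose, calib$image_to_sensor), plane)
  if (vec) as.numeric(world) else world
}
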