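#' Parameters for the multi-scale Hessian vesselness filter
#'
#' The 2D vesselness of a pixel is
#' `v0 = exp(-R_B^2 / (2 beta^2)) * (1 - exp(-S^2 / (2 c^2)))` when
#' `lambda2 >= 0` and 0 otherwise, with `R_B = lambda1 / lambda2`,
#' `S = sqrt(lambda1^2 + lambda2^2)` and eigenvalues ordered
#' `|lambda1| <= |lambda2|`. Zeroing the `lambda2 < 0` branch makes the
#' filter respond to dark (hypoechoic) tubular structures, as vessels
#' appear in B-mode ultrasound.
#'
#' @param beta sensitivity of the blob/line measure `R_B`; default 1.
#' @param c_sensitivity sensitivity of the second-order structure measure
#'   `S`; default 10 (suited to 8-bit intensity curvatures). Distinct from
#'   the dip-region mean also conventionally called `c`.
#' @param scales Gaussian standard deviations in pixels for the
#'   multi-scale Hessian. Default `c(2, 3, 4.5, 6)`: the thresholded
#'   response region of a dark tube extends past the true wall by about
#'   `sigma^2 / d` pixels (curvature shift of the `lambda2` sign change),
#'   so contour-faithful segmentation needs scales well below the vessel
#'   radius; the maximum response still localises the centre line, and a
#'   small pre-blur (see [dip_params()]) supplies the noise suppression
#'   large scales would otherwise provide.
#' @return An object of class `vesselness_params`.
#' @export
vesselness_params <- function(beta = 1, c_sensitivity = 10, scales = NULL) {
  if (is.null(scales)) scales <- c(2, 3, 4.5, 6)
  scales <- as.numeric(scales)
  if (!is.finite(beta) || beta <= 0) stop("beta must be > 0", call. = FALSE)
  if (!is.finite(c_sensitivity) || c_sensitivity <= 0) {
    stop("c_sensitivity must be > 0", call. = FALSE)
  }
  if (length(scales) == 0L || any(!is.finite(scales)) || any(scales <= 0)) {
    stop("scales must be a non-empty vector of positive sigmas", call. = FALSE)
  }
  structure(list(beta = beta, c_sensitivity = c_sensitivity, scales = scales),
            class = "vesselness_params")
}

#' Scale-normalised Hessian eigenvalues of an image
#'
#' Smooths the image with a Gaussian of standard deviation `sigma`
#' (separable, mirror boundary), takes central second differences, and
#' multiplies by `sigma^2` (scale normalisation). Eigenvalues are returned
#' ordered by magnitude, `|lambda1| <= |lambda2|` per pixel.
#'
#' @param image numeric matrix `[row, col]`.
#' @param sigma Gaussian standard deviation in pixels, > 0.
#' @return List with matrices `lambda1` and `lambda2`.
#' @export
hessian_eigenvalues <- function(image, sigma) {
  image <- as.matrix(image)
  if (nrow(image) < 3L || ncol(image) < 3L) {
    stop("image must be at least 3x3", call. = FALSE)
  }
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  cpp_hessian_eigen(image, sigma)
}

#' Scalar vesselness response
#'
#' The per-pixel, per-scale response as a function of the two ordered
#' eigenvalues. Vectorised; used internally by [vesselness()].
#'
#' @param lambda1,lambda2 eigenvalues with `|lambda1| <= |lambda2|`.
#' @param beta,c_sensitivity sensitivities (see [vesselness_params()]).
#' @return Response values in `[0, 1]`.
#' @export
vesselness_response <- function(lambda1, lambda2, beta, c_sensitivity) {
  rb2 <- (lambda1 / lambda2)^2
  rb2[lambda2 == 0] <- 0  # flat pixel: lambda1 is 0 too
  s2 <- lambda1^2 + lambda2^2
  v <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-s2 / (2 * c_sensitivity^2)))
  v[lambda2 < 0] <- 0
  v
}

#' Multi-scale vesselness image
#'
#' Evaluates the vesselness response at each scale in `params$scales` and
#' keeps, per pixel, the maximum response and the scale attaining it.
#'
#' @param image numeric matrix `[row, col]`, intensities 0..255.
#' @param params a `vesselness_params`.
#' @return Object of class `vesselness_image`: list with `values` (matrix
#'   in `[0, 1]`) and `scale_of_max` (matrix of winning sigmas, px).
#' @export
vesselness <- function(image, params = vesselness_params()) {
  stopifnot(inherits(params, "vesselness_params"))
  image <- as.matrix(image)
  best <- matrix(0, nrow(image), ncol(image))
  best_s <- matrix(params$scales[1], nrow(image), ncol(image))
  for (s in params$scales) {
    ev <- hessian_eigenvalues(image, s)
    v <- vesselness_response(ev$lambda1, ev$lambda2,
                             params$beta, params$c_sensitivity)
    upd <- v > best
    best[upd] <- v[upd]
    best_s[upd] <- s
  }
  structure(list(values = best, scale_of_max = best_s),
            class = "vesselness_image")
}

#' Parameters for the dip image
#'
#' The dip image measures, along each beam line (image column for a linear
#' probe), the depth of intensity troughs whose width matches the expected
#' vessel diameter range `[v_min, v_max]` in pixels. Defaults cover the
#' 3-9 mm hepatic vessel calibre at 0.1 mm/pixel (40-100 px).
#'
#' @param v_min,v_max vessel width search range in pixels, `0 < v_min < v_max`.
#' @param pyramid_levels number of pyramid levels for the coarse-to-fine
#'   search ([dip_image_pyramid()]); 1 disables the pyramid.
#' @param blur_sigma Gaussian pre-blur in pixels applied before the column
#'   scan (default 2).
#' @param stride step between tested widths `v` in pixels; 1 scans every
#'   integer width (exhaustive), larger values trade accuracy for speed.
#' @return An object of class `dip_params`.
#' @export
dip_params <- function(v_min = 40, v_max = 100, pyramid_levels = 1,
                       blur_sigma = 2, stride = 4) {
  if (!(v_min > 0 && v_max > v_min)) {
    stop("need 0 < v_min < v_max", call. = FALSE)
  }
  if (pyramid_levels < 1) stop("pyramid_levels must be >= 1", call. = FALSE)
  if (blur_sigma < 0) stop("blur_sigma must be >= 0", call. = FALSE)
  if (stride < 1) stop("stride must be >= 1", call. = FALSE)
  structure(list(v_min = as.integer(v_min), v_max = as.integer(v_max),
                 pyramid_levels = as.integer(pyramid_levels),
                 blur_sigma = blur_sigma, stride = as.integer(stride)),
            class = "dip_params")
}

blur_for_dip <- function(image, params) {
  if (params$blur_sigma > 0) cpp_gauss_blur(image, params$blur_sigma) else image
}

#' Dip image: intensity troughs along the beam direction
#'
#' After a Gaussian pre-blur, each column is scanned: for a centre row `x`
#' and width `v`, three window means are taken over the inclusive row
#' intervals `a = [x+v/2, x+v]`, `b = [x-v, x-v/2]`, `c = [x-v/2, x+v/2]`
#' (half-widths are `floor(v/2)`). If `c < a` and `c < b` — a trough
#' flanked by brighter tissue — every pixel in `[x-v/2, x+v/2]` receives
#' the candidate value `min(a - c, b - c)`; a pixel's final value is the
#' maximum candidate over all `(x, v)` covering it. Windows that would
#' extend outside the column are skipped.
#'
#' @param image numeric matrix `[row, col]`, intensities 0..255.
#' @param params a `dip_params`; the image must be taller than
#'   `2 * v_max + 1` rows for any window to fit.
#' @return Non-negative matrix of dip magnitudes (intensity units), class
#'   `dip_image`.
#' @export
dip_image <- function(image, params = dip_params()) {
  stopifnot(inherits(params, "dip_params"))
  image <- as.matrix(image)
  if (params$v_max >= nrow(image)) {
    stop("v_max must be smaller than the image height", call. = FALSE)
  }
  b <- blur_for_dip(image, params)
  out <- cpp_dip(b, params$v_min, params$v_max, params$stride)
  structure(out, class = c("dip_image", "matrix"))
}

#' Coarse-to-fine dip image
#'
#' Runs the dip search on a block-averaged downsampled image (factor
#' `2^(pyramid_levels - 1)`) to find columns with any trough response,
#' then repeats the full-resolution scan only on those columns (plus one
#' coarse-column margin on each side). With `pyramid_levels = 1` this is
#' exactly [dip_image()].
#'
#' @inheritParams dip_image
#' @return Matrix of dip magnitudes, class `dip_image`.
#' @export
dip_image_pyramid <- function(image, params = dip_params()) {
  stopifnot(inherits(params, "dip_params"))
  if (params$pyramid_levels == 1L) return(dip_image(image, params))
  image <- as.matrix(image)
  if (params$v_max >= nrow(image)) {
    stop("v_max must be smaller than the image height", call. = FALSE)
  }
  f <- 2L^(params$pyramid_levels - 1L)
  b <- blur_for_dip(image, params)
  coarse <- block_mean(b, f)
  cvmin <- max(1L, params$v_min %/% f)
  cvmax <- max(cvmin + 1L, as.integer(ceiling(params$v_max / f)))
  cstride <- max(1L, as.integer(round(params$stride / f)))
  cd <- cpp_dip(coarse, cvmin, cvmax, cstride)
  # keep columns that could still contribute to the half-of-maximum seed
  # threshold used downstream; 0.25 leaves a factor-2 safety margin for
  # block-averaging attenuation
  cmax <- max(cd)
  active_coarse <- apply(cd, 2L, max) >= 0.25 * cmax & cmax > 0
  # dilate by one coarse column each side, then expand to full resolution
  n <- length(active_coarse)
  dil <- active_coarse
  if (n > 1L) {
    dil <- active_coarse | c(active_coarse[-1], FALSE) |
      c(FALSE, active_coarse[-n])
  }
  active_full <- rep(dil, each = f)[seq_len(ncol(image))]
  out <- cpp_dip_columns(b, params$v_min, params$v_max, params$stride,
                         active_full)
  structure(out, class = c("dip_image", "matrix"))
}

# Block mean downsample by integer factor (trailing partial blocks dropped).
block_mean <- function(image, f) {
  nr <- (nrow(image) %/% f) * f
  nc <- (ncol(image) %/% f) * f
  x <- image[seq_len(nr), seq_len(nc), drop = FALSE]
  # average f x f blocks
  x <- rowsum(x, rep(seq_len(nr %/% f), each = f)) / f
  t(rowsum(t(x), rep(seq_len(nc %/% f), each = f)) / f)
}
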