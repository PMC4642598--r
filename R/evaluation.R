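#' Landmark pair table
#'
#' Builds the evaluation landmark table from matched positions: each
#' landmark (typically a labelled bifurcation) identified both in the
#' preoperative model space (G/CT) and in the intraoperative space
#' (P/US, world).
#'
#' @param id character vector of unique landmark ids.
#' @param g_points n x 3 matrix of positions in G-space (mm).
#' @param p_points n x 3 matrix of positions in P-space (mm).
#' @return data.frame of class `landmark_pairs` with columns
#'   `id, gx, gy, gz, px, py, pz`.
#' @export
landmark_pairs <- function(id, g_points, p_points) {
  g_points <- as.matrix(g_points); p_points <- as.matrix(p_points)
  stopifnot(length(id) == nrow(g_points), nrow(g_points) == nrow(p_points),
            ncol(g_points) == 3L, ncol(p_points) == 3L)
  if (anyDuplicated(id)) stop("landmark ids must be unique", call. = FALSE)
  if (!all(is.finite(g_points)) || !all(is.finite(p_points))) {
    stop("landmark coordinates must be finite", call. = FALSE)
  }
  d <- data.frame(id = as.character(id),
                  gx = g_points[, 1], gy = g_points[, 2], gz = g_points[, 3],
                  px = p_points[, 1], py = p_points[, 2], pz = p_points[, 3],
                  stringsAsFactors = FALSE)
  class(d) <- c("landmark_pairs", "data.frame")
  d
}

#' Target registration error at landmark pairs
#'
#' For each landmark, the error is the distance between its model
#' position mapped into P-space by the registration and its measured
#' intraoperative position: `|T g_i - p_i|`, evaluated in P-space.
#'
#' @param pairs a `landmark_pairs` table (>= 1 row).
#' @param T a `rigid_transform` mapping G-space into P-space
#'   (`p_from_g` of a [registration_result]).
#' @param provenance free-text tag recording which sweep the landmarks
#'   came from (`"registration"` or `"navigation"`).
#' @return An object of class `tre_report`: `per_landmark` data.frame
#'   (`id, error_mm, px, py, pz, dist_to_ref_mm` — the latter NA until
#'   [stratify_errors()]), `mean`, `max`, `n`, `provenance`.
#' @export
compute_tre <- function(pairs, T, provenance = "registration") {
  stopifnot(inherits(T, "rigid_transform"))
  if (nrow(pairs) < 1L) stop("need at least one landmark pair", call. = FALSE)
  gp <- as.matrix(pairs[, c("gx", "gy", "gz")])
  pp <- as.matrix(pairs[, c("px", "py", "pz")])
  mapped <- rt_apply(T, gp)
  err <- sqrt(rowSums((mapped - pp)^2))
  per <- data.frame(id = pairs$id, error_mm = err,
                    px = pp[, 1], py = pp[, 2], pz = pp[, 3],
                    dist_to_ref_mm = NA_real_, stringsAsFactors = FALSE)
  structure(list(per_landmark = per, mean = mean(err), max = max(err),
                 n = length(err), provenance = provenance),
            class = "tre_report")
}

#' @export
print.tre_report <- function(x, ...) {
  cat(sprintf("<tre_report> %s: n = %d, mean TRE %.2f mm, max TRE %.2f mm\n",
              x$provenance, x$n, x$mean, x$max))
  invisible(x)
}

#' Distance-stratified error summary
#'
#' For a locally rigid registration, the error is expected to grow with
#' distance from the landmark/region used to register. This computes, in
#' P-space, each landmark's distance to a reference point, the fraction
#' of landmarks within `radius` whose error is at or below `threshold`,
#' and a binned mean-error table for error-versus-distance curves.
#'
#' @param report a `tre_report` from [compute_tre()].
#' @param reference length-3 reference point in P-space (mm), typically
#'   the landmark used to drive the registration.
#' @param radius stratification radius in mm.
#' @param threshold error threshold in mm.
#' @param bin_width distance bin width in mm for the curve table
#'   (default 5).
#' @return List: `fraction` (NA when undefined), `defined` (FALSE when no
#'   landmark lies within `radius`), `n_within`, `n_below`, `table`
#'   (data.frame `bin_lo, bin_hi, n, mean_error_mm`), and the updated
#'   `report` with `dist_to_ref_mm` filled in.
#' @export
stratify_errors <- function(report, reference, radius, threshold,
                            bin_width = 5) {
  stopifnot(inherits(report, "tre_report"), length(reference) == 3L)
  per <- report$per_landmark
  d <- sqrt((per$px - reference[1])^2 + (per$py - reference[2])^2 +
              (per$pz - reference[3])^2)
  per$dist_to_ref_mm <- d
  report$per_landmark <- per
  within <- d <= radius
  defined <- any(within)
  fraction <- if (defined) {
    sum(within & per$error_mm <= threshold) / sum(within)
  } else NA_real_
  lo <- seq(0, max(d) + bin_width, by = bin_width)
  bin <- findInterval(d, lo, rightmost.closed = FALSE)
  tab <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    data.frame(bin_lo = lo[b], bin_hi = lo[b] + bin_width,
               n = sum(bin == b),
               mean_error_mm = mean(per$error_mm[bin == b]))
  }))
  list(fraction = fraction, defined = defined,
       n_within = sum(within),
       n_below = if (defined) sum(within & per$error_mm <= threshold) else 0L,
       table = tab, report = report)
}

#' Navigation error on a held-out sweep
#'
#' Identical computation to [compute_tre()]; the distinction is
#' provenance: the landmarks come from an independent sweep not used to
#' estimate `T`, so the result compounds registration, tracking and
#' probe-pressure errors rather than registration error alone.
#'
#' @param pairs_second_sweep a `landmark_pairs` table from the held-out
#'   sweep.
#' @param T_from_first_sweep `rigid_transform` (G to P) estimated from
#'   the registration sweep.
#' @return A `tre_report` with provenance `"navigation"`.
#' @export
navigation_error <- function(pairs_second_sweep, T_from_first_sweep) {
  compute_tre(pairs_second_sweep, T_from_first_sweep,
              provenance = "navigation")
}
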