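#' Landmark/vector correspondence for initial alignment
#'
#' One manually identified landmark (typically a bifurcation) with two
#' non-parallel unit direction vectors (branch directions), given both on
#' the preoperative centre-line model G and in the intraoperative point
#' cloud P.
#'
#' @param L,L_p length-3 landmark positions in G-space and P-space (mm).
#' @param u,v,u_p,v_p length-3 direction vectors at the landmark in the
#'   respective spaces; normalised internally; the pair in each space must
#'   subtend more than 5 degrees.
#' @return An object of class `landmark_vector_pair`.
#' @export
landmark_vector_pair <- function(L, u, v, L_p, u_p, v_p) {
  unit <- function(x) {
    n <- sqrt(sum(x^2))
    if (n == 0) stop("zero-length direction vector", call. = FALSE)
    x / n
  }
  u <- unit(u); v <- unit(v); u_p <- unit(u_p); v_p <- unit(v_p)
  ang <- function(a, b) acos(min(1, max(-1, sum(a * b)))) * 180 / pi
  if (ang(u, v) <= 5 || ang(u_p, v_p) <= 5) {
    stop("direction vectors are near-parallel (<= 5 degrees): degenerate frame",
         call. = FALSE)
  }
  structure(list(L = as.numeric(L), u = u, v = v,
                 L_p = as.numeric(L_p), u_p = u_p, v_p = v_p),
            class = "landmark_vector_pair")
}

# Right-handed orthonormal frame from two directions: e1 = u, e2 = the
# component of v orthogonal to u (normalised), e3 = e1 x e2.
frame_from_vectors <- function(u, v) {
  e1 <- u / sqrt(sum(u^2))
  w <- v - sum(v * e1) * e1
  e2 <- w / sqrt(sum(w^2))
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  cbind(e1, e2, e3)
}

#' Initial rigid alignment from one landmark and two vectors
#'
#' The rotation is the orthogonal Procrustes solution aligning the
#' orthonormal frame built from `(u, v)` on the model to the frame built
#' from `(u_p, v_p)` in the cloud; the landmark pair then fixes the
#' translation. The result maps G-space into P-space.
#'
#' @param corr a `landmark_vector_pair`.
#' @return A `rigid_transform` mapping G-space to P-space.
#' @export
initial_alignment <- function(corr) {
  stopifnot(inherits(corr, "landmark_vector_pair"))
  eg <- frame_from_vectors(corr$u, corr$v)
  ep <- frame_from_vectors(corr$u_p, corr$v_p)
  r <- ep %*% t(eg)
  rigid_transform(r, corr$L_p - as.numeric(r %*% corr$L))
}

#' ICP settings
#'
#' @param max_iterations maximum number of ICP iterations (default 100).
#' @param rms_change_tol convergence tolerance on the change of the RMS
#'   residual between iterations, in mm (default 1e-4).
#' @param max_correspondence_distance optional outlier gate: points whose
#'   closest-line distance exceeds this (mm) are excluded from the update.
#'   Default `Inf` (no gate).
#' @param seed integer; reserved for subsampling variants, unused by the
#'   default full-cloud update.
#' @return An object of class `icp_params`.
#' @export
icp_params <- function(max_iterations = 100, rms_change_tol = 1e-4,
                       max_correspondence_distance = Inf, seed = NULL) {
  if (max_iterations < 1) stop("max_iterations must be >= 1", call. = FALSE)
  if (rms_change_tol <= 0) stop("rms_change_tol must be > 0", call. = FALSE)
  structure(list(max_iterations = as.integer(max_iterations),
                 rms_change_tol = rms_change_tol,
                 max_correspondence_distance = max_correspondence_distance,
                 seed = seed),
            class = "icp_params")
}

# Closed-form least-squares rigid fit mapping x onto y (Kabsch / SVD of
# the cross-covariance, reflection-safe).
kabsch <- function(x, y) {
  mx <- colMeans(x); my <- colMeans(y)
  h <- crossprod(sweep(x, 2L, mx), sweep(y, 2L, my))
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  r <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rigid_transform(r, my - as.numeric(r %*% mx))
}

#' Point-to-line ICP registration of a cloud to a centre-line graph
#'
#' Refines a rigid registration of the preoperative centre-line graph G
#' to the intraoperative cloud P. Internally the points are mapped into
#' G-space; each iteration finds, for every point, the closest point on
#' the polylines ([closest_point()]), optionally gates distant
#' correspondences, and applies the closed-form SVD rigid update. The
#' loop stops when the RMS residual changes by less than
#' `rms_change_tol` or after `max_iterations`.
#'
#' `mode = "point_to_point"` is a cross-check variant that matches
#' against the graph densely resampled at `resample_spacing` instead of
#' exact segment projections; both modes agree closely on well-sampled
#' data.
#'
#' @param P n x 3 matrix of reconstructed centre points (mm, P-space).
#' @param g a `centreline_graph` (G-space).
#' @param init a `rigid_transform` mapping G-space to P-space, e.g. from
#'   [initial_alignment()]; default identity.
#' @param params an `icp_params`.
#' @param mode correspondence model; `"point_to_line"` (default) or
#'   `"point_to_point"`.
#' @param resample_spacing arc-length step (mm) for the point-to-point
#'   variant.
#' @return An object of class `registration_result`: `g_from_p` and
#'   `p_from_g` (exact inverses), `rms_residual` (mm), `iterations_used`,
#'   `per_iteration_rms`, `n_points_used`.
#' @export
icp_point_to_line <- function(P, g, init = rt_identity(),
                              params = icp_params(),
                              mode = c("point_to_line", "point_to_point"),
                              resample_spacing = 0.5) {
  mode <- match.arg(mode)
  stopifnot(inherits(g, "centreline_graph"), inherits(params, "icp_params"))
  P <- as.matrix(P)
  if (nrow(P) < 3L) {
    stop("need at least 3 points to estimate a rigid transform", call. = FALSE)
  }
  target <- if (mode == "point_to_point") resample_graph(g, resample_spacing)
            else NULL
  corr <- function(q) {
    if (mode == "point_to_line") {
      cp <- closest_point(g, q)
      list(feet = cp$foot, dist = cp$distance)
    } else {
      # nearest resampled vertex
      nn <- apply(q, 1L, function(p) {
        d2 <- colSums((t(target) - p)^2)
        which.min(d2)
      })
      feet <- target[nn, , drop = FALSE]
      list(feet = feet, dist = sqrt(rowSums((q - feet)^2)))
    }
  }
  t_pg <- rt_inverse(init)  # maps P-space points into G-space
  rms_trace <- numeric(0)
  prev_rms <- Inf
  n_used <- nrow(P)
  for (it in seq_len(params$max_iterations)) {
    q <- rt_apply(t_pg, P)
    cc <- corr(q)
    keep <- cc$dist <= params$max_correspondence_distance
    if (sum(keep) < 3L) {
      stop("fewer than 3 points remain after correspondence gating",
           call. = FALSE)
    }
    upd <- kabsch(q[keep, , drop = FALSE], cc$feet[keep, , drop = FALSE])
    t_pg <- rt_compose(upd, t_pg)
    q2 <- rt_apply(t_pg, P)
    cc2 <- corr(q2)
    keep2 <- cc2$dist <= params$max_correspondence_distance
    rms <- sqrt(mean(cc2$dist[keep2]^2))
    n_used <- sum(keep2)
    rms_trace <- c(rms_trace, rms)
    if (abs(prev_rms - rms) < params$rms_change_tol) break
    prev_rms <- rms
  }
  structure(list(g_from_p = t_pg, p_from_g = rt_inverse(t_pg),
                 rms_residual = rms_trace[length(rms_trace)],
                 iterations_used = length(rms_trace),
                 per_iteration_rms = rms_trace,
                 n_points_used = n_used),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf(
    "<registration_result> rms %.4f mm after %d iterations (%d points)\n",
    x$rms_residual, x$iterations_used, x$n_points_used))
  invisible(x)
}

#' RMS residual of a cloud against the centre-line graph
#'
#' Root-mean-square of the closest-centre-line distances after mapping
#' the points into G-space by `T`.
#'
#' @param P n x 3 matrix of points (P-space, mm).
#' @param g a `centreline_graph`.
#' @param T a `rigid_transform` mapping P-space into G-space
#'   (`g_from_p` of a [registration_result]).
#' @return RMS distance in mm.
#' @export
rms_residual <- function(P, g, T) {
  P <- as.matrix(P)
  if (nrow(P) == 0L) stop("empty point cloud", call. = FALSE)
  q <- rt_apply(T, P)
  sqrt(mean(closest_point(g, q)$distance^2))
}
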