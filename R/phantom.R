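# Run code with a private, seeded RNG stream; the caller's RNG state is
# untouched so simulation determinism never leaks into user code.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647))
  code
}

#' Synthetic tube phantom specification
#'
#' Describes a water-filled tube phantom as imaged by B-mode ultrasound:
#' dark (hypoechoic) tubular lumens on a brighter speckled background.
#' Tube diameters should sit in the 3-9 mm range the segmentation is
#' tuned for.
#'
#' @param tubes list of tubes, each `list(points = k x 3 matrix of
#'   centre-line control points (mm), diameter = mm)`.
#' @param background_intensity mean background grayscale (default 120).
#' @param lumen_intensity mean lumen grayscale (default 30); must be
#'   below the background (hypoechoic).
#' @param speckle_sigma grayscale noise scale (default 8): multiplicative
#'   Gaussian speckle on the background, additive Gaussian in the lumen.
#' @param shadow_probability per-frame probability of an acoustic-shadow
#'   artefact band below a tube (default 0).
#' @param seed integer driving all rendering noise.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(tubes, background_intensity = 120,
                         lumen_intensity = 30, speckle_sigma = 8,
                         shadow_probability = 0, seed = 1) {
  stopifnot(is.list(tubes), length(tubes) >= 1L)
  for (tb in tubes) {
    if (is.null(tb$points) || is.null(tb$diameter) || tb$diameter <= 0) {
      stop("each tube needs control points and a positive diameter",
           call. = FALSE)
    }
    if (nrow(tb$points) < 2L) {
      stop("each tube centre line needs >= 2 control points", call. = FALSE)
    }
  }
  if (lumen_intensity >= background_intensity) {
    stop("lumen must be darker than background (hypoechoic)", call. = FALSE)
  }
  if (shadow_probability < 0 || shadow_probability > 1) {
    stop("shadow_probability must lie in [0, 1]", call. = FALSE)
  }
  structure(list(tubes = tubes, background_intensity = background_intensity,
                 lumen_intensity = lumen_intensity,
                 speckle_sigma = speckle_sigma,
                 shadow_probability = shadow_probability,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Built-in phantom presets
#'
#' * `single_tube`: one straight 6.5 mm tube along x at 24 mm depth —
#'   the tube-phantom geometry used for diameter-recovery validation.
#' * `y_branch`: a Y of three 6 mm tubes meeting at one bifurcation.
#' * `multi_tube`: a Y-branching tube pair plus a separate straight tube
#'   (one bifurcation; non-parallel axes make the rigid registration
#'   well-posed).
#' * `liver`: a liver-like tree with a curved trunk and 8 degree-3
#'   bifurcations spanning roughly 100 mm.
#'
#' @param name preset name.
#' @param ... overrides passed on to [phantom_spec()] (intensities,
#'   noise, seed).
#' @return A `phantom_spec`.
#' @export
phantom_preset <- function(name = c("single_tube", "y_branch", "multi_tube",
                                    "liver"), ...) {
  name <- match.arg(name)
  tube <- function(points, diameter) list(points = points, diameter = diameter)
  tubes <- switch(name,
    single_tube = list(
      tube(rbind(c(-10, 24, 24), c(110, 24, 24)), 6.5)),
    y_branch = list(
      tube(rbind(c(0, 0, 0), c(40, 0, 0)), 6),
      tube(rbind(c(40, 0, 0), c(80, 25, 5)), 6),
      tube(rbind(c(40, 0, 0), c(80, -25, -5)), 6)),
    multi_tube = list(
      tube(rbind(c(-10, 20, 22), c(50, 24, 25)), 8),
      tube(rbind(c(50, 24, 25), c(110, 10, 20)), 6.5),
      tube(rbind(c(50, 24, 25), c(110, 38, 30)), 5),
      tube(rbind(c(-10, 45, 38), c(110, 48, 36)), 6)),
    liver = liver_tubes())
  phantom_spec(tubes, ...)
}

# Liver-like tree: curved trunk split at 8 junctions, one side branch per
# junction (8 degree-3 bifurcations), diameters 3-9 mm, ~100 mm extent.
liver_tubes <- function() {
  tube <- function(points, diameter) list(points = points, diameter = diameter)
  jx <- seq(10, 80, by = 10)
  trunk_node <- function(x) c(x, 8 * sin(x / 30), 0.25 * x)
  xs <- c(0, jx, 90)
  tubes <- list()
  for (i in seq_len(length(xs) - 1L)) {
    tubes[[i]] <- tube(rbind(trunk_node(xs[i]), trunk_node(xs[i + 1])), 8)
  }
  dirs <- rbind(c(0.4, 0.8, 0.3), c(0.3, -0.85, 0.2), c(0.5, 0.6, -0.55),
                c(0.2, -0.7, -0.6), c(0.45, 0.75, -0.35), c(0.35, -0.6, 0.65),
                c(0.5, 0.5, 0.65), c(0.3, -0.8, -0.45))
  for (j in seq_along(jx)) {
    d <- dirs[j, ] / sqrt(sum(dirs[j, ]^2))
    start <- trunk_node(jx[j])
    mid <- start + d * 14
    end <- mid + (d + c(0.1, 0, 0.05)) / sqrt(sum((d + c(0.1, 0, 0.05))^2)) * 12
    tubes[[length(tubes) + 1L]] <- tube(rbind(start, mid, end),
                                        3 + (j %% 4) * 1.5)
  }
  tubes
}

#' Build a phantom: ground-truth graph plus tube geometry
#'
#' The ground-truth centre-line graph has exactly the control polylines
#' as edges (shared endpoints merged into shared nodes, so junctions
#' become bifurcation nodes); the imaged geometry is the capsule sweep of
#' each polyline at its radius.
#'
#' @param spec a `phantom_spec`.
#' @return An object of class `vessel_phantom`: list with `graph`
#'   (`centreline_graph`, per-edge radii attached), `tubes`, `spec`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  nodes <- matrix(numeric(0), 0L, 3L)
  edges <- list()
  node_id <- function(p) {
    if (nrow(nodes) > 0L) {
      d2 <- rowSums((nodes - matrix(p, nrow(nodes), 3, byrow = TRUE))^2)
      hit <- which(d2 < 1e-12)
      if (length(hit)) return(hit[1])
    }
    nodes <<- rbind(nodes, p)
    nrow(nodes)
  }
  radii <- list()
  for (i in seq_along(spec$tubes)) {
    tb <- spec$tubes[[i]]
    idx <- vapply(seq_len(nrow(tb$points)), function(k) {
      node_id(as.numeric(tb$points[k, ]))
    }, integer(1))
    edges[[i]] <- idx
    radii[[i]] <- rep(tb$diameter / 2, length(idx))
  }
  structure(list(graph = centreline_graph(nodes, edges, radii),
                 tubes = spec$tubes, spec = spec),
            class = "vessel_phantom")
}

# Squared distance from world points (n x 3) to one polyline.
dist2_to_polyline <- function(pts, poly) {
  best <- rep(Inf, nrow(pts))
  for (s in seq_len(nrow(poly) - 1L)) {
    a <- poly[s, ]; d <- poly[s + 1L, ] - a
    dd <- sum(d^2)
    w <- sweep(pts, 2L, a, "-")
    t_par <- pmin(1, pmax(0, (w %*% d) / dd))
    f <- sweep(t_par %*% matrix(d, 1, 3), 2L, a, "+")
    best <- pmin(best, rowSums((pts - f)^2))
  }
  best
}

#' Transverse probe pose at a sweep position
#'
#' Convenience pose for the built-in presets: the image plane is the
#' world y-z plane at `x = x_mm` (columns along +y, rows along +z, beam
#' pointing down into the phantom, plane normal along +x).
#'
#' @param x_mm sweep position along the world x axis (mm).
#' @return A `rigid_transform` (sensor to tracker).
#' @export
transverse_probe_pose <- function(x_mm) {
  r <- cbind(c(0, 1, 0), c(0, 0, 1), c(1, 0, 0))
  rigid_transform(r, c(x_mm, 0, 0))
}

#' Render one B-mode frame of the phantom
#'
#' Pixels whose world position lies inside any tube take the lumen
#' intensity, all others the background intensity; seeded speckle noise
#' and optional column-aligned shadow bands are then applied. Rendering
#' is deterministic given `(spec$seed, frame_index)`. A plane that misses
#' the phantom produces a valid all-background frame.
#'
#' @param phantom a `vessel_phantom`.
#' @param pose `rigid_transform`, sensor to tracker.
#' @param calib a `calibration_spec`.
#' @param frame_size `c(width, height)` in pixels (default 640 x 480).
#' @param frame_index integer used with the phantom seed to key the noise.
#' @return Numeric matrix `[row, col]` with intensities in 0..255.
#' @export
render_frame <- function(phantom, pose, calib, frame_size = c(640, 480),
                         frame_index = 0) {
  stopifnot(inherits(phantom, "vessel_phantom"))
  spec <- phantom$spec
  w <- frame_size[1]; h <- frame_size[2]
  tc <- rt_compose(pose, calib$image_to_sensor)
  cols <- rep(0:(w - 1L), each = h)
  rows <- rep(0:(h - 1L), times = w)
  pts <- cbind(cols * calib$pixel_scale[1], rows * calib$pixel_scale[2], 0)
  world <- rt_apply(tc, pts)
  lumen <- rep(FALSE, nrow(world))
  for (tb in phantom$tubes) {
    r2 <- (tb$diameter / 2)^2
    lumen <- lumen | (dist2_to_polyline(world, tb$points) <= r2)
  }
  lumen_m <- matrix(lumen, h, w)
  img <- with_seed(spec$seed * 100003 + frame_index * 7919, {
    img <- matrix(spec$background_intensity, h, w)
    img <- img * (1 + matrix(stats::rnorm(h * w, 0,
                                          spec$speckle_sigma /
                                            spec$background_intensity), h, w))
    lum <- spec$lumen_intensity +
      stats::rnorm(sum(lumen_m), 0, spec$speckle_sigma)
    img[lumen_m] <- lum
    if (spec$shadow_probability > 0 &&
        stats::runif(1) < spec$shadow_probability && any(lumen_m)) {
      cc <- which(colSums(lumen_m) > 0)
      c0 <- sample(cc, 1)
      half <- max(5L, as.integer(stats::runif(1, 10, 40)))
      band <- max(1L, c0 - half):min(w, c0 + half)
      r0 <- max(which(lumen_m[, c0]))
      if (r0 < h) {
        img[(r0 + 1L):h, band] <- img[(r0 + 1L):h, band] * 0.45
      }
    }
    img
  })
  pmin(pmax(img, 0), 255)
}

#' Tracked-sweep specification
#'
#' Describes a freehand sweep: a pose path interpolated from start to
#' end with per-frame jitter emulating jerky freehand probe motion.
#'
#' @param n_frames number of frames (>= 1).
#' @param start_pose,end_pose `rigid_transform`s; intermediate poses
#'   interpolate translation linearly and rotation geodesically.
#' @param jitter_translation_mm per-frame translation jitter sigma (mm).
#' @param jitter_rotation_deg per-frame rotation jitter sigma (degrees).
#' @param frame_size `c(width, height)` pixels.
#' @param calib a `calibration_spec`.
#' @param fps frame rate used for timestamps (default 25).
#' @param seed integer driving the pose jitter.
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(n_frames, start_pose, end_pose,
                       jitter_translation_mm = 0.3,
                       jitter_rotation_deg = 0.3,
                       frame_size = c(640, 480),
                       calib = calibration_spec(), fps = 25, seed = 1) {
  stopifnot(n_frames >= 1, inherits(start_pose, "rigid_transform"),
            inherits(end_pose, "rigid_transform"),
            inherits(calib, "calibration_spec"))
  structure(list(n_frames = as.integer(n_frames), start_pose = start_pose,
                 end_pose = end_pose,
                 jitter_translation_mm = jitter_translation_mm,
                 jitter_rotation_deg = jitter_rotation_deg,
                 frame_size = frame_size, calib = calib, fps = fps,
                 seed = as.integer(seed)),
            class = "sweep_spec")
}

# Geodesic interpolation between two rotations.
slerp_rotation <- function(ra, rb, f) {
  rel <- t(ra) %*% rb
  ang <- rotation_angle(rel)
  if (ang < 1e-12) return(ra)
  # rotation axis from the skew-symmetric part
  ax <- c(rel[3, 2] - rel[2, 3], rel[1, 3] - rel[3, 1], rel[2, 1] - rel[1, 2])
  if (sqrt(sum(ax^2)) < 1e-12) ax <- c(1, 0, 0)  # 180-degree edge case
  ra %*% axis_angle_rotation(ax, f * ang)
}

#' Simulate a tracked freehand sweep over a phantom
#'
#' Renders every frame with [render_frame()] and records, per frame, the
#' exact pose and the ground truth: the true 2D pixel centre and true 3D
#' position of every centre-line/plane intersection visible in the frame.
#'
#' @param phantom a `vessel_phantom`.
#' @param sweep a `sweep_spec`.
#' @return List: `frames` (list of image matrices), `poses` (exact, with
#'   jitter), `timestamps`, `truth` (data.frame `frame, edge, column,
#'   row, x, y, z`), `calib`.
#' @export
simulate_sweep <- function(phantom, sweep) {
  stopifnot(inherits(phantom, "vessel_phantom"), inherits(sweep, "sweep_spec"))
  n <- sweep$n_frames
  fracs <- if (n == 1L) 0 else (seq_len(n) - 1) / (n - 1)
  poses <- with_seed(sweep$seed, {
    lapply(fracs, function(f) {
      r <- slerp_rotation(sweep$start_pose$rotation, sweep$end_pose$rotation, f)
      tr <- (1 - f) * sweep$start_pose$translation +
        f * sweep$end_pose$translation
      if (sweep$jitter_translation_mm > 0) {
        tr <- tr + stats::rnorm(3, 0, sweep$jitter_translation_mm)
      }
      if (sweep$jitter_rotation_deg > 0) {
        ax <- stats::rnorm(3)
        r <- r %*% axis_angle_rotation(ax, stats::rnorm(1, 0,
                                                        sweep$jitter_rotation_deg))
      }
      rigid_transform(r, tr)
    })
  })
  frames <- vector("list", n)
  truth <- list()
  for (i in seq_len(n)) {
    frames[[i]] <- render_frame(phantom, poses[[i]], sweep$calib,
                                sweep$frame_size, frame_index = i)
    ti <- frame_truth(phantom, poses[[i]], sweep$calib, sweep$frame_size)
    if (nrow(ti)) {
      ti$frame <- i
      truth[[length(truth) + 1L]] <- ti
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(edge = integer(0), column = numeric(0), row = numeric(0),
               x = numeric(0), y = numeric(0), z = numeric(0),
               frame = integer(0))
  list(frames = frames, poses = poses,
       timestamps = (seq_len(n) - 1) / sweep$fps,
       truth = truth[, c("frame", "edge", "column", "row", "x", "y", "z")],
       calib = sweep$calib)
}

# Exact plane/centre-line intersections of one frame.
frame_truth <- function(phantom, pose, calib, frame_size) {
  tc <- rt_compose(pose, calib$image_to_sensor)
  n <- tc$rotation[, 3]   # plane normal in world
  origin <- tc$translation
  out <- list()
  g <- phantom$graph
  for (e in seq_along(g$edges)) {
    idx <- g$edges[[e]]
    for (s in seq_len(length(idx) - 1L)) {
      a <- g$nodes[idx[s], ]; b <- g$nodes[idx[s + 1L], ]
      den <- sum(n * (b - a))
      if (abs(den) < 1e-9) next
      t_par <- sum(n * (origin - a)) / den
      if (t_par < 0 || t_par > 1) next
      x <- a + t_par * (b - a)
      local <- as.numeric(t(tc$rotation) %*% (x - origin))
      col <- local[1] / calib$pixel_scale[1]
      row <- local[2] / calib$pixel_scale[2]
      if (col < 0 || col > frame_size[1] - 1 ||
          row < 0 || row > frame_size[2] - 1) next
      out[[length(out) + 1L]] <- data.frame(edge = e, column = col, row = row,
                                            x = x[1], y = x[2], z = x[3])
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(edge = integer(0), column = numeric(0), row = numeric(0),
               x = numeric(0), y = numeric(0), z = numeric(0))
}

#' Rigid + smooth deformation of a centre-line graph
#'
#' Applies a rigid transform followed by a seeded smooth low-frequency
#' displacement field — the sum of a few random 3D cosine modes with
#' wavelengths at or above `smooth_scale` and total peak amplitude
#' `smooth_amplitude`. Emulates a soft-tissue shape change (e.g. the
#' insufflated versus non-insufflated mismatch) without a mechanical
#' model.
#'
#' @param g a `centreline_graph`.
#' @param rigid a `rigid_transform` (applied first).
#' @param smooth_amplitude peak displacement magnitude in mm (0 = rigid
#'   only).
#' @param smooth_scale minimum wavelength of the modes in mm.
#' @param seed integer; identical seeds give identical deformations.
#' @return The deformed `centreline_graph`.
#' @export
perturb_model <- function(g, rigid = rt_identity(), smooth_amplitude = 0,
                          smooth_scale = 80, seed = 1) {
  stopifnot(inherits(g, "centreline_graph"), inherits(rigid, "rigid_transform"))
  if (smooth_amplitude > 0 && smooth_scale <= 0) {
    stop("smooth_scale must be > 0 when smooth_amplitude > 0", call. = FALSE)
  }
  nodes <- rt_apply(rigid, g$nodes)
  if (smooth_amplitude > 0) {
    k <- 4L
    nodes <- with_seed(seed, {
      amps <- abs(stats::rnorm(k)); amps <- amps / sum(amps) * smooth_amplitude
      disp <- matrix(0, nrow(nodes), 3)
      for (j in seq_len(k)) {
        dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
        mode_dir <- stats::rnorm(3)
        mode_dir <- mode_dir / sqrt(sum(mode_dir^2))
        lambda <- smooth_scale * stats::runif(1, 1, 2)
        phase <- stats::runif(1, 0, 2 * pi)
        phase_arg <- 2 * pi * (nodes %*% dir) / lambda + phase
        disp <- disp + as.numeric(cos(phase_arg)) %*%
          matrix(mode_dir * amps[j], 1, 3)
      }
      nodes + disp
    })
  }
  centreline_graph(nodes, g$edges, g$radii, g$labels)
}
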