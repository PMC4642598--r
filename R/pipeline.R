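#' Validate a pipeline configuration
#'
#' Configurations are nested lists (usually read from YAML). Validation
#' is strict: unknown keys are rejected, required blocks and types are
#' checked, and defaults are filled in for omitted parameters.
#'
#' @param config nested list, or path to a YAML file.
#' @return The validated config with defaults filled in.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known_top <- c("version", "seed", "simulate", "inputs", "vesselness", "dip",
                 "segmentation", "registration", "evaluation")
  unknown <- setdiff(names(config), known_top)
  if (length(unknown)) {
    stop(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  if (is.null(config$version) || config$version != 1) {
    stop("config must declare 'version: 1'", call. = FALSE)
  }
  if (is.null(config$seed)) config$seed <- 1L
  check_block <- function(block, allowed, name) {
    bad <- setdiff(names(block), allowed)
    if (length(bad)) {
      stop(sprintf("unknown keys in '%s': %s", name,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    block
  }
  if (!is.null(config$simulate)) {
    config$simulate <- check_block(config$simulate,
      c("preset", "n_frames", "sweep_start_x", "sweep_end_x", "frame_width",
        "frame_height", "pixel_scale", "jitter_translation_mm",
        "jitter_rotation_deg", "speckle_sigma", "shadow_probability",
        "misalignment", "centre_jitter_mm"), "simulate")
    s <- config$simulate
    defaults <- list(preset = "multi_tube", n_frames = 40, sweep_start_x = 5,
                     sweep_end_x = 95, frame_width = 640, frame_height = 480,
                     pixel_scale = c(0.1, 0.1), jitter_translation_mm = 0.3,
                     jitter_rotation_deg = 0.3, speckle_sigma = 8,
                     shadow_probability = 0, centre_jitter_mm = 0)
    for (k in names(defaults)) if (is.null(s[[k]])) s[[k]] <- defaults[[k]]
    if (!is.null(s$misalignment)) {
      check_block(s$misalignment,
                  c("translation", "rotation_axis", "rotation_deg"),
                  "simulate.misalignment")
    }
    config$simulate <- s
  }
  if (!is.null(config$inputs)) {
    config$inputs <- check_block(config$inputs,
      c("frames_dir", "tracking_csv", "pixel_scale", "image_to_sensor",
        "graph", "landmark_correspondence"), "inputs")
  }
  if (is.null(config$simulate) && is.null(config$inputs)) {
    stop("config needs either a 'simulate' or an 'inputs' block",
         call. = FALSE)
  }
  config$vesselness <- check_block(config$vesselness,
                                   c("beta", "c_sensitivity", "scales"),
                                   "vesselness")
  config$dip <- check_block(config$dip,
                            c("v_min", "v_max", "pyramid_levels",
                              "blur_sigma", "stride"), "dip")
  config$segmentation <- check_block(config$segmentation,
    c("T_e", "T_d_fraction", "intensity_prior", "min_axis_ratio",
      "min_contour_pixels"), "segmentation")
  config$registration <- check_block(config$registration,
    c("mode", "max_iterations", "rms_change_tol",
      "max_correspondence_distance"), "registration")
  if (is.null(config$registration$mode)) config$registration$mode <- "landmark_icp"
  if (!config$registration$mode %in% c("landmark_icp", "landmark_only",
                                       "icp_only")) {
    stop("registration.mode must be landmark_icp, landmark_only or icp_only",
         call. = FALSE)
  }
  config$evaluation <- check_block(config$evaluation,
                                   c("radius", "threshold", "bin_width"),
                                   "evaluation")
  config
}

config_params <- function(config) {
  v <- config$vesselness
  d <- config$dip
  s <- config$segmentation
  r <- config$registration
  dp <- do.call(dip_params, d[!vapply(d, is.null, logical(1))])
  vp <- do.call(vesselness_params, v[!vapply(v, is.null, logical(1))])
  sp_args <- s[!vapply(s, is.null, logical(1))]
  sp_args$v_min <- dp$v_min
  sp_args$v_max <- dp$v_max
  sp <- do.call(segmentation_params, sp_args)
  ip_args <- r[!vapply(r, is.null, logical(1))]
  ip_args$mode <- NULL
  ip <- do.call(icp_params, ip_args)
  list(vparams = vp, dparams = dp, sparams = sp, icp = ip,
       mode = r$mode %||% "landmark_icp")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Landmark/vector correspondence from a graph bifurcation: the landmark
# is the highest-degree bifurcation, the vectors the directions of two
# incident polylines.
bifurcation_correspondence <- function(g_model, g_truth_world) {
  bf_m <- bifurcations(g_model)
  bf_w <- bifurcations(g_truth_world)
  if (nrow(bf_m) == 0L || nrow(bf_w) == 0L) {
    stop("landmark initialisation needs a bifurcation in both models",
         call. = FALSE)
  }
  branch_dirs <- function(g, at) {
    dirs <- list()
    for (e in g$edges) {
      p1 <- g$nodes[e[1], ]; p2 <- g$nodes[e[length(e)], ]
      if (sum((p1 - at)^2) < 0.1^2) {
        d <- g$nodes[e[2], ] - p1
      } else if (sum((p2 - at)^2) < 0.1^2) {
        d <- g$nodes[e[length(e) - 1L], ] - p2
      } else next
      dirs[[length(dirs) + 1L]] <- d / sqrt(sum(d^2))
    }
    dirs
  }
  lm <- as.numeric(bf_m[1, c("x", "y", "z")])
  lw <- as.numeric(bf_w[1, c("x", "y", "z")])
  dm <- branch_dirs(g_model, lm)
  dw <- branch_dirs(g_truth_world, lw)
  if (length(dm) < 2L || length(dw) < 2L) {
    stop("bifurcation has fewer than two resolvable branch directions",
         call. = FALSE)
  }
  landmark_vector_pair(lm, dm[[1]], dm[[2]], lw, dw[[1]], dw[[2]])
}

#' Run the full registration pipeline
#'
#' Executes the configured chain — simulate (optional), segment,
#' reconstruct, register (landmark-only, ICP-only, or landmark + ICP) and
#' evaluate — and writes per-stage artefacts, a JSON provenance record
#' and a human-readable report into `output_dir`.
#'
#' @param config nested list or YAML path (see [validate_config()]).
#' @param output_dir directory for artefacts; created if missing.
#' @param seed optional integer overriding `config$seed`.
#' @return Invisibly, a list with the registration result, TRE report
#'   (when ground truth is available), timing, and artefact paths.
#' @export
run_pipeline <- function(config, output_dir = tempfile("vesselreg_run_"),
                         seed = NULL) {
  config <- validate_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  pars <- config_params(config)
  timing <- c()
  tick <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- force(expr)
    timing[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    r
  }
  report <- list(seed = config$seed)

  if (!is.null(config$simulate)) {
    s <- config$simulate
    sim <- tick("simulate", {
      phantom <- make_phantom(phantom_preset(
        s$preset, speckle_sigma = s$speckle_sigma,
        shadow_probability = s$shadow_probability, seed = config$seed))
      calib <- calibration_spec(s$pixel_scale)
      sw <- sweep_spec(s$n_frames,
                       transverse_probe_pose(s$sweep_start_x),
                       transverse_probe_pose(s$sweep_end_x),
                       jitter_translation_mm = s$jitter_translation_mm,
                       jitter_rotation_deg = s$jitter_rotation_deg,
                       frame_size = c(s$frame_width, s$frame_height),
                       calib = calib, seed = config$seed + 1L)
      c(simulate_sweep(phantom, sw), list(phantom = phantom))
    })
    frames <- sim$frames
    poses <- sim$poses
    calib <- sim$calib
    truth_graph <- sim$phantom$graph
    mis <- s$misalignment
    model_graph <- if (!is.null(mis)) {
      transform_graph(truth_graph, rigid_transform(
        axis_angle_rotation(unlist(mis$rotation_axis), mis$rotation_deg),
        unlist(mis$translation)))
    } else truth_graph
    save_graph(model_graph, file.path(output_dir, "model_graph.json"))
  } else {
    inp <- config$inputs
    frames_paths <- sort(list.files(inp$frames_dir, pattern = "\\.png$",
                                    full.names = TRUE))
    frames <- lapply(frames_paths, read_frame_png)
    tracking <- read_tracking_csv(inp$tracking_csv)
    poses <- nearest_poses(seq_along(frames) / 25, tracking)
    calib <- calibration_spec(unlist(inp$pixel_scale),
                              read_transform(inp$image_to_sensor))
    model_graph <- load_graph(inp$graph)
    truth_graph <- NULL
  }

  seg <- tick("segment", lapply(frames, function(f) {
    segment_frame(f, pars$sparams, pars$vparams, pars$dparams)
  }))
  centres <- lapply(seg, function(x) x$centres)
  recon <- tick("reconstruct", reconstruct_centres(centres, calib, poses))
  cloud <- recon$points
  if (!is.null(config$simulate) && config$simulate$centre_jitter_mm > 0) {
    cloud <- with_seed(config$seed + 2L, {
      cloud + matrix(stats::rnorm(length(cloud), 0,
                                  config$simulate$centre_jitter_mm),
                     nrow(cloud), 3)
    })
  }
  write_cloud_csv(cloud, file.path(output_dir, "cloud.csv"))
  report$n_frames <- length(frames)
  report$n_centres <- nrow(cloud)

  reg <- tick("register", {
    init <- rt_identity()
    if (pars$mode %in% c("landmark_icp", "landmark_only")) {
      corr <- if (!is.null(truth_graph)) {
        bifurcation_correspondence(model_graph, truth_graph)
      } else {
        read_landmark_correspondence(config$inputs$landmark_correspondence)
      }
      init <- initial_alignment(corr)
    }
    if (pars$mode == "landmark_only") {
      list(g_from_p = rt_inverse(init), p_from_g = init,
           rms_residual = rms_residual(cloud, model_graph, rt_inverse(init)),
           iterations_used = 0L, per_iteration_rms = numeric(0),
           n_points_used = nrow(cloud), icp_skipped = TRUE)
    } else {
      r <- icp_point_to_line(cloud, model_graph, init = init,
                             params = pars$icp)
      r$icp_skipped <- FALSE
      r
    }
  })
  write_transform(reg$g_from_p, file.path(output_dir, "g_from_p.txt"))
  write_transform(reg$p_from_g, file.path(output_dir, "p_from_g.txt"))
  report$registration <- list(rms_residual_mm = reg$rms_residual,
                              iterations = reg$iterations_used,
                              n_points = reg$n_points_used,
                              icp_skipped = isTRUE(reg$icp_skipped),
                              mode = pars$mode)

  if (!is.null(truth_graph)) {
    ev <- tick("evaluate", {
      pairs <- landmark_pairs(sprintf("n%03d", seq_len(nrow(model_graph$nodes))),
                              model_graph$nodes, truth_graph$nodes)
      tre <- compute_tre(pairs, reg$p_from_g)
      e <- config$evaluation
      bf <- bifurcations(truth_graph)
      strat <- if (nrow(bf) > 0) {
        stratify_errors(tre, as.numeric(bf[1, c("x", "y", "z")]),
                        radius = e$radius %||% 35,
                        threshold = e$threshold %||% 10,
                        bin_width = e$bin_width %||% 5)
      } else NULL
      list(tre = tre, strat = strat)
    })
    report$evaluation <- list(mean_tre_mm = ev$tre$mean,
                              max_tre_mm = ev$tre$max, n_landmarks = ev$tre$n)
    if (!is.null(ev$strat)) {
      report$evaluation$fraction_within <- ev$strat$fraction
    }
  } else ev <- NULL

  report$timing_s <- as.list(timing)
  cfg_path <- file.path(output_dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  provenance <- list(config_md5 = unname(tools::md5sum(cfg_path)),
                     seed = config$seed,
                     package_version = as.character(utils::packageVersion("vesselreg")),
                     r_version = R.version.string)
  jsonlite::write_json(provenance, file.path(output_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  jsonlite::write_json(report, file.path(output_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(c(
    sprintf("vesselreg pipeline report (seed %d)", config$seed),
    sprintf("frames processed : %d", report$n_frames),
    sprintf("centres accepted : %d", report$n_centres),
    sprintf("registration rms : %.3f mm (%s, %d iterations)",
            reg$rms_residual, pars$mode, reg$iterations_used),
    if (!is.null(ev)) sprintf("mean / max TRE   : %.3f / %.3f mm",
                              ev$tre$mean, ev$tre$max) else character(0)),
    file.path(output_dir, "report.txt"))
  invisible(list(registration = reg, evaluation = ev, report = report,
                 output_dir = output_dir))
}

#' Read a landmark/vector correspondence CSV
#'
#' Expected columns: `space` (`g` or `p`), `kind` (`L`, `u`, `v`), `x, y,
#' z`. `L` rows are positions (mm); `u`/`v` rows are direction vectors.
#'
#' @param path CSV path.
#' @return A `landmark_vector_pair`.
#' @export
read_landmark_correspondence <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- function(space, kind) {
    r <- d[d$space == space & d$kind == kind, c("x", "y", "z")]
    if (nrow(r) != 1L) {
      stop(sprintf("correspondence CSV needs one row space=%s kind=%s",
                   space, kind), call. = FALSE)
    }
    as.numeric(r)
  }
  landmark_vector_pair(need("g", "L"), need("g", "u"), need("g", "v"),
                       need("p", "L"), need("p", "u"), need("p", "v"))
}
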