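#' Read and write 4x4 transform text files
#'
#' Transforms are exchanged as 16 whitespace-separated numbers, the 4x4
#' homogeneous matrix in row-major order — the layout used by tracking
#' logs and registration tools.
#'
#' @param path file path.
#' @return `read_transform`: a `rigid_transform`.
#' @export
read_transform <- function(path) {
  vals <- scan(path, what = numeric(), quiet = TRUE)
  if (length(vals) != 16L) {
    stop(sprintf("expected 16 numbers in '%s', found %d", path, length(vals)),
         call. = FALSE)
  }
  rt_from_matrix(matrix(vals, 4, 4, byrow = TRUE))
}

#' @rdname read_transform
#' @param t a `rigid_transform` to write.
#' @export
write_transform <- function(t, path) {
  m <- rt_to_matrix(t)
  lines <- apply(m, 1L, function(r) paste(formatC(r, format = "g", digits = 17),
                                          collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write tracking logs
#'
#' A tracking log is a CSV with columns `timestamp_s, m00..m23`: the first
#' three rows of each pose's 4x4 matrix (sensor to tracker), row-major.
#'
#' @param path file path.
#' @return `read_tracking_csv`: list with `timestamps` (numeric) and
#'   `poses` (list of `rigid_transform`).
#' @export
read_tracking_csv <- function(path) {
  d <- utils::read.csv(path)
  want <- c("timestamp_s",
            paste0("m", as.vector(outer(0:2, 0:3, paste0))))
  if (!all(want %in% names(d))) {
    stop("tracking CSV must have columns timestamp_s, m00..m23", call. = FALSE)
  }
  poses <- lapply(seq_len(nrow(d)), function(i) {
    m <- diag(4)
    for (r in 0:2) for (c in 0:3) {
      m[r + 1, c + 1] <- d[[paste0("m", r, c)]][i]
    }
    rt_from_matrix(m)
  })
  list(timestamps = d$timestamp_s, poses = poses)
}

#' @rdname read_tracking_csv
#' @param poses list of `rigid_transform` (sensor to tracker).
#' @param timestamps numeric vector of acquisition times in seconds.
#' @export
write_tracking_csv <- function(poses, timestamps, path) {
  stopifnot(length(poses) == length(timestamps))
  rows <- t(vapply(poses, function(p) {
    m <- rt_to_matrix(p)
    as.vector(t(m[1:3, ]))
  }, numeric(12)))
  d <- data.frame(timestamp_s = timestamps)
  cn <- paste0("m", as.vector(t(outer(0:2, 0:3, paste0))))
  for (j in seq_along(cn)) d[[cn[j]]] <- rows[, j]
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Pick the tracked pose nearest in time to each frame
#'
#' No interpolation is performed: each frame gets the pose whose timestamp
#' is closest (ties resolve to the earlier pose). Interpolation is a
#' documented extension point.
#'
#' @param frame_times numeric vector of frame timestamps (s).
#' @param tracking list as returned by [read_tracking_csv()].
#' @return List of `rigid_transform`, one per frame.
#' @export
nearest_poses <- function(frame_times, tracking) {
  idx <- vapply(frame_times, function(t) {
    which.min(abs(tracking$timestamps - t))
  }, integer(1))
  tracking$poses[idx]
}

#' Read/write grayscale frames as PNG
#'
#' Frames are numeric matrices `[row, col]` with intensities in 0..255.
#'
#' @param path PNG file path.
#' @return `read_frame_png`: numeric matrix in 0..255.
#' @export
read_frame_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  a * 255
}

#' @rdname read_frame_png
#' @param image numeric matrix `[row, col]`, values in 0..255.
#' @export
write_frame_png <- function(image, path) {
  png::writePNG(pmin(pmax(image / 255, 0), 1), path)
  invisible(path)
}

#' Read/write landmark CSV files
#'
#' Landmark files carry one row per landmark: `id, x, y, z` (mm) and an
#' optional `label` column.
#'
#' @param path CSV path.
#' @return `read_landmarks_csv`: data.frame with columns id, x, y, z
#'   (and label if present).
#' @export
read_landmarks_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("id", "x", "y", "z") %in% names(d))) {
    stop("landmark CSV must have columns id, x, y, z", call. = FALSE)
  }
  d
}

#' @rdname read_landmarks_csv
#' @param landmarks data.frame with columns id, x, y, z (label optional).
#' @export
write_landmarks_csv <- function(landmarks, path) {
  utils::write.csv(landmarks, path, row.names = FALSE)
  invisible(path)
}

#' Write a 3D point cloud as CSV
#' @param points n x 3 matrix (mm).
#' @param path output CSV path.
#' @export
write_cloud_csv <- function(points, path) {
  d <- as.data.frame(points)
  names(d) <- c("x", "y", "z")
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cloud_csv
#' @export
read_cloud_csv <- function(path) {
  d <- utils::read.csv(path)
  as.matrix(d[, c("x", "y", "z")])
}
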