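#' Preoperative vessel centre-line graph
#'
#' A centre-line graph holds the polyline skeleton of a vascular tree:
#' a node table (3D points, mm) and edges, each an ordered index vector
#' into the node table describing one polyline, with optional per-point
#' radii (mm) and a per-edge vessel label.
#'
#' @param nodes n x 3 numeric matrix of node coordinates (mm).
#' @param edges list of integer vectors (1-based node indices), each of
#'   length >= 2 with no zero-length segments.
#' @param radii optional list parallel to `edges`, per-point radii in mm.
#' @param labels optional character vector, one label per edge.
#' @return An object of class `centreline_graph`.
#' @export
centreline_graph <- function(nodes, edges, radii = NULL, labels = NULL) {
  nodes <- as.matrix(nodes)
  if (ncol(nodes) != 3L || !all(is.finite(nodes))) {
    stop("nodes must be a finite n x 3 matrix", call. = FALSE)
  }
  if (!is.list(edges) || length(edges) == 0L) {
    stop("edges must be a non-empty list of index vectors", call. = FALSE)
  }
  edges <- lapply(edges, as.integer)
  for (i in seq_along(edges)) {
    e <- edges[[i]]
    if (length(e) < 2L) stop("every polyline needs >= 2 points", call. = FALSE)
    if (any(e < 1L | e > nrow(nodes))) {
      stop(sprintf("edge %d has node indices out of range", i), call. = FALSE)
    }
    seg <- nodes[e[-1], , drop = FALSE] - nodes[e[-length(e)], , drop = FALSE]
    if (any(rowSums(seg^2) == 0)) {
      stop(sprintf("edge %d contains a zero-length segment", i), call. = FALSE)
    }
  }
  if (!is.null(radii)) {
    stopifnot(length(radii) == length(edges))
    radii <- lapply(radii, as.numeric)
  }
  if (!is.null(labels)) stopifnot(length(labels) == length(edges))
  structure(list(nodes = nodes, edges = edges, radii = radii, labels = labels),
            class = "centreline_graph")
}

#' @export
print.centreline_graph <- function(x, ...) {
  cat(sprintf("<centreline_graph> %d nodes, %d polylines, %d bifurcations\n",
              nrow(x$nodes), length(x$edges), nrow(bifurcations(x))))
  invisible(x)
}

#' Apply a rigid transform to a graph's nodes
#' @param g a `centreline_graph`.
#' @param t a `rigid_transform`.
#' @return The transformed graph.
#' @export
transform_graph <- function(g, t) {
  stopifnot(inherits(g, "centreline_graph"))
  centreline_graph(rt_apply(t, g$nodes), g$edges, g$radii, g$labels)
}

# All polyline segments as a flat table: start/end coordinates plus
# (edge, segment) ids. Cached computation used by the closest-point query.
graph_segments <- function(g) {
  segs <- lapply(seq_along(g$edges), function(i) {
    e <- g$edges[[i]]
    cbind(edge = i, segment = seq_len(length(e) - 1L),
          g$nodes[e[-length(e)], , drop = FALSE],
          g$nodes[e[-1], , drop = FALSE])
  })
  m <- do.call(rbind, segs)
  colnames(m) <- c("edge", "segment", "ax", "ay", "az", "bx", "by", "bz")
  m
}

#' Bifurcations of a centre-line graph
#'
#' A bifurcation is a junction where at least three polyline endpoints
#' coincide within `merge_tol`. Endpoint positions are clustered with
#' single-linkage at that tolerance (centre-line extractors may duplicate
#' junction points), and each cluster with >= 3 incident endpoints is
#' reported once.
#'
#' @param g a `centreline_graph`.
#' @param merge_tol endpoint coincidence tolerance in mm (default 0.1,
#'   far below vessel radii).
#' @return data.frame with columns `x, y, z, degree` (one row per
#'   bifurcation), ordered by decreasing degree then x.
#' @export
bifurcations <- function(g, merge_tol = 0.1) {
  stopifnot(inherits(g, "centreline_graph"))
  ends <- do.call(rbind, lapply(g$edges, function(e) {
    g$nodes[c(e[1], e[length(e)]), , drop = FALSE]
  }))
  n <- nrow(ends)
  cluster <- integer(n)
  k <- 0L
  for (i in seq_len(n)) {
    if (cluster[i] > 0L) next
    k <- k + 1L
    # single-linkage flood from i
    member <- rep(FALSE, n)
    frontier <- i
    member[i] <- TRUE
    while (length(frontier)) {
      d2 <- rowSums((ends - matrix(ends[frontier[1], ], n, 3,
                                   byrow = TRUE))^2)
      new <- which(d2 <= merge_tol^2 & !member)
      member[new] <- TRUE
      frontier <- c(frontier[-1], new)
    }
    cluster[member] <- k
  }
  out <- do.call(rbind, lapply(seq_len(k), function(j) {
    idx <- which(cluster == j)
    if (length(idx) < 3L) return(NULL)
    data.frame(x = mean(ends[idx, 1]), y = mean(ends[idx, 2]),
               z = mean(ends[idx, 3]), degree = length(idx))
  }))
  if (is.null(out)) {
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      degree = integer(0)))
  }
  out[order(-out$degree, out$x), , drop = FALSE]
}

#' Closest point on the centre-line graph
#'
#' Exact nearest point over the union of all polyline segments, with the
#' projection clamped to segment ends. Ties resolve to the lowest
#' `(edge, segment)` pair so results are deterministic.
#'
#' @param g a `centreline_graph`.
#' @param p length-3 point or n x 3 matrix (mm).
#' @return For a single point: list with `foot` (length-3), `distance`
#'   (mm), `edge`, `segment`. For a matrix: list of vectors/matrix `foot`
#'   (n x 3), `distance`, `edge`, `segment` (each length n).
#' @export
closest_point <- function(g, p) {
  stopifnot(inherits(g, "centreline_graph"))
  segs <- graph_segments(g)
  single <- is.null(dim(p))
  pts <- if (single) matrix(as.numeric(p), 1L, 3L) else as.matrix(p)
  a <- segs[, c("ax", "ay", "az"), drop = FALSE]
  d <- segs[, c("bx", "by", "bz"), drop = FALSE] - a
  dd <- rowSums(d^2)
  n <- nrow(pts); m <- nrow(segs)
  foot <- matrix(NA_real_, n, 3)
  dist <- numeric(n); edge <- integer(n); segm <- integer(n)
  # loop over segments, vectorised over points (few segments, many points)
  best <- rep(Inf, n)
  for (j in seq_len(m)) {
    w <- sweep(pts, 2L, a[j, ], "-")
    t_par <- pmin(1, pmax(0, (w %*% d[j, ]) / dd[j]))
    f <- sweep(t_par %*% matrix(d[j, ], 1, 3), 2L, a[j, ], "+")
    d2 <- rowSums((pts - f)^2)
    upd <- d2 < best  # strict improvement keeps lowest (edge, segment) on ties
    if (any(upd)) {
      best[upd] <- d2[upd]
      foot[upd, ] <- f[upd, , drop = FALSE]
      edge[upd] <- segs[j, "edge"]
      segm[upd] <- segs[j, "segment"]
    }
  }
  dist <- sqrt(best)
  if (single) {
    list(foot = as.numeric(foot[1, ]), distance = dist[1],
         edge = edge[1], segment = segm[1])
  } else {
    list(foot = foot, distance = dist, edge = edge, segment = segm)
  }
}

#' Resample all polylines at a fixed spacing
#'
#' Used by the point-to-point registration cross-check mode and by
#' brute-force test oracles.
#'
#' @param g a `centreline_graph`.
#' @param spacing arc-length step in mm.
#' @return n x 3 matrix of points along the polylines (vertices included).
#' @export
resample_graph <- function(g, spacing) {
  stopifnot(inherits(g, "centreline_graph"), spacing > 0)
  out <- lapply(g$edges, function(e) {
    pts <- g$nodes[e, , drop = FALSE]
    seg <- diff(pts)
    len <- sqrt(rowSums(seg^2))
    s <- c(0, cumsum(len))
    total <- s[length(s)]
    at <- unique(c(seq(0, total, by = spacing), total))
    idx <- findInterval(at, s, rightmost.closed = TRUE)
    idx[idx >= length(s)] <- length(s) - 1L
    frac <- (at - s[idx]) / len[idx]
    pts[idx, , drop = FALSE] + seg[idx, , drop = FALSE] * frac
  })
  do.call(rbind, out)
}

#' Load and save centre-line graphs
#'
#' Two formats are supported: a JSON schema
#' `{"nodes": [[x,y,z],...], "edges": [[i,...],...], "radii": [[r,...],...],
#' "labels": [...]}` (indices 1-based, radii/labels optional) and legacy
#' ASCII VTK polydata (`POINTS` + `LINES`, as written by centre-line
#' extraction tools).
#'
#' @param path file path; format inferred from the extension when
#'   `format = "auto"` (`.json` vs `.vtk`).
#' @param format `"auto"`, `"json"` or `"vtk"`.
#' @return `load_graph`: a `centreline_graph`.
#' @export
load_graph <- function(path, format = c("auto", "json", "vtk")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "vtk"
  }
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  if (format == "json") {
    d <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
    if (is.null(d$nodes) || is.null(d$edges)) {
      stop(sprintf("%s: JSON graph needs 'nodes' and 'edges'", path),
           call. = FALSE)
    }
    edges <- if (is.matrix(d$edges)) {
      lapply(seq_len(nrow(d$edges)), function(i) d$edges[i, ])
    } else as.list(d$edges)
    radii <- if (is.null(d$radii)) NULL else {
      if (is.matrix(d$radii)) {
        lapply(seq_len(nrow(d$radii)), function(i) d$radii[i, ])
      } else as.list(d$radii)
    }
    centreline_graph(d$nodes, edges, radii, d$labels)
  } else {
    read_vtk_polylines(path)
  }
}

#' @rdname load_graph
#' @param g a `centreline_graph` to save.
#' @export
save_graph <- function(g, path, format = c("auto", "json", "vtk")) {
  stopifnot(inherits(g, "centreline_graph"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "vtk"
  }
  if (format == "json") {
    obj <- list(nodes = g$nodes, edges = g$edges)
    if (!is.null(g$radii)) obj$radii <- g$radii
    if (!is.null(g$labels)) obj$labels <- g$labels
    jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  } else {
    write_vtk_polylines(g, path)
  }
  invisible(path)
}

read_vtk_polylines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  toks_at <- function(i) strsplit(trimws(lines[i]), "\\s+")[[1]]
  ip <- grep("^POINTS", lines)
  il <- grep("^LINES", lines)
  if (length(ip) != 1L || length(il) != 1L) {
    stop(sprintf("%s: need exactly one POINTS and one LINES section", path),
         call. = FALSE)
  }
  npts <- as.integer(toks_at(ip)[2])
  # points: read numbers following the POINTS line until 3*npts collected
  vals <- numeric(0)
  i <- ip + 1L
  while (length(vals) < 3L * npts) {
    if (i > length(lines)) {
      stop(sprintf("%s: POINTS section ended early (line %d)", path, i),
           call. = FALSE)
    }
    if (i != il) vals <- c(vals, as.numeric(toks_at(i)))
    i <- i + 1L
  }
  nodes <- matrix(vals[seq_len(3L * npts)], ncol = 3L, byrow = TRUE)
  nlines <- as.integer(toks_at(il)[2])
  edges <- vector("list", nlines)
  i <- il + 1L
  for (k in seq_len(nlines)) {
    t <- as.integer(toks_at(i))
    cnt <- t[1]
    if (is.na(cnt) || length(t) != cnt + 1L) {
      stop(sprintf("%s: malformed LINES entry at line %d", path, i),
           call. = FALSE)
    }
    edges[[k]] <- t[-1] + 1L  # VTK is 0-based
    i <- i + 1L
  }
  centreline_graph(nodes, edges)
}

write_vtk_polylines <- function(g, path) {
  n <- nrow(g$nodes)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "vessel centre-line graph",
               "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d float", n)), con)
  writeLines(apply(g$nodes, 1L, function(p) {
    paste(formatC(p, format = "g", digits = 17), collapse = " ")
  }), con)
  sz <- sum(vapply(g$edges, length, integer(1))) + length(g$edges)
  writeLines(sprintf("LINES %d %d", length(g$edges), sz), con)
  writeLines(vapply(g$edges, function(e) {
    paste(c(length(e), e - 1L), collapse = " ")
  }, character(1)), con)
  invisible(path)
}
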