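# Shared fixtures and independent oracles, all built in code.

# Random proper rigid transform with bounded magnitude.
random_rigid <- function(max_translation = 20, max_angle_deg = 180) {
  ax <- stats::rnorm(3)
  ang <- stats::runif(1, 0, max_angle_deg)
  tr <- stats::rnorm(3)
  tr <- tr / sqrt(sum(tr^2)) * stats::runif(1, 0, max_translation)
  rigid_transform(axis_angle_rotation(ax, ang), tr)
}

# Simple Y-shaped graph: trunk along x, two branches from the junction.
y_graph <- function() {
  nodes <- rbind(c(0, 0, 0), c(40, 0, 0), c(80, 25, 5), c(80, -25, -5))
  centreline_graph(nodes, list(c(1, 2), c(2, 3), c(2, 4)))
}

# Liver-like synthetic tree (8 bifurcations) as a graph.
liver_graph <- function() make_phantom(phantom_preset("liver"))$graph

# Rebuild a graph with every edge resampled at `spacing`, so dense nodes
# correspond one-to-one under smooth deformation of the node table.
densify_graph <- function(g, spacing) {
  nodes <- matrix(numeric(0), 0, 3)
  edges <- list()
  for (e in g$edges) {
    pts <- resample_polyline_points(g$nodes[e, , drop = FALSE], spacing)
    idx <- nrow(nodes) + seq_len(nrow(pts))
    nodes <- rbind(nodes, pts)
    edges[[length(edges) + 1L]] <- idx
  }
  centreline_graph(nodes, edges)
}

resample_polyline_points <- function(pts, spacing) {
  seg <- diff(pts)
  len <- sqrt(rowSums(seg^2))
  s <- c(0, cumsum(len))
  at <- unique(c(seq(0, s[length(s)], by = spacing), s[length(s)]))
  idx <- findInterval(at, s, rightmost.closed = TRUE)
  idx[idx >= length(s)] <- length(s) - 1L
  pts[idx, , drop = FALSE] + seg[idx, , drop = FALSE] * (at - s[idx]) / len[idx]
}

# Independent brute-force dip oracle: plain loops, every (x, v) pair,
# window means computed with mean() on the raw slices. Indices 0-based to
# mirror the stated interval convention.
dip_oracle <- function(image, v_min, v_max, stride = 1) {
  nr <- nrow(image)
  out <- matrix(0, nr, ncol(image))
  for (ci in seq_len(ncol(image))) {
    col <- image[, ci]
    for (v in seq(v_min, v_max, by = stride)) {
      h <- v %/% 2
      for (x in seq(v, nr - 1 - v)) {      # 0-based centre rows
        a <- mean(col[(x + h):(x + v) + 1])
        b <- mean(col[(x - v):(x - h) + 1])
        cc <- mean(col[(x - h):(x + h) + 1])
        if (cc < a && cc < b) {
          bv <- min(a - cc, b - cc)
          span <- (x - h):(x + h) + 1
          out[span, ci] <- pmax(out[span, ci], bv)
        }
      }
    }
  }
  out
}

# Independent Gaussian-smoothed Hessian oracle built on stats::filter
# with explicit mirror padding (different code path from the package).
oracle_blur <- function(image, sigma) {
  radius <- ceiling(3 * sigma)
  k <- exp(-0.5 * ((-radius):radius)^2 / sigma^2)
  k <- k / sum(k)
  pad_mirror <- function(x, r) c(x[(r + 1):2], x, x[(length(x) - 1):(length(x) - r)])
  smooth_vec <- function(x) {
    y <- stats::filter(pad_mirror(x, radius), k, sides = 2)
    as.numeric(y[(radius + 1):(radius + length(x))])
  }
  tmp <- apply(image, 2, smooth_vec)
  t(apply(t(tmp), 2, smooth_vec))
}

# Default parameter bundles scaled for small (fast) test images.
small_dip_params <- function(...) dip_params(v_min = 8, v_max = 16, stride = 1,
                                             blur_sigma = 0, ...)
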