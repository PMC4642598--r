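test_that("graph validation enforces polyline invariants", {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0))
  expect_s3_class(centreline_graph(nodes, list(c(1, 2))), "centreline_graph")
  expect_error(centreline_graph(nodes, list(c(1))), ">= 2")
  expect_error(centreline_graph(nodes, list(c(1, 3))), "out of range")
  expect_error(centreline_graph(rbind(nodes, nodes[1, ]), list(c(1, 3))),
               "zero-length")
})

test_that("JSON and VTK round-trips preserve the graph", {
  g <- y_graph()
  g$radii <- list(c(3, 3), c(2.5, 2.5), c(2, 2))
  g$labels <- c("trunk", "left", "right")
  fj <- withr::local_tempfile(fileext = ".json")
  save_graph(g, fj)
  g2 <- load_graph(fj)
  expect_equal(g2$nodes, g$nodes, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(g2$edges, g$edges)
  expect_equal(unlist(g2$radii), unlist(g$radii))

  fv <- withr::local_tempfile(fileext = ".vtk")
  save_graph(g, fv)
  g3 <- load_graph(fv)
  expect_equal(g3$nodes, g$nodes, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(g3$edges, g$edges)

  expect_error(load_graph("no/such/file.json"), "no such file")
  bad <- withr::local_tempfile(fileext = ".vtk")
  writeLines(c("# vtk DataFile Version 3.0", "x", "ASCII", "DATASET POLYDATA",
               "POINTS 2 float", "0 0 0", "1 0 0", "LINES 1 3", "3 0 1"), bad)
  expect_error(load_graph(bad), "malformed LINES")
})

test_that("minimal JSON graph loads as a single 2-point polyline", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines('{"nodes": [[0,0,0],[10,0,0]], "edges": [[1,2]]}', f)
  g <- load_graph(f)
  expect_equal(length(g$edges), 1)
  expect_equal(g$edges[[1]], c(1L, 2L))
})

test_that("bifurcations count coinciding polyline endpoints", {
  straight <- centreline_graph(rbind(c(0, 0, 0), c(5, 0, 0), c(9, 1, 0)),
                               list(c(1, 2, 3)))
  expect_equal(nrow(bifurcations(straight)), 0)

  expect_equal(bifurcations(y_graph())$degree, 3)

  # X-shaped: 4 branches meeting at one point (within merge_tol)
  nodes <- rbind(c(0, 0, 0), c(10, 10, 0), c(-10, 10, 0), c(-10, -10, 0),
                 c(10, -10, 0), c(0, 0, 0.00005))
  xg <- centreline_graph(nodes, list(c(1, 2), c(1, 3), c(6, 4), c(6, 5)))
  bf <- bifurcations(xg, merge_tol = 0.1)
  expect_equal(nrow(bf), 1)
  expect_equal(bf$degree, 4)

  # count invariant under rigid motion
  set.seed(2)
  t1 <- random_rigid()
  expect_equal(bifurcations(transform_graph(xg, t1))$degree, 4)
})

test_that("VTK polylines sharing an endpoint produce a degree-3 node", {
  f <- withr::local_tempfile(fileext = ".vtk")
  writeLines(c("# vtk DataFile Version 3.0", "fixture", "ASCII",
               "DATASET POLYDATA", "POINTS 4 float",
               "0 0 0", "10 0 0", "15 5 0", "15 -5 0",
               "LINES 3 9", "2 0 1", "2 1 2", "2 1 3"), f)
  bf <- bifurcations(load_graph(f))
  expect_equal(nrow(bf), 1)
  expect_equal(bf$degree, 3)
  expect_equal(as.numeric(bf[1, c("x", "y", "z")]), c(10, 0, 0))
})

test_that("closest_point projects and clamps exactly", {
  g <- y_graph()
  on_seg <- c(20, 0, 0)
  cp <- closest_point(g, on_seg)
  expect_equal(cp$distance, 0, tolerance = 1e-12)
  expect_equal(cp$foot, on_seg, tolerance = 1e-12)
  # beyond the far end of branch one: clamps to the endpoint
  cp2 <- closest_point(g, c(100, 40, 8))
  expect_equal(cp2$foot, c(80, 25, 5), tolerance = 1e-12)
  empty <- structure(list(nodes = matrix(numeric(0), 0, 3), edges = list()),
                     class = "centreline_graph")
  expect_error(closest_point(empty, c(0, 0, 0)))
})

test_that("closest_point agrees with a dense-sampling oracle on random queries", {
  g <- liver_graph()
  dense <- resample_graph(g, 0.01)
  set.seed(33)
  pts <- cbind(stats::runif(300, -20, 110), stats::runif(300, -40, 40),
               stats::runif(300, -30, 50))
  cp <- closest_point(g, pts)
  for (i in seq_len(50)) {   # spot-check a subset against the oracle
    d_oracle <- sqrt(min(colSums((t(dense) - pts[i, ])^2)))
    expect_lt(abs(cp$distance[i] - d_oracle), 0.01)
  }
  # 1-Lipschitz in the query point
  for (i in 1:20) {
    delta <- stats::rnorm(3, sd = 0.5)
    d2 <- closest_point(g, pts[i, ] + delta)$distance
    expect_lte(abs(d2 - cp$distance[i]), sqrt(sum(delta^2)) + 1e-9)
  }
})

test_that("closest_point ties break to the lowest edge and segment", {
  # two identical overlapping segments: the first edge must win
  g <- centreline_graph(rbind(c(0, 0, 0), c(10, 0, 0), c(0, 0, 0), c(10, 0, 0)),
                        list(c(1, 2), c(3, 4)))
  cp <- closest_point(g, c(5, 3, 0))
  expect_equal(cp$edge, 1L)
  expect_equal(cp$segment, 1L)
})

test_that("resample_graph spacing controls point density", {
  g <- centreline_graph(rbind(c(0, 0, 0), c(10, 0, 0)), list(c(1, 2)))
  pts <- resample_graph(g, 1)
  expect_equal(nrow(pts), 11)
  expect_equal(pts[, 1], 0:10, tolerance = 1e-12)
})
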