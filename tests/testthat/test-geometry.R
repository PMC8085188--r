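test_that("voronoi_partition handles the single-site and symmetric two-site cases", {
  t1 <- voronoi_partition(data.frame(x = 5, y = 5), c(10, 10), scale = 1000)
  expect_length(t1$regions, 1)
  expect_equal(polygon_area(t1$regions[[1]]$vertices, 1000), 100)

  t2 <- voronoi_partition(data.frame(x = c(2, 8), y = c(5, 5)), c(10, 10))
  areas_px <- vapply(t2$regions, function(r) abs(lobulizer:::shoelace_signed(r$vertices)), 0)
  expect_equal(areas_px, c(50, 50))
  # the dividing edge is x = 5
  for (r in t2$regions) {
    on_mid <- abs(r$vertices[, 1] - 5) < 1e-9
    expect_equal(sum(on_mid), 2)
  }
})

test_that("voronoi_partition rejects duplicate and out-of-box sites", {
  expect_error(voronoi_partition(data.frame(x = c(1, 1), y = c(2, 2)), c(10, 10)),
               "duplicate sites: 1 and 2")
  expect_error(voronoi_partition(data.frame(x = 12, y = 5), c(10, 10)),
               "outside the bounding box")
  expect_error(voronoi_partition(data.frame(x = numeric(), y = numeric()), c(10, 10)))
})

test_that("rasterized Voronoi regions agree with the per-pixel nearest-site oracle", {
  withr::with_seed(11, {
    s <- data.frame(x = runif(5, 3, 61), y = runif(5, 3, 61))
  })
  t <- voronoi_partition(s, c(64, 64))
  expect_identical(rasterize_tessellation(t), oracle_nearest_site(s, c(64, 64)))
})

test_that("region areas conserve the bounding-box area (vector form)", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      n <- sample(3:30, 1)
      s <- data.frame(x = runif(n, 1, 127), y = runif(n, 1, 127))
    })
    t <- voronoi_partition(s, c(128, 128))
    total <- sum(vapply(t$regions, function(r) abs(lobulizer:::shoelace_signed(r$vertices)), 0))
    expect_equal(total, 128 * 128, tolerance = 1e-6)
    # every region contains its own site
    for (r in t$regions) {
      expect_true(points_in_polygon(r$site[1], r$site[2], r$vertices))
    }
  }
})

test_that("delaunay_dual matches the empty-circumcircle oracle", {
  t2 <- voronoi_partition(data.frame(x = c(2, 8), y = c(5, 5)), c(10, 10))
  expect_equal(nrow(delaunay_dual(t2)), 1)

  t3 <- voronoi_partition(data.frame(x = c(20, 80, 50), y = c(20, 25, 80)), c(100, 100))
  expect_equal(nrow(delaunay_dual(t3)), 3)

  withr::with_seed(4, {
    s <- cbind(runif(10, 30, 225), runif(10, 30, 225))
  })
  t <- voronoi_partition(s, c(256, 256))
  got <- delaunay_dual(t)
  got <- got[order(got[, 1], got[, 2]), , drop = FALSE]
  expect_equal(unname(got), unname(oracle_delaunay_edges(s)))
})

test_that("polygon_area converts shoelace pixels to mm^2 and rejects bowties", {
  sq <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2, byrow = TRUE)
  expect_equal(polygon_area(sq, 1000), 1)
  sq10 <- sq * 10
  expect_equal(polygon_area(sq10, 0.5), 2.5e-5)
  bow <- matrix(c(0, 0, 10, 10, 10, 0, 0, 10), ncol = 2, byrow = TRUE)
  expect_error(polygon_area(bow), "self-intersecting")

  withr::with_seed(21, {
    ang <- sort(runif(8, 0, 2 * pi))
    v <- cbind(50 + 30 * cos(ang), 50 + 25 * sin(ang))
  })
  a_px <- polygon_area(v, 1000)  # scale 1000 um/px -> mm^2 value equals px^2
  expect_equal(a_px, oracle_mc_area(v), tolerance = 0.005)
})

test_that("side_count merges collinear joints and survives small perturbations", {
  sq <- matrix(c(0, 0, 10, 0, 10, 10, 0, 10), ncol = 2, byrow = TRUE)
  expect_equal(side_count(sq), 4)
  sq_mid <- rbind(sq[1:2, ], c(10, 5), sq[3:4, ])
  expect_equal(side_count(sq_mid), 4)

  ang <- 2 * pi * (0:6) / 7
  hept <- cbind(100 * cos(ang), 100 * sin(ang))
  withr::with_seed(5, {
    pert <- ang + runif(7, -pi / 180, pi / 180)
  })
  hept_p <- cbind(100 * cos(pert), 100 * sin(pert))
  expect_equal(side_count(hept_p), 7)

  expect_error(side_count(matrix(c(0, 0, 5, 5, 10, 10), ncol = 2, byrow = TRUE)),
               "degenerate")
})

test_that("interior cells of a hexagonal lattice are hexagons", {
  s <- lobulizer:::hex_lattice_sites(c(300, 300), 60)
  t <- voronoi_partition(s, c(300, 300))
  ids <- interior_regions(t)
  expect_gt(length(ids), 3)
  for (i in ids) expect_equal(side_count(t$regions[[i]]$vertices), 6)
})

test_that("minimum enclosing circle diameter matches exact cases and the exhaustive oracle", {
  sq <- matrix(c(0, 0, 2000, 0, 2000, 2000, 0, 2000), ncol = 2, byrow = TRUE)
  expect_equal(min_enclosing_circle_diameter(sq, 0.5), sqrt(2))
  ang <- 2 * pi * (0:5) / 6
  hexv <- cbind(600 * cos(ang), 600 * sin(ang))
  expect_equal(min_enclosing_circle_diameter(hexv, 1), 1.2)

  for (seed in 1:5) {
    withr::with_seed(seed, {
      pts <- cbind(runif(12, 0, 100), runif(12, 0, 100))
    })
    got <- min_enclosing_circle_diameter(pts, 1000) / 2
    expect_equal(got, oracle_mec(pts), tolerance = 1e-6)
  }
})

test_that("regular_polygon_area reproduces closed-form and limiting values", {
  expect_equal(regular_polygon_area(4, 1), 2)
  # hexagon = six equilateral triangles of side R
  expect_equal(regular_polygon_area(6, 1), 6 * (sqrt(3) / 4))
  # n -> infinity limit is the circle area
  expect_equal(regular_polygon_area(1e6, 1), pi, tolerance = 1e-9)
  expect_error(regular_polygon_area(2, 1), "at least 3 sides")
  expect_error(regular_polygon_area(7, -1), "positive")
})

test_that("tidiers summarize tessellations", {
  t <- voronoi_partition(data.frame(x = c(2, 8), y = c(5, 5)), c(10, 10), scale = 1000)
  td <- tidy(t)
  expect_true(all(c("region_id", "vertex", "x", "y") %in% names(td)))
  g <- glance(t)
  expect_equal(g$n_regions, 2)
  expect_equal(g$total_area_mm2, 100)
})
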