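# Landscape covariates: height classification and point-buffered metrics.

test_that("height classification follows the shrub/tree thresholds", {
  h <- height_raster(matrix(c(0.3, 2.0, 10.0, 50.0, 3.5, 0.7), 2, 3))
  cls <- classify_heights(h)
  v <- cls$values
  expect_equal(cls$classes[v[1, 1]], "open")   # 0.3 m below shrub bound
  expect_equal(cls$classes[v[2, 1]], "shrub")  # 2.0 m
  expect_equal(cls$classes[v[1, 2]], "tree")   # 10 m
  expect_equal(cls$classes[v[2, 2]], "open")   # 50 m above tree ceiling
  expect_equal(cls$classes[v[1, 3]], "tree")   # boundary 3.5 m -> tree
  expect_equal(cls$classes[v[2, 3]], "shrub")  # boundary 0.7 m -> shrub
})

test_that("invalid heights are rejected with the offending cell named", {
  m <- matrix(1, 3, 3); m[2, 3] <- NaN
  expect_error(height_raster(m), "\\[2, 3\\]")
  m[2, 3] <- -1
  expect_error(height_raster(m), "negative")
  expect_error(classify_heights(height_raster(matrix(1, 2, 2)),
                                shrub_range = c(1, 5), tree_range = c(4, 40)),
               "overlap")
})

test_that("percent cover handles saturated, absent and half-plane classes", {
  all_tree <- cover_raster(matrix(3L, 40, 40), res = 3.6)
  ctr <- c(72, 72)
  expect_identical(percent_class_within(all_tree, ctr[1], ctr[2], 50, "tree"), 1)
  expect_identical(percent_class_within(all_tree, ctr[1], ctr[2], 50, "shrub"), 0)
  # vertical half-plane of tree through the point
  m <- matrix(1L, 40, 40); m[, 21:40] <- 3L
  half <- cover_raster(m, res = 3.6)
  p <- c(20 * 3.6, 72)  # on the boundary between columns 20 and 21
  got <- percent_class_within(half, p[1], p[2], 50, "tree")
  expect_equal(got, bf_percent(half, p[1], p[2], 50, "tree"))
  expect_lt(abs(got - 0.5), 0.05)
})

test_that("percent cover over all classes sums to one", {
  cov <- random_cover(30, 30, seed = 7)
  for (p in list(c(40, 40), c(60, 75), c(35, 70))) {
    tot <- sum(vapply(cov$classes, function(cl)
      percent_class_within(cov, p[1], p[2], 30, cl), numeric(1)))
    expect_equal(tot, 1)
  }
})

test_that("buffers off or partly off the raster behave as documented", {
  cov <- random_cover(20, 20, seed = 2)  # extent 72 x 72 m
  expect_error(percent_class_within(cov, 500, 500, 30, "open"),
               "outside the raster")
  expect_warning(percent_class_within(cov, 2, 2, 30, "open"),
                 "beyond the raster")
  expect_error(edge_density_within(cov, 0, 0, -5), "radius")
})

test_that("edge density matches the isolated-cell closed form and the oracle", {
  m <- matrix(1L, 31, 31); m[16, 16] <- 3L
  cov <- cover_raster(m, res = 3.6)
  ctr <- 15.5 * 3.6
  got <- edge_density_within(cov, ctr, ctr, 50)
  expect_equal(got, (4 * 3.6) / (pi * 50^2 / 1e4), tolerance = 1e-12)
  expect_equal(signif(got, 4), 18.33)
  # homogeneous rasters have no edges
  expect_equal(edge_density_within(cover_raster(matrix(1L, 31, 31), res = 3.6),
                                   ctr, ctr, 50), 0)
  expect_equal(edge_density_within(cover_raster(matrix(3L, 31, 31), res = 3.6),
                                   ctr, ctr, 50), 0)
  # checkerboard against the exhaustive boundary enumeration
  chk <- cover_raster(matrix(rep_len(c(1L, 3L), 31 * 31), 31, 31), res = 3.6)
  expect_equal(edge_density_within(chk, ctr, ctr, 40),
               bf_edge(chk, ctr, ctr, 40))
})

test_that("edge density is invariant to swapping woody and non-woody labels", {
  cov <- random_cover(35, 35, seed = 13)
  p <- c(60, 63)
  expect_equal(edge_density_within(cov, p[1], p[2], 45,
                                   woody_classes = c("shrub", "tree")),
               edge_density_within(cov, p[1], p[2], 45,
                                   woody_classes = "open"))
})

test_that("distance to class: containment, construction and oracle", {
  m <- matrix(1L, 50, 50)
  m[40, 25] <- 3L  # tree cell center at x = 24.5 res, y = 39.5 res
  cov <- cover_raster(m, res = 2)
  # point inside the tree cell
  expect_equal(distance_to_class(cov, 24.5 * 2, 39.5 * 2, "tree"), 0)
  # single tree 100 m due north of the point
  p <- c(24.5 * 2, 39.5 * 2 - 100)
  expect_equal(distance_to_class(cov, p[1], p[2], "tree"), 100)
  expect_error(distance_to_class(cov, 10, 10, "shrub"), "widen the extent")
  # sparse random fixture vs brute force
  cov2 <- random_cover(50, 50, seed = 5, probs = c(0.94, 0.03, 0.03))
  for (p in list(c(30, 40), c(100, 9), c(171, 171))) {
    expect_equal(distance_to_class(cov2, p[1], p[2], "tree"),
                 bf_dist(cov2, p[1], p[2], "tree"))
    expect_identical(distance_to_class(cov2, p[1], p[2], "tree") == 0,
                     {j <- floor(p[1] / 3.6) + 1; i <- floor(p[2] / 3.6) + 1
                      cov2$classes[cov2$values[i, j]] == "tree"})
  }
})

test_that("all metrics agree with brute force on random rasters", {
  for (seed in c(21, 22)) {
    cov <- random_cover(42, 42, seed = seed)
    p <- c(runif(1, 50, 100), runif(1, 50, 100))
    expect_equal(percent_class_within(cov, p[1], p[2], 40, "shrub"),
                 bf_percent(cov, p[1], p[2], 40, "shrub"))
    expect_equal(edge_density_within(cov, p[1], p[2], 40),
                 bf_edge(cov, p[1], p[2], 40))
    expect_equal(distance_to_class(cov, p[1], p[2], "tree"),
                 bf_dist(cov, p[1], p[2], "tree"))
  }
})

test_that("ASCII grid round-trips and landscape_covariates aggregates", {
  h <- height_raster(matrix(runif(400, 0, 30), 20, 20), xmin = 100,
                     ymin = 250, res = 3.6)
  f <- tempfile(fileext = ".asc")
  write_ascii_grid(h, f)
  h2 <- read_ascii_grid(f, "height")
  expect_equal(h2$values, h$values, tolerance = 1e-9)
  expect_equal(h2$xmin, 100); expect_equal(h2$res, 3.6)
  cov <- classify_heights(h)
  write_ascii_grid(cov, f)
  cov2 <- read_ascii_grid(f, "cover")
  expect_identical(cov2$values, cov$values)
  pts <- data.frame(id = 1:2, x = c(130, 140), y = c(280, 290))
  lc <- landscape_covariates(cov, pts, radius = 25)
  expect_equal(nrow(lc), 2)
  expect_true(all(c("pct_shrub", "pct_tree", "WE", "TD") %in% names(lc)))
  expect_equal(lc$pct_open + lc$pct_shrub + lc$pct_tree, c(1, 1))
  unlink(f)
})
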