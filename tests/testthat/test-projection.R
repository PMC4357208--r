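test_that("box-with-cut projection recovers the oracle pentagon", {
  ts <- slack_system(R = matrix(c(1, 1), 1), rhs = 1.5, up = c(1, 1))
  reg <- project_pair(ts$system, ts$b, ts$bounds, c("x1", "x2"), n_dir = 64)
  expect_false(reg$degenerate)
  oracle <- brute_vertices(matrix(c(1, 1), 1), 1.5, c(1, 1))
  expect_equal(nrow(reg$vertices), nrow(oracle))  # pentagon
  for (i in seq_len(nrow(oracle)))
    expect_true(any(apply(reg$vertices, 1, function(v) all(abs(v - oracle[i, ]) < 1e-6))))
  expect_equal(reg$area, 1 - 0.125, tolerance = 1e-9)
  ## counter-clockwise orientation (positive signed area)
  V <- reg$vertices; n <- nrow(V); i2 <- c(2:n, 1)
  expect_gt(sum(V[, 1] * V[i2, 2] - V[i2, 1] * V[, 2]), 0)
})

test_that("equality-linked pair degenerates to a flagged segment", {
  ## x1 - x2 = 0 encoded through a balanced row with no slack
  R <- matrix(c(1, 1), 1)
  ts <- slack_system(R, 2, up = c(1, 1))
  ts$system$A <- rbind(ts$system$A, c(1, -1, 0))
  rownames(ts$system$A)[2] <- "link"
  ts$b <- c(ts$b, link = 0)
  reg <- project_pair(ts$system, ts$b, ts$bounds, c("x1", "x2"))
  expect_true(reg$degenerate)
  expect_true(contains_point(reg, c(0.5, 0.5)))
  expect_false(contains_point(reg, c(0.2, 0.8)))
})

test_that("point membership: vertices in, far points out", {
  ts <- slack_system(R = matrix(c(1, 1), 1), rhs = 1.5, up = c(1, 1))
  reg <- project_pair(ts$system, ts$b, ts$bounds, c("x1", "x2"))
  for (i in seq_len(nrow(reg$vertices)))
    expect_true(contains_point(reg, reg$vertices[i, ]))
  expect_false(contains_point(reg, c(2, 2)))
  expect_false(contains_point(reg, c(0.9, 0.9)))  # beyond the cut
})

test_that("doubling sweep directions never shrinks the recovered area", {
  set.seed(3)
  for (rep in 1:5) {
    d <- sample(2:3, 1)
    R <- matrix(stats::runif(2 * d, -1, 1), 2, d)
    ts <- slack_system(R, rhs = rowSums(pmax(R, 0)) * 0.7 + 0.1, up = rep(1, d))
    areas <- vapply(c(8, 16, 32, 64), function(nd)
      project_pair(ts$system, ts$b, ts$bounds, c("x1", "x2"), n_dir = nd)$area, 0)
    expect_true(all(diff(areas) >= -1e-9))
  }
})

test_that("projection equals the brute-force oracle on random toy systems", {
  set.seed(7)
  for (rep in 1:8) {
    d <- sample(2:4, 1); m <- sample(1:3, 1)
    R <- matrix(stats::runif(m * d, -1, 1), m, d)
    rhs <- rowSums(pmax(R, 0)) * 0.6 + 0.05   # keeps a nonempty region in [0,1]^d
    ts <- slack_system(R, rhs, up = rep(1, d))
    V <- brute_vertices(R, rhs, up = rep(1, d))
    expect_gt(nrow(V), 0)
    reg <- project_pair(ts$system, ts$b, ts$bounds, c("x1", "x2"), n_dir = 96)
    proj <- unique(round(V[, 1:2, drop = FALSE], 7))
    hull <- if (nrow(proj) > 2) proj[grDevices::chull(proj), , drop = FALSE] else proj
    ## identical area and mutual containment of vertex sets
    area_or <- if (nrow(hull) >= 3) {
      i2 <- c(2:nrow(hull), 1)
      0.5 * abs(sum(hull[, 1] * hull[i2, 2] - hull[i2, 1] * hull[, 2]))
    } else 0
    expect_equal(reg$area, area_or, tolerance = 1e-6)
    for (i in seq_len(nrow(hull)))
      expect_true(contains_point(reg, hull[i, ], tol = 1e-6))
  }
})

test_that("trend sign of scenario extremes", {
  pts_neg <- cbind(x = c(0, 0.5, 1), y = c(1, 0.4, 0))
  expect_equal(pairwise_trend(pts_neg), -1)
  pts_pos <- cbind(x = c(0, 1, 2), y = c(0, 2, 3.5))
  expect_equal(pairwise_trend(pts_pos), 1)
  expect_true(is.na(pairwise_trend(cbind(c(1, 1), c(0, 2)))))  # no x spread
  expect_true(is.na(pairwise_trend(cbind(1, 1))))              # single point
})

test_that("study flux-pair regions enclose the scenario extremes; PYK-ME trend inverse", {
  st <- study_setup()
  cal <- calibrate_loads(st$system, st$bounds)
  tab <- enumerate_scenarios(st$system, cal, st$bounds)
  reg <- project_pair(st$system, cal, st$bounds, c("r_TCA", "r_PYK"))
  pts <- scenario_points(tab, c("r_TCA", "r_PYK"))
  for (i in seq_len(nrow(pts)))
    expect_true(contains_point(reg, pts[i, ], tol = 1e-6))
  ## convex combinations of scenario extremes stay inside the region
  expect_true(contains_point(reg, 0.5 * pts[1, ] + 0.5 * pts[min(4, nrow(pts)), ],
                             tol = 1e-6))
  ## pyruvate kinase and malic enzyme vary inversely across the extremes
  expect_equal(pairwise_trend(tab, c("r_PYK", "r_ME")), -1)
})
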