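test_that("a filled disk yields exactly one contour on the circle", {
  img <- disk_image(96, 28)
  ct <- extract_contours(contour_feature_map(img))
  expect_length(ct, 1)
  p <- ct[[1]]$points
  r <- sqrt((p[, 1] - 47.5)^2 + (p[, 2] - 47.5)^2)
  expect_lt(max(abs(r - 28)), 2)
  expect_gt(nrow(p), 2 * pi * 28 * 0.8)   # most of the circumference
})

test_that("blank maps yield no contours", {
  expect_length(extract_contours(feature_map(matrix(0, 32, 32), "raw")), 0)
  expect_length(extract_contours(contour_feature_map(matrix(0.5, 64, 64))),
                0)
})

test_that("two well-separated rectangles yield two contours", {
  ct <- extract_contours(contour_feature_map(two_rects_image()))
  expect_length(ct, 2)
})

test_that("contour chains are 8-connected without repeats", {
  ct <- extract_contours(contour_feature_map(disk_image()))
  p <- ct[[1]]$points
  d <- abs(diff(p[, 1])) <= 1 & abs(diff(p[, 2])) <= 1
  expect_true(all(d))
  expect_false(any(diff(p[, 1]) == 0 & diff(p[, 2]) == 0))
})

test_that("CSS finds the single corner of an L-shaped polyline", {
  # constructed chain: 60 steps along +x then 60 along +y
  pts <- rbind(cbind(0:60, 0), cbind(60, 1:60))
  ct <- structure(list(id = 1L, points = cbind(x = pts[, 1], y = pts[, 2]),
                       closed = FALSE), class = "contour")
  kp <- css_feature_points(ct)
  expect_equal(nrow(kp), 1)
  expect_lte(abs(kp$contour_index - 61), 2)
})

test_that("CSS finds nothing on a straight chain", {
  ct <- structure(list(id = 1L, points = cbind(x = 0:80, y = rep(5, 81)),
                       closed = FALSE), class = "contour")
  expect_equal(nrow(css_feature_points(ct)), 0)
})

test_that("CSS finds the four corners of a square chain", {
  s <- 40
  pts <- rbind(cbind(0:s, 0), cbind(s, 1:s),
               cbind((s - 1):0, s), cbind(0, (s - 1):1))
  ct <- structure(list(id = 1L, points = cbind(x = pts[, 1], y = pts[, 2]),
                       closed = TRUE), class = "contour")
  kp <- css_feature_points(ct)
  expect_equal(nrow(kp), 4)
})

test_that("arm vectors follow the chain on both sides", {
  pts <- rbind(cbind(0:20, 0), cbind(20, 1:20))
  ct <- structure(list(id = 1L, points = cbind(x = pts[, 1], y = pts[, 2]),
                       closed = FALSE), class = "contour")
  arms <- arm_vectors(ct, 21, arm_length = 5)   # the corner at (20, 0)
  got <- list(arms$arm_left, arms$arm_right)
  expect_true(any(vapply(got, function(a) all(a == c(-5, 0)), TRUE)))
  expect_true(any(vapply(got, function(a) all(a == c(0, 5)), TRUE)))
  # straight chain: arms anti-parallel
  st <- structure(list(id = 1L, points = cbind(x = 0:30, y = rep(0, 31)),
                       closed = FALSE), class = "contour")
  a2 <- arm_vectors(st, 15, 5)
  expect_equal(a2$arm_left, -a2$arm_right)
  # too close to an open end
  expect_null(arm_vectors(st, 2, 5))
  # closed square corner: arms along the two incident sides
  s <- 20
  sq <- rbind(cbind(0:s, 0), cbind(s, 1:s), cbind((s - 1):0, s),
              cbind(0, (s - 1):1))
  sqc <- structure(list(id = 1L, points = cbind(x = sq[, 1], y = sq[, 2]),
                        closed = TRUE), class = "contour")
  a3 <- arm_vectors(sqc, s + 1, 4)  # corner (20, 0)
  expect_equal(a3$arm_left, c(-4, 0))
  expect_equal(a3$arm_right, c(0, 4))
})

test_that("bisector follows the min-norm weighted unit-sum rule", {
  expect_equal(bisector(c(1, 0), c(0, 1)), c(1, 1))
  # min(|L|, |R|) scales the sum of unit vectors
  expect_equal(bisector(c(2, 0), c(0, 1)), c(1, 1))
  # anti-parallel arms are degenerate
  expect_equal(bisector(c(1, 0), c(-1, 0)), c(0, 0))
  expect_error(bisector(c(0, 0), c(1, 0)), "non-zero")
})

test_that("orientation_from_bisector covers all quadrants and boundaries", {
  expect_equal(orientation_from_bisector(1, 1), pi / 4)
  expect_equal(orientation_from_bisector(-1, 0), pi)
  expect_equal(orientation_from_bisector(1, -1), 7 * pi / 4)
  expect_equal(orientation_from_bisector(0, 1), pi / 2)
  expect_equal(orientation_from_bisector(0, -1), 3 * pi / 2)
  expect_error(orientation_from_bisector(0, 0), "degenerate")
})

test_that("orientation matches the two-argument arctangent on random input", {
  set.seed(42)
  x <- runif(1000, -1, 1)
  y <- runif(1000, -1, 1)
  bad <- x == 0 & y == 0
  x <- x[!bad]; y <- y[!bad]
  got <- mapply(orientation_from_bisector, x, y)
  want <- atan2(y, x) %% (2 * pi)
  expect_lt(max(abs(got - want)), 1e-9)
  expect_true(all(got >= 0 & got < 2 * pi))
})

test_that("a square image yields four diagonal corner orientations", {
  kp <- detect_and_orient(contour_feature_map(square_image()))
  expect_equal(nrow(kp), 4)
  want <- c(45, 135, 225, 315)
  got <- sort(kp$orientation) * 180 / pi
  expect_lt(max(circ_diff_deg(got, want)), 5)
  expect_true(all(kp$orientation >= 0 & kp$orientation < 2 * pi))
})

test_that("blank images yield no keypoints", {
  kp <- detect_and_orient(contour_feature_map(matrix(0.2, 96, 96)))
  expect_equal(nrow(kp), 0)
})

test_that("keypoint count is robust to 2x downsampling", {
  img <- square_blob_scene(400)
  half <- (img[seq(1, 399, 2), seq(1, 399, 2)] +
             img[seq(2, 400, 2), seq(1, 399, 2)] +
             img[seq(1, 399, 2), seq(2, 400, 2)] +
             img[seq(2, 400, 2), seq(2, 400, 2)]) / 4
  n1 <- nrow(detect_and_orient(contour_feature_map(img)))
  n2 <- nrow(detect_and_orient(contour_feature_map(half)))
  expect_gte(n2, ceiling(0.6 * n1))
  expect_lte(n2, floor(1.4 * n1))
})

test_that("dense keypoints sample the chains with valid orientations", {
  dk <- dense_keypoints(contour_feature_map(disk_image()))
  expect_gt(nrow(dk), 20)
  expect_true(all(dk$orientation >= 0 & dk$orientation < 2 * pi))
  # disk normals point radially (inward or outward): check alignment with
  # the radius direction modulo pi
  rad <- atan2(dk$y - 47.5, dk$x - 47.5)
  d <- abs(dk$orientation - rad) %% pi
  d <- pmin(d, pi - d)
  expect_lt(stats::median(d) * 180 / pi, 20)
})
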