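test_that("rmse follows the root-mean-square formula", {
  p <- rbind(c(0, 0), c(3, 4))
  r <- rbind(c(0, 0), c(0, 0))
  expect_equal(rmse_points(p, r), sqrt(25 / 2))   # distances 0 and 5
  expect_equal(rmse_points(p, p), 0)
  expect_equal(rmse_points(rbind(c(1, 1)), rbind(c(4, 5))), 5)
  expect_error(rmse_points(p, r[1, , drop = FALSE]), "equal")
})

test_that("rmse is invariant to a common rigid motion", {
  set.seed(41)
  p <- cbind(runif(12, 0, 50), runif(12, 0, 50))
  r <- p + matrix(rnorm(24), 12, 2)
  tf <- similarity_transform(1, 0.8, 12, -7)    # rigid: scale 1
  expect_equal(rmse_points(p, r),
               rmse_points(transform_points(tf, p), transform_points(tf, r)),
               tolerance = 1e-10)
})

test_that("precision counts the 5-px boundary as correct", {
  p <- rbind(c(0, 0), c(3, 0), c(5, 0), c(7, 0))
  r <- rbind(c(0, 0), c(0, 0), c(0, 0), c(0, 0))
  pr <- precision_recall(p, r, correspond_count = 4)
  expect_equal(pr$precision, 3 / 4)
  expect_equal(pr$n_correct, 3L)
  # all perfect
  pr2 <- precision_recall(r, r, correspond_count = 4)
  expect_equal(pr2$precision, 1)
  expect_equal(pr2$recall, 1)
  # 10 matches, 6 within radius, 12 correspondences
  set.seed(42)
  p3 <- cbind(c(rep(0, 6), rep(20, 4)), 0)
  r3 <- cbind(rep(0, 10), 0)
  pr3 <- precision_recall(p3, r3, correspond_count = 12)
  expect_equal(pr3$precision, 0.6)
  expect_equal(pr3$recall, 0.5)
  expect_error(precision_recall(p3[0, ], r3[0, ], 5), "at least one")
})

test_that("precision times total equals the correct count exactly", {
  set.seed(43)
  for (rep in 1:5) {
    n <- sample(3:40, 1)
    p <- cbind(runif(n, 0, 10), runif(n, 0, 10))
    r <- p + matrix(rnorm(2 * n, 0, 4), n, 2)
    pr <- precision_recall(p, r, correspond_count = n)
    # the correct count is an exact integer behind the ratio
    expect_identical(pr$n_correct,
                     as.integer(round(pr$precision * pr$n_matches)))
    expect_equal(pr$precision * pr$n_matches, pr$n_correct)
  }
})

test_that("accuracy is the usual confusion-matrix ratio", {
  expect_equal(accuracy_score(2, 2, 1, 0), 0.8)
  expect_equal(accuracy_score(0, 0, 1, 1), 0)
  expect_equal(accuracy_score(5, 5, 0, 0), 1)
  expect_error(accuracy_score(-1, 0, 0, 2), "negative")
  expect_error(accuracy_score(0, 0, 0, 0), "empty")
})

test_that("orientation agreement wraps and uses a strict threshold", {
  expect_equal(orientation_agreement(0, 359), 1L)      # wraps to 1 degree
  expect_equal(orientation_agreement(0, 5), 0L)        # exactly 5: strict
  expect_equal(orientation_agreement(0, 4.999), 1L)
  a <- c(10, 100, 250, 359.5)
  expect_equal(orientation_agreement(a, a), 4L)
  expect_error(orientation_agreement(1:3, 1:2), "mismatch")
})

test_that("metrics agree with naive re-count oracles on random instances", {
  set.seed(44)
  for (rep in 1:50) {
    n <- 50
    p <- cbind(runif(n, 0, 30), runif(n, 0, 30))
    r <- p + matrix(rnorm(2 * n, 0, 4), n, 2)
    # naive recount
    d <- sqrt((p[, 1] - r[, 1])^2 + (p[, 2] - r[, 2])^2)
    n_ok <- 0L
    for (i in seq_len(n)) if (d[i] <= 5) n_ok <- n_ok + 1L
    corr <- sample(n_ok:(2 * n), 1)
    pr <- precision_recall(p, r, correspond_count = corr)
    expect_equal(pr$precision, n_ok / n)
    expect_equal(pr$recall, n_ok / corr)
    expect_equal(rmse_points(p, r), sqrt(sum(d^2) / n))
    a1 <- runif(n, 0, 360); a2 <- runif(n, 0, 360)
    dd <- abs(a1 - a2) %% 360
    expect_equal(orientation_agreement(a1, a2),
                 sum(pmin(dd, 360 - dd) < 5))
  }
})

test_that("correspond_count pairs keypoints through the true transform", {
  kp_ir <- data.frame(x = c(0, 10, 20), y = c(0, 0, 0))
  kp_vis <- data.frame(x = c(2, 52), y = c(3, 3))
  tf <- similarity_transform(1, 0, 0, 0)
  expect_equal(correspond_count(kp_ir, kp_vis, tf, radius = 5), 1L)
  tf2 <- similarity_transform(2, 0, 2, 3)   # maps 0 -> (2,3), 10 -> (22,3)
  expect_equal(correspond_count(kp_ir, kp_vis, tf2, radius = 5), 1L)
  expect_equal(correspond_count(kp_ir[0, ], kp_vis, tf, 5), 0L)
})
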