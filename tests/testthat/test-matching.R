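# helpers to build descriptor sets directly
desc_set <- function(vectors, xy = NULL) {
  n <- nrow(vectors)
  if (is.null(xy)) xy <- cbind(seq_len(n) * 10, seq_len(n) * 10)
  list(vectors = vectors,
       info = data.frame(keypoint = seq_len(n), x = xy[, 1], y = xy[, 2],
                         orientation = 0, scale = 8))
}
unit_rows <- function(m) m / sqrt(rowSums(m^2))

test_that("identical descriptor sets match one-to-one", {
  set.seed(21)
  v <- unit_rows(matrix(runif(8 * 128), 8, 128))
  m <- bilateral_match(desc_set(v), desc_set(v), ratio = 0.8)
  expect_equal(nrow(m), 8)
  expect_equal(m$ir_keypoint, m$vis_keypoint)
  expect_true(all(m$distance < 1e-6))
})

test_that("mutual matching is stricter than one-directional (oracle)", {
  set.seed(22)
  A <- unit_rows(matrix(runif(10 * 128), 10, 128))
  B <- unit_rows(matrix(runif(10 * 128), 10, 128))
  D <- sqrt(pmax(outer(rowSums(A^2), rowSums(B^2), "+") -
                   2 * tcrossprod(A, B), 0))
  nn_ab <- apply(D, 1, which.min)
  nn_ba <- apply(D, 2, which.min)
  mutual <- sum(vapply(seq_len(10), function(i) nn_ba[nn_ab[i]] == i, TRUE))
  m <- bilateral_match(desc_set(A), desc_set(B), ratio = 1)
  expect_lte(nrow(m), mutual)          # ratio test can only remove more
  expect_lte(mutual, 10)               # and mutual <= one-directional count
  # every reported pair is a mutual nearest neighbour per the oracle
  for (r in seq_len(nrow(m))) {
    i <- m$ir_keypoint[r]; v <- m$vis_keypoint[r]
    expect_equal(unname(nn_ab[i]), v)
    expect_equal(unname(nn_ba[v]), i)
  }
})

test_that("a zero ratio accepts nothing", {
  set.seed(23)
  v <- unit_rows(matrix(runif(5 * 128), 5, 128))
  expect_equal(nrow(bilateral_match(desc_set(v), desc_set(v), ratio = 0)), 0)
})

test_that("the spatial search radius gates far-away candidates", {
  set.seed(24)
  v <- unit_rows(matrix(runif(4 * 128), 4, 128))
  near <- desc_set(v, cbind(rep(10, 4), 10 * 1:4))
  far <- desc_set(v, cbind(rep(500, 4), 10 * 1:4))
  expect_equal(nrow(bilateral_match(near, far, ratio = 1,
                                    search_radius = 50)), 0)
  expect_equal(nrow(bilateral_match(near, far, ratio = 1,
                                    search_radius = Inf)), 4)
})

test_that("RANSAC recovers an exact planted similarity", {
  set.seed(31)
  src <- cbind(runif(20, 0, 100), runif(20, 0, 100))
  tf <- similarity_transform(2, 30 * pi / 180, 10, -5)
  dst <- transform_points(tf, src)
  m <- data.frame(ir_x = src[, 1], ir_y = src[, 2],
                  vis_x = dst[, 1], vis_y = dst[, 2],
                  distance = 0, stage = "bilateral", inlier = NA)
  fit <- ransac_similarity(m, inlier_tol = 1, iterations = 500, seed = 5)
  expect_true(fit$ok)
  expect_equal(fit$n_inliers, 20)
  expect_equal(fit$transform$s, 2, tolerance = 1e-6)
  expect_equal(fit$transform$phi, 30 * pi / 180, tolerance = 1e-6)
  expect_equal(fit$transform$tx, 10, tolerance = 1e-6)
  expect_equal(fit$transform$ty, -5, tolerance = 1e-6)
})

test_that("RANSAC survives 40 percent outliers", {
  set.seed(32)
  src <- cbind(runif(20, 0, 100), runif(20, 0, 100))
  tf <- similarity_transform(2, 30 * pi / 180, 10, -5)
  dst <- transform_points(tf, src)
  # add outliers so they make up 40% of the total
  n_out <- 13
  src_o <- cbind(runif(n_out, 0, 100), runif(n_out, 0, 100))
  dst_o <- cbind(runif(n_out, 0, 300), runif(n_out, 0, 300))
  m <- data.frame(ir_x = c(src[, 1], src_o[, 1]),
                  ir_y = c(src[, 2], src_o[, 2]),
                  vis_x = c(dst[, 1], dst_o[, 1]),
                  vis_y = c(dst[, 2], dst_o[, 2]),
                  distance = 0, stage = "bilateral", inlier = NA)
  fit <- ransac_similarity(m, inlier_tol = 3, iterations = 2000, seed = 7)
  expect_true(fit$ok)
  expect_true(all(fit$matches$inlier[1:20]))
  expect_lt(abs(fit$transform$s - 2) / 2, 0.01)
  expect_lt(abs(fit$transform$phi - 30 * pi / 180), 0.5 * pi / 180)
  expect_lt(max(abs(c(fit$transform$tx - 10, fit$transform$ty + 5))), 0.5)
})

test_that("RANSAC is deterministic given the seed and fails gracefully", {
  set.seed(33)
  src <- cbind(runif(12, 0, 50), runif(12, 0, 50))
  dst <- src + matrix(rnorm(24, 0, 0.5), 12, 2)
  m <- data.frame(ir_x = src[, 1], ir_y = src[, 2],
                  vis_x = dst[, 1], vis_y = dst[, 2],
                  distance = 0, stage = "bilateral", inlier = NA)
  f1 <- ransac_similarity(m, 2, 300, seed = 99)
  f2 <- ransac_similarity(m, 2, 300, seed = 99)
  expect_identical(f1, f2)
  # identity correspondences recover the identity
  expect_equal(f1$transform$s, 1, tolerance = 0.05)
  expect_error(ransac_similarity(m[1, ], 2, 100, 1),
               class = "gocao_registration_failure")
})

test_that("transform algebra round-trips", {
  tf <- similarity_transform(1.7, 0.6, 12, -8)
  p <- cbind(runif(5, -20, 80), runif(5, -20, 80))
  back <- transform_points(invert_transform(tf), transform_points(tf, p))
  expect_equal(unname(back), unname(p), tolerance = 1e-10)
  comp <- compose_transforms(tf, invert_transform(tf))
  expect_equal(comp$s, 1, tolerance = 1e-10)
  expect_equal(comp$phi, 0, tolerance = 1e-10)
  expect_equal(abs(comp$tx) + abs(comp$ty), 0, tolerance = 1e-8)
  expect_error(similarity_transform(-1), "positive")
})

test_that("refinement recovers a perturbed transform and never degrades", {
  pair <- generate_pair(scene_pair_spec(
    seed = 77, scene_size = c(256L, 256L), ir_size = c(256L, 256L),
    s = 1, phi = 0, tx = 0, ty = 0, illumination_level = 3,
    noise_sigma = 0, ir_noise_sigma = 0, ir_blur_sigma = 0,
    intensity_map_ir = "identity", blob_count = 3L))
  A <- pair$visible
  true_tf <- similarity_transform(1.03, 0.02, 4, -3)
  B <- warp_image(A, true_tf, fill = 0.35)   # B(p) = A(true_tf(p))
  cfg <- default_config()
  ki <- dense_keypoints(contour_feature_map(B), cfg)
  rough <- similarity_transform(1.005, 0.005, 6.5, -0.5)  # a few px off
  rs <- list(transform = rough,
             matches = data.frame(ir_x = numeric(0), ir_y = numeric(0),
                                  vis_x = numeric(0), vis_y = numeric(0),
                                  distance = numeric(0),
                                  stage = character(0),
                                  inlier = logical(0)),
             n_inliers = 0L, ok = TRUE)
  fine <- refine_matches(rs, ki, B, A, window = 8, iterations = 3,
                         patch_radius = 10, min_cc = 0.5)
  expect_lte(fine$mean_error_after, fine$mean_error_before + 1e-9)
  # the refined transform reproduces the planted warp on test points
  pts <- cbind(runif(30, 60, 200), runif(30, 60, 200))
  err_rough <- sqrt(rowSums((transform_points(rough, pts) -
                               transform_points(true_tf, pts))^2))
  err_fine <- sqrt(rowSums((transform_points(fine$transform, pts) -
                              transform_points(true_tf, pts))^2))
  expect_lt(mean(err_fine), mean(err_rough))
  expect_lt(mean(err_fine), 1.5)
})

test_that("refinement is a no-op at an exact transform", {
  pair <- generate_pair(scene_pair_spec(
    seed = 78, scene_size = c(192L, 192L), ir_size = c(192L, 192L),
    s = 1, phi = 0, tx = 0, ty = 0, illumination_level = 3,
    noise_sigma = 0, ir_noise_sigma = 0, ir_blur_sigma = 0,
    intensity_map_ir = "identity", blob_count = 2L))
  A <- pair$visible
  cfg <- default_config()
  ki <- dense_keypoints(contour_feature_map(A), cfg)
  ident <- similarity_transform(1, 0, 0, 0)
  rs <- list(transform = ident,
             matches = data.frame(ir_x = numeric(0), ir_y = numeric(0),
                                  vis_x = numeric(0), vis_y = numeric(0),
                                  distance = numeric(0),
                                  stage = character(0),
                                  inlier = logical(0)),
             n_inliers = 0L, ok = TRUE)
  fine <- refine_matches(rs, ki, A, A, window = 4, iterations = 2,
                         patch_radius = 10, min_cc = 0.5)
  expect_equal(fine$transform$s, 1, tolerance = 2e-3)
  expect_lt(abs(fine$transform$phi), 2e-3)
  expect_lt(abs(fine$transform$tx) + abs(fine$transform$ty), 0.5)
})
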