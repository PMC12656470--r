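test_that("Gabor kernel matches the closed form and is even-symmetric", {
  p <- gabor_params(f = 0.25, theta = 0, sigma = 2, gamma = 1)
  k <- make_gabor_kernel(p)
  c0 <- p$support + 1
  # centre value: envelope and carrier are both 1 at the origin
  expect_equal(k[c0, c0], 1 / (2 * pi * 4))
  # hand-evaluated off-centre ratio: exp(-0.5) * cos(pi)
  expect_equal(k[c0, c0 + 2] / k[c0, c0], exp(-0.5) * cos(pi))
  # even symmetry holds exactly for every orientation
  for (th in c(0, pi / 8, pi / 3, 2)) {
    k <- make_gabor_kernel(gabor_params(f = 0.2, theta = th, sigma = 3))
    expect_identical(k, k[rev(seq_len(nrow(k))), rev(seq_len(ncol(k)))])
  }
  expect_error(gabor_params(f = -1, theta = 0, sigma = 2), "positive")
  expect_error(gabor_params(f = 0.2, theta = 0, sigma = 0), "positive")
})

test_that("constant images produce a near-zero Gabor response", {
  f <- gabor_feature_map(matrix(0.5, 32, 32), normalize = FALSE)
  # bound derived from the bank's peak gain (sum of |kernel| bounds the
  # gain at any frequency)
  gain <- max(vapply(default_gabor_bank(),
                     function(p) sum(abs(make_gabor_kernel(p))), 0))
  expect_lt(max(abs(f$values)), 1e-3 * gain)
})

test_that("a vertical step edge peaks within one pixel of the edge", {
  img <- matrix(0, 32, 32)
  img[, 17:32] <- 1
  bank <- list(gabor_params(f = 0.375, theta = 0, sigma = 2, gamma = 0.5,
                            support = 12))
  f <- gabor_feature_map(img, bank, normalize = FALSE)
  prof <- abs(f$values[16, ])
  # edge lies between columns 16 and 17 (1-based)
  expect_lte(abs(which.max(prof) - 16.5), 1.5)
})

test_that("a single-kernel bank reduces to plain convolution", {
  set.seed(11)
  img <- matrix(runif(24 * 20), 24, 20)
  p <- gabor_params(f = 0.3, theta = pi / 5, sigma = 1.5)
  f <- gabor_feature_map(img, list(p), normalize = FALSE)
  expect_equal(f$values, gocao:::conv2_reflect(img, make_gabor_kernel(p)),
               tolerance = 1e-12)
})

test_that("FFT convolution agrees with a quadruple-loop oracle", {
  set.seed(7)
  img <- matrix(runif(16 * 16), 16, 16)
  k <- make_gabor_kernel(gabor_params(f = 0.3, theta = pi / 7, sigma = 1,
                                      support = 3))
  expect_equal(gocao:::conv2_reflect(img, k), naive_conv2_reflect(img, k),
               tolerance = 1e-9)
})

test_that("ordinal kernels are balanced and lobes normalized", {
  # single positive lobe: a discretized Gaussian of unit mass
  p1 <- ordinal_params(positive_lobes = cbind(omega = 0, sigma = 1),
                       negative_lobes = cbind(omega = 9, sigma = 0.1),
                       c_p = 1, c_n = 0)
  k1 <- make_ordinal_kernel(p1)
  expect_equal(sum(k1), 1, tolerance = 1e-9)
  # default triple lobe: zero sum
  k <- make_ordinal_kernel(ordinal_params())
  expect_lt(abs(sum(k)), 1e-6)
  # mirrored lobes give an even kernel
  expect_equal(k, rev(k))
  # 2-D isotropic realization also balances
  expect_lt(abs(sum(gocao:::make_ordinal_kernel_2d(ordinal_params()))), 1e-6)
  # support must cover the lobes
  expect_error(make_ordinal_kernel(ordinal_params(), support = 2), "support")
  expect_error(ordinal_params(positive_lobes = cbind(omega = 0, sigma = -1)),
               "sigma")
})

test_that("ordinal map is linear and kills constants", {
  set.seed(3)
  op <- ordinal_params()
  F1 <- feature_map(matrix(rnorm(30 * 30), 30, 30), "gabor-F")
  F2 <- feature_map(matrix(rnorm(30 * 30), 30, 30), "gabor-F")
  Fc <- feature_map(2.5 * F1$values - 1.2 * F2$values, "gabor-F")
  s1 <- ordinal_feature_map(F1, op, normalize = FALSE)$values
  s2 <- ordinal_feature_map(F2, op, normalize = FALSE)$values
  sc <- ordinal_feature_map(Fc, op, normalize = FALSE)$values
  expect_equal(sc, 2.5 * s1 - 1.2 * s2, tolerance = 1e-10)
  # zero map stays zero; constant map dies under the balanced kernel
  z <- ordinal_feature_map(feature_map(matrix(0, 20, 20), "gabor-F"), op,
                           normalize = FALSE)
  expect_true(all(z$values == 0))
  cst <- ordinal_feature_map(feature_map(matrix(0.7, 20, 20), "gabor-F"),
                             op, normalize = FALSE)
  expect_lt(max(abs(cst$values)), 1e-6)
})

test_that("impulse response reproduces the (symmetric) ordinal kernel", {
  op <- ordinal_params()
  k2 <- gocao:::make_ordinal_kernel_2d(op)
  s <- (nrow(k2) - 1) / 2
  F0 <- matrix(0, 25, 25)
  F0[13, 13] <- 1
  S <- ordinal_feature_map(feature_map(F0, "gabor-F"), op,
                           normalize = FALSE)
  got <- S$values[(13 - s):(13 + s), (13 - s):(13 + s)]
  # the kernel is even-symmetric, so convolution == correlation here;
  # this pins down the convolution convention
  expect_equal(got, k2, tolerance = 1e-12)
})

test_that("the bank response is covariant with 90-degree rotation", {
  set.seed(5)
  img <- disk_image(48, 14) + 0.02 * matrix(rnorm(48 * 48), 48, 48)
  rot90 <- function(m) t(m)[, seq_len(nrow(m))][, rev(seq_len(nrow(m)))]
  f1 <- gabor_feature_map(img, normalize = FALSE)$values
  f2 <- gabor_feature_map(rot90(img), normalize = FALSE)$values
  expect_equal(f2, rot90(f1), tolerance = 1e-9)
})

test_that("feature map constructor validates input", {
  expect_error(feature_map(matrix(c(1, NA), 1, 2)), "finite")
  expect_error(gabor_feature_map(matrix(numeric(0), 0, 0)), "non-empty")
  expect_error(gabor_feature_map(matrix(1, 4, 4), bank = list()), "empty")
})
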