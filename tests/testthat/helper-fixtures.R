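# Shared fixtures, built in code.

# filled disk of radius r centred in an n x n frame
disk_image <- function(n = 96, r = 28, value = 0.9) {
  X <- matrix(0:(n - 1), n, n, byrow = TRUE)
  Y <- matrix(0:(n - 1), n, n)
  img <- matrix(0, n, n)
  img[sqrt((X - (n - 1) / 2)^2 + (Y - (n - 1) / 2)^2) < r] <- value
  img
}

# axis-aligned filled square, corners at (lo, lo) .. (hi, hi) (0-based)
square_image <- function(n = 128, lo = 40, hi = 87, value = 0.9) {
  img <- matrix(0, n, n)
  img[(lo + 1):(hi + 1), (lo + 1):(hi + 1)] <- value
  img
}

# two well-separated filled rectangles
two_rects_image <- function() {
  img <- matrix(0, 128, 128)
  img[21:51, 21:61] <- 0.8
  img[81:111, 61:111] <- 0.8
  img
}

# scene of three squares and one lobed blob, used for rotation equivariance
square_blob_scene <- function(n = 320) {
  X <- matrix(0:(n - 1), n, n, byrow = TRUE)
  Y <- matrix(0:(n - 1), n, n)
  img <- matrix(0.3, n, n)
  img[X >= 40 & X <= 135 & Y >= 40 & Y <= 125] <- 0.85
  img[X >= 185 & X <= 280 & Y >= 55 & Y <= 140] <- 0.75
  img[X >= 55 & X <= 140 & Y >= 185 & Y <= 275] <- 0.8
  a <- atan2(Y - 225, X - 230)
  img[sqrt((X - 230)^2 + (Y - 225)^2) < 42 + 10 * cos(4 * a + 0.6)] <- 0.7
  img
}

# rotate a scene about its centre by `deg` (bilinear, constant fill);
# returns the image and the forward point map original -> rotated
rotate_scene <- function(img, deg, fill = 0.3) {
  th <- deg * pi / 180
  ctr <- (nrow(img) - 1) / 2   # square images only
  bwd <- similarity_transform(1, -th,
                              ctr - (cos(-th) * ctr - sin(-th) * ctr),
                              ctr - (sin(-th) * ctr + cos(-th) * ctr))
  fwd <- similarity_transform(1, th,
                              ctr - (cos(th) * ctr - sin(th) * ctr),
                              ctr - (sin(th) * ctr + cos(th) * ctr))
  list(image = warp_image(img, bwd, fill = fill), forward = fwd)
}

# naive quadruple-loop 2-D convolution with reflected (symmetric) borders —
# independent oracle for the FFT path
naive_conv2_reflect <- function(img, k) {
  nr <- nrow(img); nc <- ncol(img)
  kr <- (nrow(k) - 1) / 2; kc <- (ncol(k) - 1) / 2
  refl <- function(i, n) {          # symmetric reflection, edge included
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0
    for (u in -kr:kr) for (v in -kc:kc) {
      acc <- acc + img[refl(i - u, nr), refl(j - v, nc)] *
        k[u + kr + 1, v + kc + 1]
    }
    out[i, j] <- acc
  }
  out
}

# circular angular difference in degrees
circ_diff_deg <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

# match keypoints of a rotated scene to the originals through the known
# forward map and return the circular orientation errors (degrees)
equivariance_errors <- function(kp1, kp2, fwd, deg, pair_radius = 6) {
  proj <- transform_points(fwd, cbind(kp1$x, kp1$y))
  errs <- c()
  for (i in seq_len(nrow(kp1))) {
    d2 <- (kp2$x - proj[i, 1])^2 + (kp2$y - proj[i, 2])^2
    j <- which.min(d2)
    if (d2[j] <= pair_radius^2) {
      errs <- c(errs,
                circ_diff_deg((kp1$orientation[i] * 180 / pi + deg) %% 360,
                              kp2$orientation[j] * 180 / pi))
    }
  }
  errs
}
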