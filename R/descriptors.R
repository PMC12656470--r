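# Modified-SIFT descriptors on the contour feature maps: gradient
# orientations are folded modulo pi (8 bins over [0, pi)) so that a
# contrast reversal between modalities leaves the descriptor unchanged,
# and magnitudes are normalized to tame spectrum-dependent contrast.

#' Folded gradient field of a feature map
#'
#' Central-difference gradients with angles folded modulo `pi` (opposite
#' gradient directions merge — the 16-to-8-bin reduction) and magnitudes
#' divided by their 99th percentile, clamped to 1.
#'
#' @param map A `feature_map` or numeric matrix.
#' @return List with `magnitude`, `angle` (in `[0, pi)`), and the raw
#'   components `gx`, `gy`.
#' @export
folded_gradients <- function(map) {
  v <- if (inherits(map, "feature_map")) map$values else map
  nr <- nrow(v); nc <- ncol(v)
  # central differences, replicated border
  left <- v[, c(1, seq_len(nc - 1)), drop = FALSE]
  right <- v[, c(seq_len(nc - 1) + 1, nc), drop = FALSE]
  up <- v[c(1, seq_len(nr - 1)), , drop = FALSE]
  down <- v[c(seq_len(nr - 1) + 1, nr), , drop = FALSE]
  gx <- (right - left) / 2
  gy <- (down - up) / 2
  mag <- sqrt(gx^2 + gy^2)
  q99 <- stats::quantile(mag, 0.99, names = FALSE)
  if (q99 > 0) mag <- pmin(mag / q99, 1)
  ang <- atan2(gy, gx) %% pi
  list(magnitude = mag, angle = ang, gx = gx, gy = gy)
}

# Bilinear sampling of matrix m at 0-based coordinates (x, y); out-of-range
# coordinates are clamped to the border.
bilinear_sample <- function(m, x, y) {
  nr <- nrow(m); nc <- ncol(m)
  x <- pmin(pmax(x, 0), nc - 1)
  y <- pmin(pmax(y, 0), nr - 1)
  x0 <- floor(x); y0 <- floor(y)
  x1 <- pmin(x0 + 1, nc - 1); y1 <- pmin(y0 + 1, nr - 1)
  fx <- x - x0; fy <- y - y0
  i00 <- y0 + 1 + x0 * nr; i10 <- y0 + 1 + x1 * nr
  i01 <- y1 + 1 + x0 * nr; i11 <- y1 + 1 + x1 * nr
  m[i00] * (1 - fx) * (1 - fy) + m[i10] * fx * (1 - fy) +
    m[i01] * (1 - fx) * fy + m[i11] * fx * fy
}

# Core descriptor computation from precomputed gradient fields.
# Returns a unit-norm length-128 vector, or NULL for flat/out-of-map patches.
msift_from_gradients <- function(grads, nr, nc, x, y, orientation, radius,
                                 clamp = 0.2) {
  margin <- ceiling(radius * sqrt(2)) + 1
  if (x < margin || y < margin || x > nc - 1 - margin || y > nr - 1 - margin)
    return(NULL)
  # sample grid in the keypoint frame (orientation O mapped to +x)
  u <- seq(-radius + 0.5, radius - 0.5, by = 1)
  U <- matrix(u, 2 * radius, 2 * radius, byrow = TRUE)
  V <- matrix(u, 2 * radius, 2 * radius)
  co <- cos(orientation); si <- sin(orientation)
  px <- x + co * U - si * V
  py <- y + si * U + co * V
  gx <- bilinear_sample(grads$gx, px, py)
  gy <- bilinear_sample(grads$gy, px, py)
  mag <- sqrt(gx^2 + gy^2)
  q99 <- attr(grads, "q99")
  if (!is.null(q99) && q99 > 0) mag <- pmin(mag / q99, 1)
  w <- as.vector(mag * exp(-(U^2 + V^2) / (2 * radius^2)))
  if (sum(w) < 1e-12) return(NULL)
  ang <- (atan2(gy, gx) - orientation) %% pi   # folded, relative to O
  # cell coordinates in [−0.5, 3.5] and orientation bin in [0, 8)
  cellw <- (2 * radius) / 4
  cx <- as.vector((U + radius) / cellw - 0.5)
  cy <- as.vector((V + radius) / cellw - 0.5)
  ob <- as.vector(ang) / (pi / 8)
  hist <- numeric(128)
  x0 <- floor(cx); y0 <- floor(cy); o0 <- floor(ob)
  fx <- cx - x0; fy <- cy - y0; fo <- ob - o0
  idx_all <- integer(0); w_all <- numeric(0)
  for (dx in 0:1) for (dy in 0:1) for (do in 0:1) {
    xi <- x0 + dx; yi <- y0 + dy
    oi <- (o0 + do) %% 8
    wt <- w * (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
      (if (do) fo else 1 - fo)
    ok <- xi >= 0 & xi <= 3 & yi >= 0 & yi <= 3 & wt > 0
    if (!any(ok)) next
    idx_all <- c(idx_all, (yi[ok] * 4 + xi[ok]) * 8 + oi[ok] + 1)
    w_all <- c(w_all, wt[ok])
  }
  if (length(idx_all)) {
    agg <- rowsum(w_all, idx_all)
    hist[as.integer(rownames(agg))] <- agg[, 1]
  }
  nrm <- sqrt(sum(hist^2))
  if (nrm < 1e-12) return(NULL)
  hist <- pmin(hist / nrm, clamp)
  nrm <- sqrt(sum(hist^2))
  if (nrm < 1e-12) return(NULL)
  hist / nrm
}

#' MSIFT descriptor of one keypoint
#'
#' Samples a `(2 * patch_radius)^2` patch rotated so the keypoint's main
#' orientation maps to +x, accumulates a 4 x 4 x 8 histogram of folded
#' gradient angles (relative to the orientation, modulo `pi`, 8 bins of
#' `pi/8`) weighted by magnitude and a Gaussian spatial window, with
#' trilinear interpolation across cells and bins; components are clamped at
#' 0.2 and the vector renormalized to unit L2 norm.
#'
#' @param map A `feature_map` or matrix.
#' @param keypoint One-row keypoint data frame (needs `x`, `y`,
#'   `orientation`), as produced by [detect_and_orient()].
#' @param patch_radius Patch radius in pixels.
#' @return Length-128 unit vector, or `NULL` when the patch leaves the map
#'   or is flat.
#' @export
describe <- function(map, keypoint, patch_radius = 8) {
  v <- if (inherits(map, "feature_map")) map$values else map
  grads <- folded_gradients(v)
  attr(grads, "q99") <- stats::quantile(sqrt(grads$gx^2 + grads$gy^2),
                                        0.99, names = FALSE)
  msift_from_gradients(grads, nrow(v), ncol(v),
                       keypoint$x[1], keypoint$y[1],
                       keypoint$orientation[1], patch_radius)
}

#' MSIFT descriptors for a keypoint set
#'
#' One descriptor per (keypoint, scale); keypoints whose patch leaves the
#' map or is flat are skipped. Gradients are computed once per map.
#'
#' @param map A `feature_map` or matrix.
#' @param keypoints Keypoint data frame from [detect_and_orient()].
#' @param scales Patch radii in pixels (multi-scale for the visible image,
#'   a single radius for the infrared image).
#' @return List with `vectors` (n x 128 matrix) and `info` (data frame:
#'   `keypoint` row index, `x`, `y`, `orientation`, `scale`).
#' @export
describe_all <- function(map, keypoints, scales = c(8, 16, 24)) {
  v <- if (inherits(map, "feature_map")) map$values else map
  grads <- folded_gradients(v)
  attr(grads, "q99") <- stats::quantile(sqrt(grads$gx^2 + grads$gy^2),
                                        0.99, names = FALSE)
  vecs <- list(); info <- list()
  if (nrow(keypoints)) {
    for (i in seq_len(nrow(keypoints))) {
      for (r in scales) {
        d <- msift_from_gradients(grads, nrow(v), ncol(v),
                                  keypoints$x[i], keypoints$y[i],
                                  keypoints$orientation[i], r)
        if (is.null(d)) next
        vecs[[length(vecs) + 1L]] <- d
        info[[length(info) + 1L]] <-
          data.frame(keypoint = i, x = keypoints$x[i], y = keypoints$y[i],
                     orientation = keypoints$orientation[i], scale = r)
      }
    }
  }
  if (length(vecs) == 0L)
    return(list(vectors = matrix(numeric(0), 0, 128),
                info = data.frame(keypoint = integer(0), x = numeric(0),
                                  y = numeric(0), orientation = numeric(0),
                                  scale = numeric(0))))
  list(vectors = do.call(rbind, vecs), info = do.call(rbind, info))
}
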