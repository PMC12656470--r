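# Ground-truthed synthetic visible/infrared pair generator. Emulates the
# acquisition regime of a co-mounted visible + thermal camera: a shared
# contour-rich scene of smooth closed body-like shapes, rendered at
# 640 x 480 for the visible channel and — through a planted similarity
# transform, a reversed monotone intensity map, heavy blur and 8x
# downsampling — at 80 x 60 for the infrared channel.

#' Specification of a synthetic visible/infrared scene pair
#'
#' @param seed Integer seed; all randomness of the generator flows from it.
#' @param scene_size Visible frame `c(width, height)` in px.
#' @param ir_size Infrared frame `c(width, height)` in px; the
#'   width/height ratios to the visible frame must agree.
#' @param s,phi,tx,ty Planted similarity between frames beyond the
#'   resolution ratio (applied in the visible frame).
#' @param illumination_level Illumination group 1 (darkest) to 4
#'   (brightest, saturating); see [illumination_schedule()].
#' @param blob_count Number of smooth closed shapes.
#' @param texture_amp Amplitude of the smooth background texture.
#' @param noise_sigma Gaussian noise s.d. of the visible image.
#' @param ir_noise_sigma Gaussian noise s.d. of the infrared image.
#' @param ir_blur_sigma Gaussian blur s.d. (visible-frame px) applied to the
#'   scene before it is sampled onto the infrared grid (anti-aliasing plus
#'   thermal diffusion).
#' @param intensity_map_ir `"reversed"` (default; contrast-reversed monotone
#'   map), `"identity"`, or a vectorized monotone function on `[0, 1]`.
#' @return A validated `scene_pair_spec` object.
#' @export
scene_pair_spec <- function(seed = 1L,
                            scene_size = c(640L, 480L),
                            ir_size = c(80L, 60L),
                            s = 1.05, phi = 0.05, tx = 6, ty = -4,
                            illumination_level = 2L,
                            blob_count = 4L,
                            texture_amp = 0.06,
                            noise_sigma = 0.01,
                            ir_noise_sigma = 0.02,
                            ir_blur_sigma = 3.5,
                            intensity_map_ir = "reversed") {
  if (any(scene_size < 8) || any(ir_size < 8))
    stop("scene_pair_spec: frame sizes too small", call. = FALSE)
  kx <- scene_size[1] / ir_size[1]
  ky <- scene_size[2] / ir_size[2]
  if (abs(kx - ky) > 1e-9)
    stop("scene_pair_spec: visible/IR size ratios must agree", call. = FALSE)
  if (s <= 0) stop("scene_pair_spec: s must be positive", call. = FALSE)
  if (!illumination_level %in% 1:4)
    stop("scene_pair_spec: illumination_level must be in 1..4",
         call. = FALSE)
  if (blob_count < 1)
    stop("scene_pair_spec: blob_count must be >= 1", call. = FALSE)
  if (noise_sigma < 0 || ir_noise_sigma < 0 || ir_blur_sigma < 0)
    stop("scene_pair_spec: noise/blur parameters must be >= 0",
         call. = FALSE)
  structure(list(seed = as.integer(seed), scene_size = as.integer(scene_size),
                 ir_size = as.integer(ir_size),
                 s = s, phi = phi, tx = tx, ty = ty,
                 illumination_level = as.integer(illumination_level),
                 blob_count = as.integer(blob_count),
                 texture_amp = texture_amp, noise_sigma = noise_sigma,
                 ir_noise_sigma = ir_noise_sigma,
                 ir_blur_sigma = ir_blur_sigma,
                 intensity_map_ir = intensity_map_ir,
                 resolution_ratio = kx),
            class = "scene_pair_spec")
}

#' Illumination schedule
#'
#' Maps an illumination group 1..4 to photometric parameters
#' `(gain, offset, gamma)` applied to the visible rendering as
#' `clip(gain * v^gamma + offset)`. Level 1 is darkest; level 3 is the
#' neutral identity; level 4 is over-bright with a compressive gamma, so
#' highlights saturate.
#'
#' @param level Integer in 1..4.
#' @return List with `gain`, `offset`, `gamma`.
#' @export
illumination_schedule <- function(level) {
  if (!length(level) == 1L || !level %in% 1:4)
    stop("illumination_schedule: level must be one of 1..4", call. = FALSE)
  switch(level,
         list(gain = 0.45, offset = 0.00, gamma = 1.5),
         list(gain = 0.75, offset = 0.02, gamma = 1.2),
         list(gain = 1.00, offset = 0.00, gamma = 1.0),
         list(gain = 1.40, offset = 0.08, gamma = 0.7))
}

# Fourier-perturbed ellipse radius at polar angle(s) ang.
blob_radius <- function(blob, ang) {
  r <- rep(1, length(ang))
  for (i in seq_along(blob$harm_k))
    r <- r + blob$harm_a[i] * cos(blob$harm_k[i] * ang + blob$harm_psi[i])
  blob$r0 * r
}

# Sample the random shapes of a scene. Each blob is a star-shaped
# Fourier-perturbed ellipse. The guaranteed strong 4th harmonic produces at
# least 4 pronounced curvature maxima per shape, and the 7th-harmonic term
# sharpens them further — animal-body silhouettes carry limb- and ear-like
# protrusions whose corner curvature is well above that of a bare ellipse.
sample_blobs <- function(spec) {
  w <- spec$scene_size[1]; h <- spec$scene_size[2]
  lapply(seq_len(spec$blob_count), function(b) {
    list(cx = stats::runif(1, 0.22 * w, 0.78 * w),
         cy = stats::runif(1, 0.22 * h, 0.78 * h),
         r0 = stats::runif(1, 0.09, 0.15) * min(w, h),
         harm_k = c(2, 3, 4, 5, 7),
         harm_a = c(stats::runif(1, -0.08, 0.08),
                    stats::runif(1, -0.06, 0.06),
                    sample(c(-1, 1), 1) * stats::runif(1, 0.12, 0.18),
                    stats::runif(1, -0.05, 0.05),
                    sample(c(-1, 1), 1) * stats::runif(1, 0.02, 0.05)),
         harm_psi = stats::runif(5, 0, 2 * pi),
         intensity = stats::runif(1, 0.70, 0.85))
  })
}

# Render the clean (pre-illumination, pre-noise) scene in the visible frame.
render_scene <- function(spec, blobs) {
  w <- spec$scene_size[1]; h <- spec$scene_size[2]
  # smooth background texture from a coarse random grid
  gw <- max(4L, ceiling(w / 40)); gh <- max(4L, ceiling(h / 40))
  coarse <- matrix(stats::runif(gh * gw), gh, gw)
  tx <- (0:(w - 1)) * (gw - 1) / (w - 1)
  ty <- (0:(h - 1)) * (gh - 1) / (h - 1)
  texture <- bilinear_sample(coarse,
                             rep(tx, each = h), rep(ty, times = w))
  scene <- matrix(0.35 + spec$texture_amp * (2 * texture - 1), h, w)
  X <- matrix(0:(w - 1), h, w, byrow = TRUE)
  Y <- matrix(0:(h - 1), h, w)
  for (blob in blobs) {
    dx <- X - blob$cx; dy <- Y - blob$cy
    d <- sqrt(dx^2 + dy^2)
    ang <- atan2(dy, dx)
    rr <- blob_radius(blob, ang)
    cov <- pmin(pmax((rr - d) / 1.5 + 0.5, 0), 1)  # 1.5-px soft edge
    scene <- scene * (1 - cov) + blob$intensity * cov
  }
  pmin(pmax(scene, 0), 1)
}

# Monotone IR intensity remap.
ir_remap <- function(v, map) {
  if (is.function(map)) return(map(v))
  switch(map,
         reversed = 1 - v^0.9,
         identity = v,
         stop("generate_pair: unknown intensity_map_ir", call. = FALSE))
}

#' Generate a ground-truthed synthetic visible/infrared pair
#'
#' Renders smooth closed shapes on a textured background; the visible image
#' adds the illumination schedule and Gaussian noise; the infrared image is
#' the planted-transform-warped scene after a monotone (by default
#' contrast-reversed) intensity remap, heavy blur and downsampling to the
#' infrared grid, plus its own noise. Deterministic given `spec$seed`.
#'
#' @param spec A [scene_pair_spec()].
#' @return List with `visible` (h x w matrix), `ir` (IR-sized matrix), and
#'   `truth`: `transform` (`similarity_transform` mapping native IR
#'   coordinates to visible coordinates, resolution ratio included),
#'   `transform_extra` (the planted part beyond the resolution ratio),
#'   `resolution_ratio`, `control_points` (data frame `vis_x`, `vis_y`,
#'   `ir_x`, `ir_y` on shape contours), `keypoint_truth` (true curvature
#'   maxima of the shapes, visible frame).
#' @export
generate_pair <- function(spec) {
  stopifnot(inherits(spec, "scene_pair_spec"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(spec$seed)
  w <- spec$scene_size[1]; h <- spec$scene_size[2]
  iw <- spec$ir_size[1]; ih <- spec$ir_size[2]
  k <- spec$resolution_ratio
  cshift <- (k - 1) / 2
  blobs <- sample_blobs(spec)
  scene <- render_scene(spec, blobs)

  il <- illumination_schedule(spec$illumination_level)
  visible <- il$gain * scene^il$gamma + il$offset
  if (spec$noise_sigma > 0)
    visible <- visible + matrix(stats::rnorm(h * w, 0, spec$noise_sigma),
                                h, w)
  visible <- pmin(pmax(visible, 0), 1)

  # full composite transform: native IR -> visible
  tf_extra <- similarity_transform(spec$s, spec$phi, spec$tx, spec$ty)
  tf_scale <- similarity_transform(k, 0, cshift, cshift)
  tf_full <- compose_transforms(tf_extra, tf_scale)

  blurred <- if (spec$ir_blur_sigma > 0)
    as.matrix(EBImage::gblur(scene, sigma = spec$ir_blur_sigma))
  else scene
  qx <- matrix(0:(iw - 1), ih, iw, byrow = TRUE)
  qy <- matrix(0:(ih - 1), ih, iw)
  p <- transform_points(tf_full, cbind(as.vector(qx), as.vector(qy)))
  ir <- matrix(bilinear_sample(blurred, p[, 1], p[, 2]), ih, iw)
  ir <- ir_remap(ir, spec$intensity_map_ir)
  if (spec$ir_noise_sigma > 0)
    ir <- ir + matrix(stats::rnorm(ih * iw, 0, spec$ir_noise_sigma), ih, iw)
  ir <- pmin(pmax(ir, 0), 1)

  truth <- list(transform = tf_full, transform_extra = tf_extra,
                resolution_ratio = k,
                control_points = control_points(blobs, tf_full, w, h,
                                                iw, ih),
                keypoint_truth = keypoint_truth(blobs))
  list(visible = visible, ir = ir, truth = truth)
}

# Paired contour control points: samples on each blob boundary that lie
# inside both frames; the pairing is exact by construction.
control_points <- function(blobs, tf_full, w, h, iw, ih, per_blob = 12L) {
  inv <- invert_transform(tf_full)
  out <- list()
  for (blob in blobs) {
    ang <- seq(0, 2 * pi, length.out = per_blob + 1L)[seq_len(per_blob)]
    r <- blob_radius(blob, ang)
    px <- blob$cx + r * cos(ang)
    py <- blob$cy + r * sin(ang)
    q <- transform_points(inv, cbind(px, py))
    ok <- px >= 2 & px <= w - 3 & py >= 2 & py <= h - 3 &
      q[, 1] >= 1 & q[, 1] <= iw - 2 & q[, 2] >= 1 & q[, 2] <= ih - 2
    if (any(ok))
      out[[length(out) + 1L]] <-
        data.frame(vis_x = px[ok], vis_y = py[ok],
                   ir_x = q[ok, 1], ir_y = q[ok, 2])
  }
  if (length(out) == 0L)
    return(data.frame(vis_x = numeric(0), vis_y = numeric(0),
                      ir_x = numeric(0), ir_y = numeric(0)))
  do.call(rbind, out)
}

# True corner locations: curvature maxima of each blob boundary.
keypoint_truth <- function(blobs, n_samples = 720L) {
  out <- list()
  for (b in seq_along(blobs)) {
    blob <- blobs[[b]]
    ang <- seq(0, 2 * pi, length.out = n_samples + 1L)[seq_len(n_samples)]
    r <- blob_radius(blob, ang)
    xs <- blob$cx + r * cos(ang)
    ys <- blob$cy + r * sin(ang)
    kap <- abs(chain_curvature(xs, ys, closed = TRUE))
    prev <- c(kap[n_samples], kap[-n_samples])
    nxt <- c(kap[-1], kap[1])
    pk <- which(kap > prev & kap >= nxt)
    if (length(pk))
      out[[length(out) + 1L]] <-
        data.frame(x = xs[pk], y = ys[pk], blob = b,
                   curvature = kap[pk])
  }
  if (length(out) == 0L)
    return(data.frame(x = numeric(0), y = numeric(0), blob = integer(0),
                      curvature = numeric(0)))
  do.call(rbind, out)
}
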