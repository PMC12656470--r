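# End-to-end registration of a visible / infrared image pair.

# Upsample the IR image onto the visible grid. With resolution ratio k and
# pixel centres at integer coordinates, upsampled pixel p corresponds to
# native IR coordinate (p - c) / k with c = (k - 1) / 2 (block-centre
# alignment); the same constants convert coordinates back.
upsample_ir <- function(ir, vis_dim, k) {
  cshift <- (k - 1) / 2
  nr <- vis_dim[1]; nc <- vis_dim[2]
  xs <- (rep(0:(nc - 1), each = nr) - cshift) / k
  ys <- (rep(0:(nr - 1), times = nc) - cshift) / k
  # clamped sampling: the half-pixel rim outside the source grid replicates
  # the edge instead of injecting a spurious dark frame contour
  matrix(bilinear_sample(ir, xs, ys), nr, nc)
}

# Smoothed contour-energy map: |S| blurred so the two modalities' band-pass
# fine structure (which is spectrum-specific) is averaged out and only the
# shared contour layout remains. This is the surface descriptors match on.
contour_energy_map <- function(S, smooth) {
  v <- if (inherits(S, "feature_map")) S$values else S
  e <- abs(v)
  if (smooth > 0) e <- as.matrix(EBImage::gblur(e, sigma = smooth))
  feature_map(normalize_map(e), kind = "raw")
}

#' Register a visible / infrared image pair
#'
#' Full rough-to-fine pipeline. The IR image is bilinearly upsampled to the
#' visible grid; contour feature maps are built for both images (Gabor bank
#' then ordinal filter); contour chains are extracted and sampled into
#' dense keypoints with angular-bisector orientations (CSS corners are also
#' detected and reported); MSIFT descriptors computed on the smoothed
#' contour-energy maps are matched bilaterally under a spatial guide
#' radius; a similarity transform is estimated by RANSAC with rig-prior
#' hypothesis gating; and the registration is refined by normal-constrained
#' |ZNCC| search on the intensity images. The resolution ratio is composed
#' into the reported transform, which maps native IR coordinates to visible
#' coordinates.
#'
#' @param visible,infrared Numeric matrices in `[0, 1]` (or file paths read
#'   with [read_image()]). The visible image is the higher-resolution one.
#' @param config Pipeline configuration, see [default_config()].
#' @param truth Optional ground truth (from [generate_pair()]); when given,
#'   a [metric_report()] is attached.
#' @return A `registration_result`: `transform` (native IR to visible),
#'   `transform_upsampled` (upsampled-IR frame to visible),
#'   `resolution_ratio`, `matches` (all stages, native IR coordinates plus
#'   `ir_up_x`/`ir_up_y`), `keypoints_vis`, `keypoints_ir` (CSS corners;
#'   native coords plus `x_up`/`y_up`), `counts` per stage, `refinement`
#'   (mean normal residual before/after), and `metrics` (or `NULL`).
#' @export
register_pair <- function(visible, infrared, config = default_config(),
                          truth = NULL) {
  if (is.character(visible)) visible <- read_image(visible)
  if (is.character(infrared)) infrared <- read_image(infrared)
  if (!is.matrix(visible) || !is.matrix(infrared) ||
      length(visible) == 0L || length(infrared) == 0L)
    stop("register_pair: inputs must be non-empty single-channel matrices",
         call. = FALSE)
  kx <- ncol(visible) / ncol(infrared)
  ky <- nrow(visible) / nrow(infrared)
  if (abs(kx - ky) / kx > 0.05)
    stop("register_pair: inconsistent visible/IR aspect ratios",
         call. = FALSE)
  k <- sqrt(kx * ky)
  cshift <- (k - 1) / 2
  say <- function(...) if (isTRUE(config$verbose)) message(sprintf(...))

  ir_up <- upsample_ir(infrared, dim(visible), k)
  bank <- config_gabor_bank(config)
  op <- config_ordinal_params(config)
  S_vis <- ordinal_feature_map(gabor_feature_map(visible, bank), op)
  S_ir <- ordinal_feature_map(gabor_feature_map(ir_up, bank), op)

  cc <- config$contours
  get_contours <- function(S)
    extract_contours(S, threshold = cc$threshold,
                     min_length = cc$min_length, spur_prune = cc$spur_prune,
                     chain_strength = cc$chain_strength,
                     ridge_smooth = cc$ridge_smooth,
                     min_response = cc$min_response,
                     close_gaps = cc$close_gaps)
  ct_vis <- get_contours(S_vis)
  ct_ir <- get_contours(S_ir)
  kp_vis <- detect_and_orient(ct_vis, config)
  kp_ir <- detect_and_orient(ct_ir, config)
  dk_vis <- dense_keypoints(ct_vis, config)
  dk_ir <- dense_keypoints(ct_ir, config)
  say("keypoints: visible %d corners + %d dense, infrared %d corners + %d dense",
      nrow(kp_vis), nrow(dk_vis), nrow(kp_ir), nrow(dk_ir))
  if (nrow(dk_vis) == 0L || nrow(dk_ir) == 0L)
    stop_registration("keypoints", "no contour keypoints detected",
                      n_vis = nrow(dk_vis), n_ir = nrow(dk_ir))

  E_vis <- contour_energy_map(S_vis, config$descriptors$smooth)
  E_ir <- contour_energy_map(S_ir, config$descriptors$smooth)
  mk_vis <- dk_vis; mk_ir <- dk_ir
  if (!isTRUE(config$descriptors$align)) {
    mk_vis$orientation <- 0
    mk_ir$orientation <- 0
  }
  d_vis <- describe_all(E_vis, mk_vis, scales = config$descriptors$vis_scales)
  d_ir <- describe_all(E_ir, mk_ir, scales = config$descriptors$ir_scale)
  say("descriptors: visible %d, infrared %d",
      nrow(d_vis$vectors), nrow(d_ir$vectors))
  if (nrow(d_vis$vectors) == 0L || nrow(d_ir$vectors) == 0L)
    stop_registration("descriptors", "no descriptors survive",
                      n_vis = nrow(d_vis$vectors), n_ir = nrow(d_ir$vectors))

  m <- bilateral_match(d_ir, d_vis, ratio = config$descriptors$ratio,
                       search_radius = config$descriptors$search_radius)
  say("bilateral matches: %d", nrow(m))
  if (nrow(m) < 2L)
    stop_registration("bilateral", "fewer than 2 bilateral matches",
                      n_matches = nrow(m))

  rc <- config$ransac
  rs <- ransac_similarity(m, inlier_tol = rc$inlier_tol,
                          iterations = rc$iterations, seed = rc$seed,
                          scale_range = rc$scale_range,
                          max_rotation = rc$max_rotation,
                          max_translation = rc$max_translation,
                          min_sample_sep = rc$min_sample_sep)
  say("rough inliers: %d (ok = %s)", rs$n_inliers, rs$ok)
  if (!rs$ok)
    stop_registration("ransac", "consensus below 4 inliers",
                      n_inliers = rs$n_inliers)

  fine <- refine_matches(rs, dk_ir, ir_up, visible,
                         window = config$refine$window,
                         iterations = config$refine$iterations,
                         patch_radius = config$refine$patch_radius,
                         min_cc = config$refine$min_cc)
  say("fine: mean normal residual %.3f -> %.3f px",
      fine$mean_error_before, fine$mean_error_after)

  tf_up <- fine$transform
  t_comp <- transform_points(tf_up, c(cshift, cshift))
  tf_full <- similarity_transform(tf_up$s * k, tf_up$phi,
                                  t_comp[1], t_comp[2])

  matches <- fine$matches
  matches$ir_up_x <- matches$ir_x
  matches$ir_up_y <- matches$ir_y
  matches$ir_x <- (matches$ir_up_x - cshift) / k
  matches$ir_y <- (matches$ir_up_y - cshift) / k

  to_native <- function(kp) {
    if (nrow(kp) == 0L) return(kp)
    kp$x_up <- kp$x
    kp$y_up <- kp$y
    kp$x <- (kp$x_up - cshift) / k
    kp$y <- (kp$y_up - cshift) / k
    kp
  }
  kp_ir <- to_native(kp_ir)
  dk_ir_native <- to_native(dk_ir)

  result <- structure(list(
    transform = tf_full,
    transform_upsampled = tf_up,
    resolution_ratio = k,
    matches = matches,
    keypoints_vis = kp_vis,
    keypoints_ir = kp_ir,
    dense_vis = dk_vis,
    dense_ir = dk_ir_native,
    counts = list(keypoints_vis = nrow(kp_vis), keypoints_ir = nrow(kp_ir),
                  dense_vis = nrow(dk_vis), dense_ir = nrow(dk_ir),
                  descriptors_vis = nrow(d_vis$vectors),
                  descriptors_ir = nrow(d_ir$vectors),
                  bilateral = sum(matches$stage != "fine"),
                  rough = rs$n_inliers,
                  fine = sum(matches$stage == "fine")),
    refinement = list(mean_error_before = fine$mean_error_before,
                      mean_error_after = fine$mean_error_after),
    metrics = NULL), class = "registration_result")
  if (!is.null(truth))
    result$metrics <- metric_report(result, truth,
                                    radius = config$metrics$radius)
  result
}

#' @export
print.registration_result <- function(x, ...) {
  cat("<registration_result>\n")
  print(x$transform)
  cat(sprintf("  resolution ratio: %.3f\n", x$resolution_ratio))
  cat(sprintf(
    "  corners %d/%d, dense %d/%d, bilateral %d, rough %d, fine %d\n",
    x$counts$keypoints_vis, x$counts$keypoints_ir,
    x$counts$dense_vis, x$counts$dense_ir,
    x$counts$bilateral, x$counts$rough, x$counts$fine))
  cat(sprintf("  refinement: %.3f -> %.3f px\n",
              x$refinement$mean_error_before, x$refinement$mean_error_after))
  if (!is.null(x$metrics)) print(x$metrics)
  invisible(x)
}

#' Compare contour-keypoint orientations on Gabor-ordinal maps versus raw
#' images
#'
#' Runs the keypoint detection and bisector orientation stage twice on a
#' ground-truthed pair — once on the Gabor-ordinal contour feature maps and
#' once directly on the raw images — and reports, for each route, the
#' keypoint counts and the number of cross-modality keypoint pairs whose
#' orientations agree (circular error below `tol_deg` after removing the
#' planted rotation). Keypoints are paired through the ground-truth
#' transform (nearest visible keypoint within `pair_radius` px). Both CSS
#' corners and dense contour keypoints enter the comparison.
#'
#' @param visible,infrared Image matrices.
#' @param truth Ground truth from [generate_pair()].
#' @param config Pipeline configuration.
#' @param pair_radius Keypoint pairing radius in visible-frame px.
#' @param tol_deg Orientation agreement tolerance, degrees (strict).
#' @return Data frame with one row per route (`"gabor-ordinal"`, `"raw"`):
#'   `n_keypoints_vis`, `n_keypoints_ir`, `n_paired`, `n_agree`.
#' @export
orient_compare <- function(visible, infrared, truth,
                           config = default_config(), pair_radius = 3,
                           tol_deg = 5) {
  k <- truth$resolution_ratio
  cshift <- (k - 1) / 2
  ir_up <- upsample_ir(infrared, dim(visible), k)
  bank <- config_gabor_bank(config)
  op <- config_ordinal_params(config)
  routes <- list(
    "gabor-ordinal" = list(
      vis = ordinal_feature_map(gabor_feature_map(visible, bank), op),
      ir = ordinal_feature_map(gabor_feature_map(ir_up, bank), op)),
    "raw" = list(vis = feature_map(visible, kind = "raw"),
                 ir = feature_map(ir_up, kind = "raw")))
  cc <- config$contours
  all_kp <- function(S) {
    ct <- extract_contours(S, threshold = cc$threshold,
                           min_length = cc$min_length,
                           spur_prune = cc$spur_prune,
                           chain_strength = cc$chain_strength,
                           ridge_smooth = cc$ridge_smooth,
                           min_response = cc$min_response,
                           close_gaps = cc$close_gaps)
    a <- detect_and_orient(ct, config)
    b <- dense_keypoints(ct, config)
    cols <- c("x", "y", "orientation")
    unique(rbind(a[, cols, drop = FALSE], b[, cols, drop = FALSE]))
  }
  out <- list()
  for (nm in names(routes)) {
    kp_v <- all_kp(routes[[nm]]$vis)
    kp_i <- all_kp(routes[[nm]]$ir)
    n_pair <- 0L; n_agree <- 0L
    if (nrow(kp_v) > 0L && nrow(kp_i) > 0L) {
      native <- cbind((kp_i$x - cshift) / k, (kp_i$y - cshift) / k)
      proj <- transform_points(truth$transform, native)
      for (i in seq_len(nrow(proj))) {
        d2 <- (kp_v$x - proj[i, 1])^2 + (kp_v$y - proj[i, 2])^2
        j <- which.min(d2)
        if (d2[j] <= pair_radius^2) {
          n_pair <- n_pair + 1L
          a <- (kp_i$orientation[i] + truth$transform$phi) * 180 / pi
          b <- kp_v$orientation[j] * 180 / pi
          n_agree <- n_agree +
            orientation_agreement(a, b, tol_deg = tol_deg)
        }
      }
    }
    out[[nm]] <- data.frame(route = nm, n_keypoints_vis = nrow(kp_v),
                            n_keypoints_ir = nrow(kp_i),
                            n_paired = n_pair, n_agree = n_agree)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
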