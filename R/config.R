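# Pipeline configuration: defaults, YAML loading, validation.

#' Default pipeline configuration
#'
#' Nested list of every tunable parameter of the registration pipeline.
#' Units are pixels unless noted. Sections:
#' \describe{
#'   \item{gabor}{`orientations` (count over `[0, pi)`), `sigmas` (envelope
#'     scales), `gamma` (aspect ratio).}
#'   \item{ordinal}{`omega` (flank offset), `sigma_p`/`sigma_n` (lobe
#'     scales), `c_p` (positive coefficient; the negative one is balanced
#'     automatically).}
#'   \item{contours}{`threshold` (binarization quantile of `|S|`),
#'     `min_length`, `css_sigmas` (chain steps), `curvature_threshold`
#'     (1/px), `nms_sep` (steps), `arm_length` (steps, the [arm_vectors()]
#'     primitive), `arm_gap` / `arm_span` (standoff-chord arms used for
#'     corner main orientations),
#'     `dense_step` / `dense_arm` (chain sampling and arm length for the
#'     dense matching keypoints), `max_keypoints`.}
#'   \item{descriptors}{`vis_scales` (multi-scale patch radii, visible),
#'     `ir_scale` (single radius, infrared), `ratio` (nearest/second-nearest
#'     acceptance threshold), `smooth` (Gaussian sigma of the contour-energy
#'     map descriptors are computed on), `align` (rotate patches to the
#'     keypoint main orientation; off by default because the co-mounted rig
#'     leaves only a few degrees of true rotation, far less than the noise
#'     of per-point normal estimates), `search_radius` (guided-matching
#'     gate, px).}
#'   \item{ransac}{`iterations`, `inlier_tol` (px at visible scale), `seed`,
#'     and the rig-prior hypothesis gates `scale_range`, `max_rotation`
#'     (rad), `max_translation` (px), `min_sample_sep` (px).}
#'   \item{refine}{`window` (normal-search half-range, first iteration),
#'     `iterations`, `patch_radius` (correlation patch), `min_cc`
#'     (minimum |ZNCC|).}
#'   \item{metrics}{`radius` (correct-match radius, px).}
#' }
#' @return Named nested list.
#' @export
default_config <- function() {
  list(
    gabor = list(orientations = 8L, sigmas = c(2, 4, 8), gamma = 0.5),
    ordinal = list(omega = 2, sigma_p = 1, sigma_n = 1, c_p = 1),
    contours = list(threshold = 0.9, min_length = 10L,
                    spur_prune = 6L, chain_strength = 0.35,
                    ridge_smooth = 1.5, min_response = 0.2,
                    close_gaps = 3L,
                    css_sigmas = c(3, 6, 9), curvature_threshold = 0.05,
                    nms_sep = 5L, arm_length = 5L,
                    arm_gap = 8L, arm_span = 16L,
                    dense_step = 4L, dense_arm = 10L,
                    max_keypoints = 450L),
    descriptors = list(vis_scales = c(16, 24, 32), ir_scale = 24,
                       ratio = 0.95, smooth = 5, align = FALSE,
                       search_radius = 100),
    ransac = list(iterations = 4000L, inlier_tol = 4, seed = 42L,
                  scale_range = c(1 / 1.3, 1.3), max_rotation = 0.26,
                  max_translation = 150, min_sample_sep = 20),
    refine = list(window = 10L, iterations = 4L, patch_radius = 12L,
                  min_cc = 0.6),
    metrics = list(radius = 5),
    verbose = FALSE
  )
}

#' Load a pipeline configuration
#'
#' Starts from [default_config()], merges a YAML file (if given), then named
#' overrides. Unknown keys and out-of-range values are rejected with the
#' offending name.
#'
#' @param path Path to a YAML file, or `NULL` for defaults only.
#' @param overrides Named nested list of overrides applied last.
#' @return Validated configuration list.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path))
      stop(sprintf("load_config: no such file '%s'", path), call. = FALSE)
    file_cfg <- yaml::read_yaml(path)
    if (is.null(file_cfg)) file_cfg <- list()
    cfg <- merge_config(cfg, file_cfg, "")
  }
  if (length(overrides)) cfg <- merge_config(cfg, overrides, "")
  validate_config(cfg)
  cfg
}

merge_config <- function(base, upd, prefix) {
  if (length(upd) == 0L) return(base)
  nms <- names(upd)
  if (is.null(nms) || any(nms == ""))
    stop(sprintf("config error: unnamed entry under '%s'", prefix),
         call. = FALSE)
  for (nm in nms) {
    full <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (!nm %in% names(base))
      stop(sprintf("config error: unknown key '%s'", full), call. = FALSE)
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      if (!is.list(upd[[nm]]))
        stop(sprintf("config error: '%s' must be a section", full),
             call. = FALSE)
      base[[nm]] <- merge_config(base[[nm]], upd[[nm]], full)
    } else {
      base[[nm]] <- upd[[nm]]
    }
  }
  base
}

validate_config <- function(cfg) {
  chk <- function(ok, field, what) {
    if (!ok) stop(sprintf("config error: '%s' %s", field, what),
                  call. = FALSE)
  }
  chk(cfg$gabor$orientations >= 1, "gabor.orientations", "must be >= 1")
  chk(all(cfg$gabor$sigmas > 0), "gabor.sigmas", "must be positive")
  chk(cfg$gabor$gamma > 0, "gabor.gamma", "must be positive")
  chk(cfg$ordinal$omega > 0, "ordinal.omega", "must be positive")
  chk(cfg$ordinal$sigma_p > 0 && cfg$ordinal$sigma_n > 0,
      "ordinal.sigma_p/sigma_n", "must be positive")
  chk(cfg$contours$threshold > 0 && cfg$contours$threshold < 1,
      "contours.threshold", "must be in (0, 1)")
  chk(cfg$contours$min_length >= 2, "contours.min_length", "must be >= 2")
  chk(cfg$contours$spur_prune >= 0, "contours.spur_prune", "must be >= 0")
  chk(cfg$contours$ridge_smooth >= 0, "contours.ridge_smooth",
      "must be >= 0")
  chk(cfg$contours$min_response >= 0 && cfg$contours$min_response < 1,
      "contours.min_response", "must be in [0, 1)")
  chk(cfg$contours$close_gaps >= 0, "contours.close_gaps", "must be >= 0")
  chk(cfg$contours$chain_strength >= 0 && cfg$contours$chain_strength <= 1,
      "contours.chain_strength", "must be in [0, 1]")
  chk(all(cfg$contours$css_sigmas > 0), "contours.css_sigmas",
      "must be positive")
  chk(cfg$contours$curvature_threshold > 0, "contours.curvature_threshold",
      "must be positive")
  chk(cfg$contours$arm_length >= 1, "contours.arm_length", "must be >= 1")
  chk(cfg$contours$arm_gap >= 0, "contours.arm_gap", "must be >= 0")
  chk(cfg$contours$arm_span >= 1, "contours.arm_span", "must be >= 1")
  chk(cfg$contours$dense_step >= 1, "contours.dense_step", "must be >= 1")
  chk(cfg$contours$dense_arm >= 1, "contours.dense_arm", "must be >= 1")
  chk(cfg$contours$max_keypoints >= 1, "contours.max_keypoints",
      "must be >= 1")
  chk(all(cfg$descriptors$vis_scales >= 2), "descriptors.vis_scales",
      "must be >= 2")
  chk(cfg$descriptors$ir_scale >= 2, "descriptors.ir_scale", "must be >= 2")
  chk(cfg$descriptors$ratio > 0 && cfg$descriptors$ratio <= 1,
      "descriptors.ratio", "must be in (0, 1]")
  chk(cfg$descriptors$smooth >= 0, "descriptors.smooth", "must be >= 0")
  chk(cfg$descriptors$search_radius > 0, "descriptors.search_radius",
      "must be positive")
  chk(cfg$ransac$iterations >= 1, "ransac.iterations", "must be >= 1")
  chk(cfg$ransac$inlier_tol > 0, "ransac.inlier_tol", "must be positive")
  chk(length(cfg$ransac$scale_range) == 2L &&
        cfg$ransac$scale_range[1] >= 0 &&
        cfg$ransac$scale_range[2] > cfg$ransac$scale_range[1],
      "ransac.scale_range", "must be an increasing length-2 range")
  chk(cfg$ransac$max_rotation > 0, "ransac.max_rotation",
      "must be positive")
  chk(cfg$refine$window >= 1, "refine.window", "must be >= 1")
  chk(cfg$refine$iterations >= 1, "refine.iterations", "must be >= 1")
  chk(cfg$refine$patch_radius >= 1, "refine.patch_radius", "must be >= 1")
  chk(cfg$refine$min_cc >= 0 && cfg$refine$min_cc < 1, "refine.min_cc",
      "must be in [0, 1)")
  chk(cfg$metrics$radius > 0, "metric_radius", "must be positive")
  invisible(cfg)
}

# Ordinal filter parameters from the config section.
config_ordinal_params <- function(cfg) {
  o <- cfg$ordinal
  ordinal_params(
    positive_lobes = cbind(omega = 0, sigma = o$sigma_p),
    negative_lobes = cbind(omega = c(-o$omega, o$omega),
                           sigma = c(o$sigma_n, o$sigma_n)),
    c_p = o$c_p)
}

# Gabor bank from the config section.
config_gabor_bank <- function(cfg) {
  default_gabor_bank(orientations = cfg$gabor$orientations,
                     sigmas = cfg$gabor$sigmas, gamma = cfg$gabor$gamma)
}
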