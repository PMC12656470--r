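# Registration evaluation: RMSE, precision/recall under the 5-px
# correct-match rule, accuracy, and orientation agreement.

#' Root-mean-square registration error
#'
#' `sqrt(sum(||p_i - r_i||^2) / N)` over paired points.
#'
#' @param points,refs n x 2 matrices (columns x, y) of registered and
#'   reference coordinates.
#' @return RMSE in pixels.
#' @export
rmse_points <- function(points, refs) {
  points <- as.matrix(points); refs <- as.matrix(refs)
  if (nrow(points) != nrow(refs) || nrow(points) == 0L)
    stop("rmse_points: need equal, non-zero numbers of points", call. = FALSE)
  sqrt(sum((points - refs)^2) / nrow(points))
}

#' Precision and recall of a match set
#'
#' A match is correct when its Euclidean distance to the reference location
#' is at most `radius` (boundary included). Precision is correct/total;
#' recall is correct/`correspond_count`, where the denominator is the number
#' of keypoint correspondences available in principle (see
#' [correspond_count()]).
#'
#' @param points,refs n x 2 matrices of matched and reference coordinates.
#' @param correspond_count Number of corresponding feature points.
#' @param radius Correct-match radius, px (default 5).
#' @return List with `precision`, `recall` (NULL when its denominator is 0),
#'   `n_correct`, `n_matches`.
#' @export
precision_recall <- function(points, refs, correspond_count, radius = 5) {
  points <- as.matrix(points); refs <- as.matrix(refs)
  if (nrow(points) != nrow(refs))
    stop("precision_recall: length mismatch", call. = FALSE)
  n <- nrow(points)
  if (n == 0L)
    stop("precision_recall: need at least one match", call. = FALSE)
  d <- sqrt(rowSums((points - refs)^2))
  correct <- sum(d <= radius)
  list(precision = correct / n,
       recall = if (correspond_count >= 1) correct / correspond_count,
       n_correct = correct, n_matches = n)
}

#' Detection accuracy from a confusion matrix
#'
#' `(TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param tp,tn,fp,fn Non-negative counts, total at least 1.
#' @return Accuracy fraction in `[0, 1]`.
#' @export
accuracy_score <- function(tp, tn, fp, fn) {
  cnt <- c(tp, tn, fp, fn)
  if (any(cnt < 0)) stop("accuracy_score: negative count", call. = FALSE)
  tot <- sum(cnt)
  if (tot < 1) stop("accuracy_score: empty confusion matrix", call. = FALSE)
  (tp + tn) / tot
}

#' Orientation agreement count
#'
#' Counts angle pairs whose circular difference (minimum over the 360-degree
#' wrap) is strictly below `tol_deg`.
#'
#' @param orients_a,orients_b Paired angle vectors in degrees.
#' @param tol_deg Agreement tolerance in degrees (strict; default 5).
#' @return Integer count.
#' @export
orientation_agreement <- function(orients_a, orients_b, tol_deg = 5) {
  if (length(orients_a) != length(orients_b))
    stop("orientation_agreement: length mismatch", call. = FALSE)
  d <- abs(orients_a - orients_b) %% 360
  d <- pmin(d, 360 - d)
  sum(d < tol_deg)
}

#' Number of corresponding feature points under a ground-truth transform
#'
#' Counts IR keypoints whose true location in the visible frame (through the
#' ground-truth transform) falls within `radius` px of some visible keypoint
#' — the recall denominator when ground truth is available.
#'
#' @param kp_ir,kp_vis Keypoint data frames (need columns `x`, `y`); IR
#'   coordinates in the frame the transform maps from.
#' @param truth_transform `similarity_transform` mapping IR coords to
#'   visible coords.
#' @param radius Pairing radius, px.
#' @return Integer count.
#' @export
correspond_count <- function(kp_ir, kp_vis, truth_transform, radius = 5) {
  if (nrow(kp_ir) == 0L || nrow(kp_vis) == 0L) return(0L)
  proj <- transform_points(truth_transform, cbind(kp_ir$x, kp_ir$y))
  cnt <- 0L
  vx <- kp_vis$x; vy <- kp_vis$y
  for (i in seq_len(nrow(proj))) {
    if (min((vx - proj[i, 1])^2 + (vy - proj[i, 2])^2) <= radius^2)
      cnt <- cnt + 1L
  }
  cnt
}

#' Assemble a metric report for a registration against ground truth
#'
#' @param result A `registration_result` (see [register_pair()]).
#' @param truth Ground truth from [generate_pair()] (needs `transform` and
#'   `control_points`).
#' @param radius Correct-match radius, px.
#' @return List of class `metric_report`: `rmse` (control-point RMSE in the
#'   visible frame), `precision` (fraction of final registration points
#'   within `radius` of truth), `recall` (correct rough-stage keypoint
#'   matches over corresponding feature points), `n_matches`, `n_correct`,
#'   `n_rough_correct`, `n_correspond`.
#' @export
metric_report <- function(result, truth, radius = 5) {
  cp <- truth$control_points
  est <- transform_points(result$transform,
                          cbind(cp$ir_x, cp$ir_y))
  rmse <- rmse_points(est, cbind(cp$vis_x, cp$vis_y))
  m <- result$matches
  fin <- m[m$inlier %in% TRUE, , drop = FALSE]
  # final registration points: the fine stage when present, else the rough
  if (any(fin$stage == "fine")) fin <- fin[fin$stage == "fine", , drop = FALSE]
  # precision: fraction of final registration points within the
  # correct-match radius of their ground-truth location
  precision <- NULL; n_correct <- 0L
  if (nrow(fin) > 0L) {
    refs <- transform_points(truth$transform, cbind(fin$ir_x, fin$ir_y))
    pr <- precision_recall(cbind(fin$vis_x, fin$vis_y), refs,
                           correspond_count = 1L, radius = radius)
    precision <- pr$precision
    n_correct <- pr$n_correct
  }
  # recall: correct keypoint-to-keypoint (rough-stage) matches over the
  # number of IR feature points (corners + dense) whose true location has
  # a detected visible counterpart within the radius
  kp_union <- function(a, b) {
    cols <- c("x", "y")
    unique(rbind(a[, cols, drop = FALSE], b[, cols, drop = FALSE]))
  }
  ncorr <- correspond_count(kp_union(result$keypoints_ir, result$dense_ir),
                            kp_union(result$keypoints_vis,
                                     result$dense_vis),
                            truth$transform, radius)
  rough <- m[m$stage == "rough" & m$inlier %in% TRUE, , drop = FALSE]
  recall <- NULL; n_rough_correct <- 0L
  if (nrow(rough) > 0L && ncorr >= 1L) {
    rref <- transform_points(truth$transform, cbind(rough$ir_x, rough$ir_y))
    d <- sqrt(rowSums((cbind(rough$vis_x, rough$vis_y) - rref)^2))
    n_rough_correct <- sum(d <= radius)
    recall <- n_rough_correct / ncorr
  }
  structure(list(rmse = rmse,
                 precision = precision, recall = recall,
                 n_matches = nrow(fin),
                 n_correct = n_correct,
                 n_rough_correct = n_rough_correct,
                 n_correspond = ncorr),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "<metrics: RMSE %.3f px | precision %s | recall %s | %d matches>\n",
    x$rmse,
    if (is.null(x$precision)) "-" else sprintf("%.3f", x$precision),
    if (is.null(x$recall)) "-" else sprintf("%.3f", x$recall),
    x$n_matches))
  invisible(x)
}
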