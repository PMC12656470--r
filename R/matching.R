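# Bilateral descriptor matching, RANSAC similarity estimation and the
# normal-constrained correlation refinement (the rough-to-fine stage).

#' Bilateral (mutual nearest-neighbour) descriptor matching
#'
#' A pair is kept iff each descriptor is the other's nearest neighbour and
#' the nearest/second-nearest distance ratio on the IR side is at most
#' `ratio`. With a finite `search_radius` the neighbour search is restricted
#' to descriptors within that spatial distance (guided matching: co-mounted
#' cameras bound how far a correspondence can move between frames).
#' Multi-scale visible descriptors are collapsed so each keypoint appears in
#' at most one match (smallest distance wins); equal distances break towards
#' the lower index.
#'
#' @param desc_ir,desc_vis Descriptor sets from [describe_all()].
#' @param ratio Nearest/second-nearest distance ratio threshold.
#' @param search_radius Spatial gating radius in px (`Inf` disables).
#' @return Match data frame: `ir_x`, `ir_y`, `vis_x`, `vis_y`, `ir_keypoint`,
#'   `vis_keypoint`, `distance`, `stage` (`"bilateral"`), `inlier` (NA).
#' @export
bilateral_match <- function(desc_ir, desc_vis, ratio = 0.7,
                            search_radius = Inf) {
  empty <- data.frame(ir_x = numeric(0), ir_y = numeric(0),
                      vis_x = numeric(0), vis_y = numeric(0),
                      ir_keypoint = integer(0), vis_keypoint = integer(0),
                      distance = numeric(0), stage = character(0),
                      inlier = logical(0))
  ni <- nrow(desc_ir$vectors); nv <- nrow(desc_vis$vectors)
  if (ni == 0L || nv == 0L || ratio <= 0) return(empty)
  A <- desc_ir$vectors; B <- desc_vis$vectors
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  D <- sqrt(d2)
  if (is.finite(search_radius)) {
    sep2 <- outer(desc_ir$info$x, desc_vis$info$x, "-")^2 +
      outer(desc_ir$info$y, desc_vis$info$y, "-")^2
    D[sep2 > search_radius^2] <- Inf
  }
  nn_iv <- apply(D, 1, which.min)           # IR -> vis
  nn_vi <- apply(D, 2, which.min)           # vis -> IR
  keep <- integer(0)
  for (i in seq_len(ni)) {
    v <- nn_iv[i]
    if (!is.finite(D[i, v])) next
    if (nn_vi[v] != i) next
    d1 <- D[i, v]
    d2nd <- if (nv > 1L) suppressWarnings(min(D[i, -v])) else Inf
    if (is.finite(d2nd) && d2nd > 0) {
      if (d1 / d2nd > ratio) next
    } else if (is.finite(d2nd) && d1 > 0) next
    keep <- c(keep, i)
  }
  if (length(keep) == 0L) return(empty)
  m <- data.frame(
    ir_x = desc_ir$info$x[keep], ir_y = desc_ir$info$y[keep],
    vis_x = desc_vis$info$x[nn_iv[keep]],
    vis_y = desc_vis$info$y[nn_iv[keep]],
    ir_keypoint = desc_ir$info$keypoint[keep],
    vis_keypoint = desc_vis$info$keypoint[nn_iv[keep]],
    distance = D[cbind(keep, nn_iv[keep])],
    stage = "bilateral", inlier = NA)
  # collapse to unique keypoints on both sides, best distance first
  m <- m[order(m$distance, m$ir_keypoint), ]
  m <- m[!duplicated(m$ir_keypoint), ]
  m <- m[!duplicated(m$vis_keypoint), ]
  rownames(m) <- NULL
  m
}

#' RANSAC similarity estimation from putative matches
#'
#' Repeatedly samples 2 matches, fits the closed-form similarity, counts
#' matches whose reprojection error is at most `inlier_tol`, keeps the best
#' consensus and refits by least squares on its inliers (with one consensus
#' re-evaluation after the refit). Deterministic given `seed`.
#'
#' Hypotheses can be gated by prior bounds on the transform (`scale_range`,
#' `max_rotation`, `max_translation`): for a fixed two-camera rig the
#' residual transform after resolution equalization is close to identity,
#' and discarding implausible hypotheses stops small spurious consensus sets
#' from out-voting the true one. The permissive defaults disable gating.
#'
#' @param matches Match data frame from [bilateral_match()].
#' @param inlier_tol Inlier reprojection tolerance, px.
#' @param iterations Number of RANSAC samples.
#' @param seed Integer seed for the sampling stream.
#' @param scale_range Length-2 admissible range for the hypothesis scale.
#' @param max_rotation Maximum admissible |rotation| in radians.
#' @param max_translation Maximum admissible translation norm in px.
#' @param min_sample_sep Minimum distance between the two sampled IR points
#'   (closer pairs give ill-conditioned hypotheses).
#' @return List with `transform` (a `similarity_transform`), `matches` (the
#'   input with `inlier` set; inliers have `stage = "rough"`), `n_inliers`,
#'   and `ok` (`FALSE` when the consensus has fewer than 4 inliers).
#' @export
ransac_similarity <- function(matches, inlier_tol = 3, iterations = 2000L,
                              seed = 42L, scale_range = c(0, Inf),
                              max_rotation = pi, max_translation = Inf,
                              min_sample_sep = 1e-9) {
  n <- nrow(matches)
  if (n < 2L)
    stop_registration("ransac", "need at least 2 matches for a similarity",
                      n_matches = n)
  src <- cbind(matches$ir_x, matches$ir_y)
  dst <- cbind(matches$vis_x, matches$vis_y)
  u <- complex(real = src[, 1], imaginary = src[, 2])
  v <- complex(real = dst[, 1], imaginary = dst[, 2])
  best_n <- -1L; best_err <- Inf; best_in <- NULL
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  for (it in seq_len(iterations)) {
    ij <- sample.int(n, 2L)
    du <- u[ij[2]] - u[ij[1]]
    if (Mod(du) < min_sample_sep) next
    a <- (v[ij[2]] - v[ij[1]]) / du
    if (Mod(a) < scale_range[1] || Mod(a) > scale_range[2]) next
    if (abs(Arg(a)) > max_rotation) next
    b <- v[ij[1]] - a * u[ij[1]]
    if (Mod(b) > max_translation) next
    err <- Mod(a * u + b - v)
    inl <- err <= inlier_tol
    ni <- sum(inl)
    toterr <- sum(err[inl])
    if (ni > best_n || (ni == best_n && toterr < best_err)) {
      best_n <- ni; best_err <- toterr; best_in <- inl
    }
  }
  if (is.null(best_in) || best_n < 2L)
    stop_registration("ransac", "no valid similarity hypothesis found",
                      n_matches = n)
  tf <- fit_similarity(src[best_in, , drop = FALSE],
                       dst[best_in, , drop = FALSE])
  if (is.null(tf))
    stop_registration("ransac", "degenerate inlier configuration",
                      n_matches = n)
  # one consensus re-evaluation with the least-squares fit
  err <- sqrt(rowSums((transform_points(tf, src) - dst)^2))
  inl <- err <= inlier_tol
  if (sum(inl) >= 2L) {
    tf2 <- fit_similarity(src[inl, , drop = FALSE], dst[inl, , drop = FALSE])
    if (!is.null(tf2)) {
      tf <- tf2
      err <- sqrt(rowSums((transform_points(tf, src) - dst)^2))
      inl <- err <= inlier_tol
    }
  }
  out <- matches
  out$inlier <- inl
  out$stage[inl] <- "rough"
  list(transform = tf, matches = out, n_inliers = sum(inl),
       ok = sum(inl) >= 4L)
}

# Registration-failure condition with stage diagnostics.
stop_registration <- function(stage, msg, ...) {
  stop(structure(class = c("gocao_registration_failure", "error",
                           "condition"),
                 list(message = sprintf("[%s] %s", stage, msg),
                      call = sys.call(-1), stage = stage,
                      diagnostics = list(...))))
}

# Zero-normalized cross-correlation of two equal-size patches.
zncc <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na < 1e-12 || nb < 1e-12) return(NA_real_)
  sum(a * b) / (na * nb)
}

# Least-squares similarity from point-to-line constraints: minimizes
# sum_i ( n_i . (T(q_i) - p_i) )^2 over T(q) = a q + b (complex a, b).
# Linear in (Re a, Im a, Re b, Im b).
fit_similarity_p2l <- function(q, p, n) {
  A <- cbind(n[, 1] * q[, 1] + n[, 2] * q[, 2],
             -n[, 1] * q[, 2] + n[, 2] * q[, 1],
             n[, 1], n[, 2])
  rhs <- n[, 1] * p[, 1] + n[, 2] * p[, 2]
  th <- tryCatch(qr.solve(A, rhs), error = function(e) NULL)
  if (is.null(th)) return(NULL)
  a <- complex(real = th[1], imaginary = th[2])
  if (Mod(a) < 1e-9) return(NULL)
  similarity_transform(Mod(a), Arg(a), th[3], th[4])
}

#' Fine positional refinement of visible match locations
#'
#' For every supplied IR contour keypoint, the IR patch around its projected
#' visible-frame location (warped through the current transform) is compared
#' by absolute zero-normalized cross-correlation against visible patches
#' shifted along the keypoint's contour-normal direction (the angular
#' bisector orientation); the visible location is renewed to the correlation
#' peak (parabolic sub-pixel interpolation). The absolute value makes the
#' correlation blind to the contrast reversal between spectra, and the
#' normal-only search sidesteps the aperture ambiguity of sliding along a
#' contour. The transform is then refit from the point-to-normal-line
#' constraints with residual trimming, and the whole cycle is iterated with
#' a shrinking search window. If the mean normal residual would increase,
#' the input transform is returned unchanged, so refinement never degrades
#' the registration.
#'
#' @param ransac_fit Result of [ransac_similarity()] (or any list with a
#'   `transform` and `matches`).
#' @param keypoints_ir Data frame of IR-frame keypoints with `x`, `y`,
#'   `orientation` (in the same frame the transform maps from).
#' @param map_ir,map_vis Matrices (or `feature_map`s) the correlation runs
#'   on — normally the upsampled IR and visible intensity images.
#' @param window Search half-range along the normal (px) for the first
#'   iteration; later iterations shrink it.
#' @param iterations Renewal/refit cycles.
#' @param patch_radius Correlation patch half-width, px.
#' @param min_cc Minimum |ZNCC| for a renewed location to be used.
#' @return List like [ransac_similarity()]'s: `transform`, `matches` (the
#'   rough matches plus one `"fine"` row per renewed keypoint),
#'   `n_inliers`, `ok`, `mean_error_before`, `mean_error_after` (mean
#'   absolute normal residuals of the renewed constraint set).
#' @export
refine_matches <- function(ransac_fit, keypoints_ir, map_ir, map_vis,
                           window = 10L, iterations = 3L,
                           patch_radius = 12L, min_cc = 0.6) {
  vi <- if (inherits(map_ir, "feature_map")) map_ir$values else map_ir
  vv <- if (inherits(map_vis, "feature_map")) map_vis$values else map_vis
  fit0 <- ransac_fit$transform
  fit <- fit0
  r <- patch_radius
  us <- seq(-r, r)
  U <- matrix(us, 2 * r + 1, 2 * r + 1, byrow = TRUE)
  V <- matrix(us, 2 * r + 1, 2 * r + 1)
  windows <- pmax(3L, round(window * 0.6^(seq_len(iterations) - 1L)))
  tols <- pmax(1.25, 4 * 0.6^(seq_len(iterations) - 1L))
  renew <- function(fit, w) {
    inv <- invert_transform(fit)
    qs <- list(); ps <- list(); ns <- list(); ccs <- c()
    for (i in seq_len(nrow(keypoints_ir))) {
      q <- c(keypoints_ir$x[i], keypoints_ir$y[i])
      ci <- transform_points(fit, q)
      o <- keypoints_ir$orientation[i] + fit$phi
      nhat <- c(cos(o), sin(o))
      sx <- inv$s * (cos(inv$phi) * (ci[1] + U) - sin(inv$phi) * (ci[2] + V)) +
        inv$tx
      sy <- inv$s * (sin(inv$phi) * (ci[1] + U) + cos(inv$phi) * (ci[2] + V)) +
        inv$ty
      if (min(sx) < 0 || min(sy) < 0 || max(sx) > ncol(vi) - 1 ||
          max(sy) > nrow(vi) - 1) next
      templ <- matrix(bilinear_sample(vi, sx, sy), 2 * r + 1, 2 * r + 1)
      if (stats::sd(templ) < 1e-4) next   # flat patch: no signal
      ts <- -w:w
      prof <- rep(NA_real_, length(ts))
      for (k in seq_along(ts)) {
        px <- ci[1] + ts[k] * nhat[1] + U
        py <- ci[2] + ts[k] * nhat[2] + V
        if (min(px) < 0 || min(py) < 0 || max(px) > ncol(vv) - 1 ||
            max(py) > nrow(vv) - 1) next
        prof[k] <- abs(zncc(templ,
                            matrix(bilinear_sample(vv, px, py),
                                   2 * r + 1, 2 * r + 1)))
      }
      if (all(is.na(prof))) next
      k0 <- which.max(prof)
      if (prof[k0] < min_cc) next
      tstar <- ts[k0]
      if (k0 > 1 && k0 < length(ts) && !any(is.na(prof[k0 + c(-1, 1)]))) {
        den <- 2 * (2 * prof[k0] - prof[k0 - 1] - prof[k0 + 1])
        if (den > 1e-9)
          tstar <- tstar +
            max(-0.5, min(0.5, (prof[k0 + 1] - prof[k0 - 1]) / den))
      }
      qs[[length(qs) + 1L]] <- q
      ps[[length(ps) + 1L]] <- ci + tstar * nhat
      ns[[length(ns) + 1L]] <- nhat
      ccs <- c(ccs, prof[k0])
    }
    if (length(qs) == 0L) return(NULL)
    list(q = do.call(rbind, qs), p = do.call(rbind, ps),
         n = do.call(rbind, ns), cc = ccs)
  }
  cons <- NULL
  for (it in seq_len(iterations)) {
    cons <- renew(fit, windows[it])
    if (is.null(cons) || nrow(cons$q) < 8L) break
    f2 <- fit
    for (rep in 1:2) {
      e <- abs(rowSums(cons$n * (transform_points(f2, cons$q) - cons$p)))
      keep <- e <= tols[it]
      if (sum(keep) < 8L) break
      f3 <- fit_similarity_p2l(cons$q[keep, , drop = FALSE],
                               cons$p[keep, , drop = FALSE],
                               cons$n[keep, , drop = FALSE])
      if (is.null(f3)) break
      f2 <- f3
    }
    fit <- f2
  }
  # monotonicity guarantee on the final constraint set
  final <- renew(fit, 3L)
  mean_resid <- function(f, cons) {
    if (is.null(cons) || nrow(cons$q) == 0L) return(NA_real_)
    mean(abs(rowSums(cons$n * (transform_points(f, cons$q) - cons$p))))
  }
  err_before <- mean_resid(fit0, final)
  err_after <- mean_resid(fit, final)
  if (is.na(err_after) || (!is.na(err_before) && err_after > err_before)) {
    fit <- fit0
    err_after <- err_before
  }
  matches <- ransac_fit$matches
  if (!is.null(final) && nrow(final$q) > 0L && !identical(fit, fit0)) {
    fine_rows <- data.frame(
      ir_x = final$q[, 1], ir_y = final$q[, 2],
      vis_x = final$p[, 1], vis_y = final$p[, 2],
      ir_keypoint = NA_integer_, vis_keypoint = NA_integer_,
      distance = 1 - final$cc, stage = "fine", inlier = TRUE)
    common <- intersect(names(matches), names(fine_rows))
    matches <- rbind(matches[, common, drop = FALSE],
                     fine_rows[, common, drop = FALSE])
  }
  list(transform = fit, matches = matches,
       n_inliers = ransac_fit$n_inliers, ok = ransac_fit$ok,
       mean_error_before = err_before, mean_error_after = err_after)
}
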