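# Contour extraction from ordinal feature maps, curvature-scale-space corner
# detection, and angular-bisector main-orientation assignment.

#' Extract contour chains from an ordinal feature map
#'
#' `|S|` is binarized (by default at its 90th percentile), thinned to a
#' 1-pixel skeleton (Zhang-Suen) and traced into ordered 8-connected chains.
#' Chains shorter than `min_length` are discarded; the result is ordered by
#' decreasing length.
#'
#' An even band-pass filter responds to a step edge with an antisymmetric
#' (+/-) double ridge whose zero crossing sits exactly on the edge, so
#' `|S|` is first smoothed with a small Gaussian (`ridge_smooth`) to merge
#' the two humps into a single band centred on the contour before
#' binarization.
#'
#' The skeleton is spur-pruned before tracing (side branches shorter than
#' `spur_prune` disappear), and chains whose mean `|S|` falls below
#' `chain_strength` times that of the strongest chain are discarded: an
#' even band-pass filter flanks every contour ridge with side lobes at
#' roughly 0.4 of its amplitude, and this relative cut removes their
#' skeletons while keeping genuinely weaker object contours.
#'
#' @param S A `feature_map` (kind `"ordinal-S"` or `"raw"`) or matrix.
#' @param threshold Quantile of `|S|` used for binarization, in (0, 1).
#' @param min_length Minimum chain length in pixels.
#' @param spur_prune Endpoint-pruning iterations applied to the skeleton.
#' @param chain_strength Relative mean-`|S|` cutoff for keeping a chain.
#' @param ridge_smooth Gaussian sigma (px) for smoothing `|S|` before
#'   binarization; 0 disables.
#' @param min_response Absolute floor on the binarization threshold as a
#'   fraction of the map maximum. A pure percentile rule keeps a fixed
#'   pixel fraction however sparse the true contours are, flooding large
#'   images with texture ridges; the floor makes the rule content-adaptive.
#' @param close_gaps Box size (px) of a morphological closing applied to
#'   the binary band before thinning; oriented filters dip at sharp corners
#'   and the closing bridges the resulting band gaps. 0 disables.
#' @return A list of `contour` objects: each has `id`, `points` (n x 2
#'   matrix, columns `x`, `y`, 0-based) and `closed`.
#' @export
extract_contours <- function(S, threshold = 0.9, min_length = 10L,
                             spur_prune = 6L, chain_strength = 0.35,
                             ridge_smooth = 1.5, min_response = 0.2,
                             close_gaps = 3L) {
  v <- if (inherits(S, "feature_map")) S$values else S
  a <- abs(v)
  if (max(a) == 0) return(list())
  if (ridge_smooth > 0)
    a <- as.matrix(EBImage::gblur(a, sigma = ridge_smooth))
  thr <- max(stats::quantile(a, threshold, names = FALSE),
             min_response * max(a))
  if (thr <= 0) thr <- max(a) * 1e-6
  mask <- a >= thr
  if (close_gaps > 0 && nrow(mask) > close_gaps && ncol(mask) > close_gaps) {
    brush <- EBImage::makeBrush(close_gaps, "box")
    mask <- as.matrix(EBImage::closing(EBImage::Image(mask * 1),
                                       brush)) > 0.5
  }
  skel <- prune_spurs(thin_zhang_suen(mask), spur_prune)
  chains <- trace_chains(skel)
  chains <- Filter(function(ch) nrow(ch$points) >= min_length, chains)
  if (length(chains) > 1L && chain_strength > 0) {
    strength <- vapply(chains, function(ch) {
      mean(a[cbind(ch$points[, "y"] + 1L, ch$points[, "x"] + 1L)])
    }, 0)
    chains <- chains[strength >= chain_strength * max(strength)]
  }
  chains <- chains[order(-vapply(chains, function(ch) nrow(ch$points), 0))]
  for (i in seq_along(chains)) chains[[i]]$id <- i
  chains
}

# Remove skeleton endpoints iteratively, deleting side branches up to
# `iter` pixels long. Closed rings have no endpoints and are untouched.
prune_spurs <- function(skel, iter) {
  if (iter < 1L) return(skel)
  nr <- nrow(skel); nc <- ncol(skel)
  if (nr < 3L || nc < 3L) return(skel)
  for (i in seq_len(iter)) {
    nb <- matrix(0L, nr, nc)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rs <- max(1, 1 + dr):min(nr, nr + dr)
      cs <- max(1, 1 + dc):min(nc, nc + dc)
      nb[rs, cs] <- nb[rs, cs] + skel[rs - dr, cs - dc]
    }
    ends <- skel & nb <= 1L
    if (!any(ends)) break
    skel[ends] <- FALSE
  }
  skel
}

# Zhang-Suen binary thinning, vectorized over matrix shifts.
thin_zhang_suen <- function(mask) {
  m <- mask
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 3L || nc < 3L) return(m)
  shift <- function(x, dr, dc) {
    out <- matrix(FALSE, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- x[rs - dr, cs - dc]
    out
  }
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      # neighbours P2..P9 clockwise starting due north
      p2 <- shift(m, 1, 0);  p3 <- shift(m, 1, -1); p4 <- shift(m, 0, -1)
      p5 <- shift(m, -1, -1); p6 <- shift(m, -1, 0); p7 <- shift(m, -1, 1)
      p8 <- shift(m, 0, 1);  p9 <- shift(m, 1, 1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
        (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (step == 1) {
        cond <- m & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- m & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) {
        m[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# Trace a skeleton into ordered 8-connected chains. Endpoints (degree 1) are
# used as chain starts first; remaining unvisited pixels (pure loops) are
# started anywhere. Junction pixels terminate a walk, splitting branches.
# Works on linear indices with preallocated buffers (chains can run to
# thousands of pixels).
trace_chains <- function(skel) {
  idx <- which(skel)
  if (length(idx) == 0L) return(list())
  nr <- nrow(skel); nc <- ncol(skel)
  npx <- length(idx)
  on_skel <- logical(nr * nc); on_skel[idx] <- TRUE
  visited <- logical(nr * nc)
  # neighbour offsets in linear indexing (fixed order: deterministic)
  noff <- c(-nr - 1L, -1L, nr - 1L, -nr, nr, -nr + 1L, 1L, nr + 1L)
  nbrs_of <- function(p) {
    cand <- p + noff
    r <- ((p - 1L) %% nr) + 1L
    ok <- cand >= 1L & cand <= nr * nc
    # drop wrap-arounds across matrix columns
    rr <- ((cand - 1L) %% nr) + 1L
    ok <- ok & abs(rr - r) <= 1L
    cand[ok]
  }
  degs <- integer(npx)
  for (i in seq_len(npx)) degs[i] <- sum(on_skel[nbrs_of(idx[i])])
  buf <- integer(npx)
  walk_dir <- function(start) {
    n <- 0L; p <- start
    repeat {
      visited[p] <<- TRUE
      n <- n + 1L; buf[n] <<- p
      nb <- nbrs_of(p)
      nxt <- nb[on_skel[nb] & !visited[nb]]
      if (length(nxt) == 0L) break
      p <- nxt[1L]
    }
    buf[seq_len(n)]
  }
  chains <- list()
  ord <- order(degs != 1L)  # endpoints first
  for (i in ord) {
    p0 <- idx[i]
    if (visited[p0]) next
    fwd <- walk_dir(p0)
    # a walk started mid-chain leaves the other side unvisited: walk it too
    # and prepend it reversed so the chain stays ordered
    nb <- nbrs_of(p0)
    rest <- nb[on_skel[nb] & !visited[nb]]
    pts <- if (length(rest)) c(rev(walk_dir(rest[1L])), fwd) else fwd
    if (length(pts) < 2L) next
    pr <- ((pts - 1L) %% nr) + 1L
    pc <- ((pts - 1L) %/% nr) + 1L
    m <- length(pts)
    closed <- m > 8L && abs(pr[1L] - pr[m]) <= 2L && abs(pc[1L] - pc[m]) <= 2L
    chains[[length(chains) + 1L]] <- structure(
      list(id = NA_integer_,
           points = cbind(x = pc - 1L, y = pr - 1L),
           closed = closed),
      class = "contour")
  }
  chains
}

#' @export
print.contour <- function(x, ...) {
  cat(sprintf("<contour #%s: %d px, %s>\n", x$id, nrow(x$points),
              if (x$closed) "closed" else "open"))
  invisible(x)
}

# Gaussian smoothing of a 1-D signal along a chain; circular for closed
# chains, reflected ends for open ones.
smooth_chain <- function(v, sigma, closed) {
  h <- max(1L, ceiling(3 * sigma))
  g <- exp(-(seq(-h, h))^2 / (2 * sigma^2))
  g <- g / sum(g)
  n <- length(v)
  if (closed) {
    ext <- c(v[(n - min(h, n) + 1L):n], v, v[1:min(h, n)])
  } else {
    ext <- c(rev(v[1:min(h, n)]), v, rev(v[(n - min(h, n) + 1L):n]))
  }
  out <- stats::filter(ext, g, sides = 2)
  as.numeric(out[(h + 1L):(h + n)])
}

# Curvature of a smoothed chain via central differences:
# kappa = (x'y'' - y'x'') / (x'^2 + y'^2)^(3/2)
chain_curvature <- function(xs, ys, closed) {
  n <- length(xs)
  d <- function(v) {
    if (closed) (c(v[-1], v[1]) - c(v[n], v[-n])) / 2
    else c(v[2] - v[1], (v[-(1:2)] - v[1:(n - 2)]) / 2, v[n] - v[n - 1])
  }
  dx <- d(xs); dy <- d(ys)
  ddx <- d(dx); ddy <- d(dy)
  den <- (dx^2 + dy^2)^1.5
  k <- (dx * ddy - dy * ddx) / pmax(den, 1e-12)
  k[den < 1e-12] <- 0
  k
}

#' Curvature-scale-space corner points of a contour
#'
#' The chain's coordinates are smoothed with each Gaussian scale; local
#' maxima of `|kappa|` at the coarsest scale above `curvature_threshold`
#' that persist (stay above threshold within ±2 positions) at every finer
#' scale are kept, then thinned by non-maximum suppression along the chain.
#'
#' @param contour A `contour` object.
#' On open chains, candidates within two coarse smoothing lengths of either
#' end are discarded: the reflection padding used for smoothing makes
#' curvature estimates there unreliable.
#'
#' @param sigmas Smoothing scales in chain steps (coarsest used for
#'   detection). The finest scale should stay above ~3 steps so that raster
#'   aliasing ripple along diagonal edges is not detected as corners.
#' @param curvature_threshold Minimum `|kappa|` (1/px).
#' @param nms_sep Minimum separation between corners along the chain, steps.
#' @return Data frame with columns `x`, `y`, `contour_id`, `contour_index`
#'   (1-based index into the chain), `css_scale`, `curvature`. Orientation
#'   is not yet assigned.
#' @export
css_feature_points <- function(contour, sigmas = c(3, 6, 9),
                               curvature_threshold = 0.05, nms_sep = 5L) {
  pts <- contour$points
  n <- nrow(pts)
  empty <- data.frame(x = numeric(0), y = numeric(0),
                      contour_id = integer(0), contour_index = integer(0),
                      frac = numeric(0),
                      css_scale = numeric(0), curvature = numeric(0))
  if (n < 2L * max(ceiling(3 * max(sigmas)), 5L)) return(empty)
  sigmas <- sort(sigmas)
  coarse <- sigmas[length(sigmas)]
  kap <- lapply(sigmas, function(s) {
    xs <- smooth_chain(pts[, "x"], s, contour$closed)
    ys <- smooth_chain(pts[, "y"], s, contour$closed)
    abs(chain_curvature(xs, ys, contour$closed))
  })
  kc <- kap[[length(kap)]]
  # local maxima at the coarsest scale
  prev <- if (contour$closed) c(kc[n], kc[-n]) else c(Inf, kc[-n])
  nxt <- if (contour$closed) c(kc[-1], kc[1]) else c(kc[-1], Inf)
  cand <- which(kc >= curvature_threshold & kc >= prev & kc > nxt)
  if (!contour$closed) {
    margin <- ceiling(2 * coarse)
    cand <- cand[cand > margin & cand <= n - margin]
  }
  if (length(cand) == 0L) return(empty)
  # persistence across the finer scales
  persists <- vapply(cand, function(i) {
    win <- (i - 2L):(i + 2L)
    if (contour$closed) win <- ((win - 1L) %% n) + 1L
    else win <- win[win >= 1L & win <= n]
    all(vapply(kap[-length(kap)],
               function(kf) max(kf[win]) >= curvature_threshold, TRUE))
  }, TRUE)
  cand <- cand[persists]
  if (length(cand) == 0L) return(empty)
  # non-maximum suppression along the chain
  ord <- cand[order(-kc[cand])]
  keep <- integer(0)
  for (i in ord) {
    sep <- abs(keep - i)
    if (contour$closed && length(sep)) sep <- pmin(sep, n - sep)
    if (all(sep >= nms_sep)) keep <- c(keep, i)
  }
  keep <- sort(keep)
  # sub-step localization: parabolic interpolation of the coarse-scale
  # curvature peak (quantized vertices rotate the bisector arms)
  frac <- vapply(keep, function(i) {
    im <- if (i > 1L) i - 1L else if (contour$closed) n else i
    ip <- if (i < n) i + 1L else if (contour$closed) 1L else i
    den <- 2 * (2 * kc[i] - kc[im] - kc[ip])
    if (den > 1e-12) max(-0.5, min(0.5, (kc[ip] - kc[im]) / den)) else 0
  }, 0)
  data.frame(x = pts[keep, "x"], y = pts[keep, "y"],
             contour_id = rep(contour$id %||% NA_integer_, length(keep)),
             contour_index = keep, frac = frac,
             css_scale = coarse, curvature = kc[keep])
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

# Interpolated chain position at fractional index t (wrapping for closed
# chains); linear interpolation between adjacent points.
chain_point <- function(contour, t) {
  n <- nrow(contour$points)
  if (contour$closed) t <- ((t - 1) %% n) + 1
  t <- max(1, min(n, t))
  i0 <- floor(t); i1 <- min(if (contour$closed) i0 %% n + 1 else i0 + 1, n)
  f <- t - i0
  (1 - f) * contour$points[i0, c("x", "y")] +
    f * contour$points[i1, c("x", "y")]
}

# Standoff chord arms at a fractional chain index: each arm is the chord
# from `gap` to `gap + span` steps away from the vertex, pointing away from
# it. Skipping the first `gap` steps keeps the rasterized corner apex out
# of the direction estimate.
standoff_chords <- function(contour, t, gap, span) {
  n <- nrow(contour$points)
  if (!contour$closed && (t - gap - span < 1 || t + gap + span > n))
    return(NULL)
  aL <- chain_point(contour, t - gap - span) - chain_point(contour, t - gap)
  aR <- chain_point(contour, t + gap + span) - chain_point(contour, t + gap)
  if (all(abs(aL) < 1e-12) || all(abs(aR) < 1e-12)) return(NULL)
  list(arm_left = as.numeric(aL), arm_right = as.numeric(aR))
}

# Arm vectors at a fractional chain index on a (smoothed) contour.
arm_vectors_frac <- function(contour, t, arm_length) {
  n <- nrow(contour$points)
  if (!contour$closed && (t - arm_length < 1 || t + arm_length > n))
    return(NULL)
  p <- chain_point(contour, t)
  aL <- chain_point(contour, t - arm_length) - p
  aR <- chain_point(contour, t + arm_length) - p
  if (all(abs(aL) < 1e-12) || all(abs(aR) < 1e-12)) return(NULL)
  list(arm_left = as.numeric(aL), arm_right = as.numeric(aR))
}

# Copy of a contour with Gaussian-smoothed coordinates. Arm vectors taken on
# the smoothed chain are far less sensitive to pixelation than raw endpoint
# differences, which matters for orientation stability under rotation.
smoothed_contour <- function(contour, sigma = 2) {
  if (sigma <= 0) return(contour)
  contour$points <- cbind(
    x = smooth_chain(contour$points[, "x"], sigma, contour$closed),
    y = smooth_chain(contour$points[, "y"], sigma, contour$closed))
  contour
}

#' Contour arm vectors at a chain position
#'
#' The left and right arms at chain position `index` are
#' `P[index - arm_length] - P[index]` and `P[index + arm_length] - P[index]`
#' (indices wrap for closed contours). Points of an open contour closer than
#' `arm_length` to an end have no arms and return `NULL`.
#'
#' @param contour A `contour` object.
#' @param index 1-based chain position.
#' @param arm_length Arm length in chain steps.
#' @return List with `arm_left` and `arm_right` (length-2 numeric vectors),
#'   or `NULL` when the arms cannot be formed.
#' @export
arm_vectors <- function(contour, index, arm_length = 5L) {
  n <- nrow(contour$points)
  iL <- index - arm_length
  iR <- index + arm_length
  if (contour$closed) {
    iL <- ((iL - 1L) %% n) + 1L
    iR <- ((iR - 1L) %% n) + 1L
  } else if (iL < 1L || iR > n) {
    return(NULL)
  }
  p <- contour$points[index, c("x", "y")]
  aL <- contour$points[iL, c("x", "y")] - p
  aR <- contour$points[iR, c("x", "y")] - p
  if (all(aL == 0) || all(aR == 0)) return(NULL)
  list(arm_left = as.numeric(aL), arm_right = as.numeric(aR))
}

#' Angular bisector vector of two contour arms
#'
#' `v = min(|L|, |R|) * (L / |L| + R / |R|)`. Exactly (or numerically)
#' anti-parallel arms give the zero vector, which downstream code treats as
#' a degenerate keypoint and drops.
#'
#' @param arm_left,arm_right Non-zero length-2 numeric vectors.
#' @return Length-2 numeric vector `(x_im, y_im)`.
#' @export
bisector <- function(arm_left, arm_right) {
  nl <- sqrt(sum(arm_left^2))
  nr <- sqrt(sum(arm_right^2))
  if (nl == 0 || nr == 0)
    stop("bisector: arms must be non-zero", call. = FALSE)
  min(nl, nr) * (arm_left / nl + arm_right / nr)
}

#' Main orientation from a bisector vector
#'
#' Quadrant-resolved arctangent mapped to `[0, 2*pi)`:
#' `atan(y/x)` when `y >= 0` and `x >= 0`; `atan(y/x) + pi` when `x < 0`;
#' `atan(y/x) + 2*pi` when `y < 0` and `x > 0`; the `x == 0` boundary maps
#' by continuity to `pi/2` (y > 0) and `3*pi/2` (y < 0).
#'
#' @param x_im,y_im Bisector components (not both zero).
#' @return Orientation in radians, in `[0, 2*pi)`.
#' @export
orientation_from_bisector <- function(x_im, y_im) {
  if (x_im == 0 && y_im == 0)
    stop("orientation_from_bisector: zero vector is degenerate", call. = FALSE)
  if (x_im == 0) return(if (y_im > 0) pi / 2 else 3 * pi / 2)
  o <- if (y_im >= 0 && x_im >= 0) atan(y_im / x_im)
  else if (x_im < 0) atan(y_im / x_im) + pi
  else atan(y_im / x_im) + 2 * pi
  o %% (2 * pi)
}

#' Regularly sampled contour keypoints with bisector orientations
#'
#' Samples every `step`-th chain point of each extracted contour and assigns
#' it the angular-bisector orientation of its contour arms (which, away from
#' corners, is the contour normal). Dense contour keypoints carry the
#' correspondence load for matching two modalities whose corner detections
#' do not repeat reliably; the sparse CSS corners remain the descriptive
#' feature set.
#'
#' @param S A `feature_map` (or matrix), or a precomputed list of
#'   `contour` objects from [extract_contours()].
#' @param config Pipeline configuration list (the `contours` entries are
#'   used; arms use `dense_arm` steps).
#' @param step Chain sampling step in pixels.
#' @param max_points Upper bound on returned keypoints; larger sets are
#'   evenly thinned (keeps the run time of matching and refinement bounded
#'   on contour-rich scenes).
#' @return Keypoint data frame (`x`, `y`, `contour_id`, `contour_index`,
#'   `orientation`).
#' @export
dense_keypoints <- function(S, config = default_config(),
                            step = config$contours$dense_step,
                            max_points = config$contours$max_keypoints) {
  cc <- config$contours
  contours <- if (is.list(S) && !inherits(S, "feature_map") &&
                  all(vapply(S, inherits, TRUE, "contour"))) S
  else extract_contours(S, threshold = cc$threshold,
                        min_length = cc$min_length,
                        spur_prune = cc$spur_prune,
                        chain_strength = cc$chain_strength,
                        ridge_smooth = cc$ridge_smooth,
                        min_response = cc$min_response,
                        close_gaps = cc$close_gaps)
  out <- list()
  for (ct in contours) {
    cts <- smoothed_contour(ct, min(cc$css_sigmas))
    for (i in seq(1L, nrow(ct$points), by = step)) {
      arms <- arm_vectors(cts, i, arm_length = cc$dense_arm)
      if (is.null(arms)) next
      v <- bisector(arms$arm_left, arms$arm_right)
      if (sqrt(sum(v^2)) < 1e-9) next
      out[[length(out) + 1L]] <- data.frame(
        x = ct$points[i, "x"], y = ct$points[i, "y"],
        contour_id = ct$id, contour_index = i,
        orientation = orientation_from_bisector(v[1], v[2]))
    }
  }
  if (length(out) == 0L)
    return(data.frame(x = numeric(0), y = numeric(0),
                      contour_id = integer(0), contour_index = integer(0),
                      orientation = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (nrow(res) > max_points) {
    res <- res[round(seq(1L, nrow(res), length.out = max_points)), ]
    rownames(res) <- NULL
  }
  res
}

#' Detect contour keypoints and assign main orientations
#'
#' Composes [extract_contours()], [css_feature_points()], [bisector()] and
#' [orientation_from_bisector()]. The two arms entering the bisector are
#' estimated as standoff chords on the smoothed chain: each arm is the chord
#' from `arm_gap` to `arm_gap + arm_span` steps away from the sub-step
#' corner vertex. The gap skips the staircase apex zone of the rasterized
#' corner, whose shape depends on the corner's angle to the pixel grid, so
#' the resulting orientation is stable under scene rotation to a few
#' degrees. Degenerate keypoints (anti-parallel arms, arms unavailable near
#' open ends) are dropped. When more than `max_keypoints` survive, the
#' highest-curvature ones are kept.
#'
#' @param S A `feature_map` (or matrix), or a precomputed list of
#'   `contour` objects from [extract_contours()].
#' @param config Pipeline configuration list, see [default_config()]; only
#'   the `contours` entries are used.
#' @return Data frame of keypoints: `x`, `y`, `contour_id`, `contour_index`,
#'   `arm_lx`, `arm_ly`, `arm_rx`, `arm_ry`, `orientation` (radians in
#'   `[0, 2*pi)`), `css_scale`, `curvature`.
#' @export
detect_and_orient <- function(S, config = default_config()) {
  cc <- config$contours
  contours <- if (is.list(S) && !inherits(S, "feature_map") &&
                  all(vapply(S, inherits, TRUE, "contour"))) S
  else extract_contours(S, threshold = cc$threshold,
                        min_length = cc$min_length,
                        spur_prune = cc$spur_prune,
                        chain_strength = cc$chain_strength,
                        ridge_smooth = cc$ridge_smooth,
                        min_response = cc$min_response,
                        close_gaps = cc$close_gaps)
  out <- list()
  for (ct in contours) {
    kp <- css_feature_points(ct, sigmas = cc$css_sigmas,
                             curvature_threshold = cc$curvature_threshold,
                             nms_sep = cc$nms_sep)
    if (nrow(kp) == 0L) next
    cts <- smoothed_contour(ct, min(cc$css_sigmas))
    rows <- lapply(seq_len(nrow(kp)), function(i) {
      arms <- standoff_chords(cts, kp$contour_index[i] + kp$frac[i],
                              gap = cc$arm_gap, span = cc$arm_span)
      if (is.null(arms)) return(NULL)
      v <- bisector(arms$arm_left, arms$arm_right)
      if (sqrt(sum(v^2)) < 1e-9) return(NULL)  # anti-parallel: degenerate
      cbind(kp[i, , drop = FALSE],
            data.frame(arm_lx = arms$arm_left[1], arm_ly = arms$arm_left[2],
                       arm_rx = arms$arm_right[1], arm_ry = arms$arm_right[2],
                       orientation = orientation_from_bisector(v[1], v[2])))
    })
    rows <- Filter(Negate(is.null), rows)
    if (length(rows)) out[[length(out) + 1L]] <- do.call(rbind, rows)
  }
  if (length(out) == 0L)
    return(data.frame(x = numeric(0), y = numeric(0),
                      contour_id = integer(0), contour_index = integer(0),
                      css_scale = numeric(0), curvature = numeric(0),
                      arm_lx = numeric(0), arm_ly = numeric(0),
                      arm_rx = numeric(0), arm_ry = numeric(0),
                      orientation = numeric(0)))
  kp <- do.call(rbind, out)
  rownames(kp) <- NULL
  if (nrow(kp) > cc$max_keypoints) {
    kp <- kp[order(-kp$curvature)[seq_len(cc$max_keypoints)], ]
    kp <- kp[order(kp$contour_id, kp$contour_index), ]
    rownames(kp) <- NULL
  }
  kp
}
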