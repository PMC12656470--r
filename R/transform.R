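# Similarity transforms (scale, rotation, translation) and image warping.

#' Create a similarity transform
#'
#' Maps a point `p` to `s * R(phi) %*% p + t`, with `R` the counter-clockwise
#' rotation in the image frame (+y down).
#'
#' @param s Scale, `> 0`.
#' @param phi Rotation in radians.
#' @param tx,ty Translation in pixels.
#' @return A `similarity_transform` object.
#' @export
similarity_transform <- function(s = 1, phi = 0, tx = 0, ty = 0) {
  if (!is.finite(s) || s <= 0)
    stop("similarity_transform: scale must be positive", call. = FALSE)
  structure(list(s = s, phi = phi, tx = tx, ty = ty),
            class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf(
    "<similarity: s = %.6g, phi = %.4f rad (%.2f deg), t = (%.3f, %.3f)>\n",
    x$s, x$phi, x$phi * 180 / pi, x$tx, x$ty))
  invisible(x)
}

#' Apply a similarity transform to points
#'
#' @param tf A `similarity_transform`.
#' @param pts n x 2 matrix (columns x, y) or length-2 vector.
#' @return n x 2 matrix of transformed points.
#' @export
transform_points <- function(tf, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  co <- cos(tf$phi); si <- sin(tf$phi)
  cbind(x = tf$s * (co * pts[, 1] - si * pts[, 2]) + tf$tx,
        y = tf$s * (si * pts[, 1] + co * pts[, 2]) + tf$ty)
}

#' Invert a similarity transform
#' @param tf A `similarity_transform`.
#' @return The inverse `similarity_transform`.
#' @export
invert_transform <- function(tf) {
  co <- cos(tf$phi); si <- sin(tf$phi)
  s <- 1 / tf$s
  similarity_transform(s, -tf$phi,
                       tx = -s * (co * tf$tx + si * tf$ty),
                       ty = -s * (-si * tf$tx + co * tf$ty))
}

#' Compose two similarity transforms
#'
#' `compose_transforms(a, b)` applies `b` first, then `a`.
#' @param a,b `similarity_transform` objects.
#' @return Their composition as a `similarity_transform`.
#' @export
compose_transforms <- function(a, b) {
  t2 <- transform_points(a, c(b$tx, b$ty))
  similarity_transform(a$s * b$s, a$phi + b$phi, t2[1], t2[2])
}

#' Warp an image through a similarity transform (inverse mapping)
#'
#' Output pixel `(x, y)` takes the bilinearly interpolated value of the
#' source at `tf(x, y)`, i.e. `tf` maps output coordinates to source
#' coordinates. Samples falling outside the source are filled with `fill`.
#'
#' @param img Numeric matrix.
#' @param tf `similarity_transform` mapping output coords to source coords.
#' @param out_dim Output `c(height, width)`; defaults to `dim(img)`.
#' @param fill Fill value for out-of-source samples.
#' @return Numeric matrix of size `out_dim`.
#' @export
warp_image <- function(img, tf, out_dim = dim(img), fill = 0) {
  nr <- out_dim[1]; nc <- out_dim[2]
  xs <- rep(0:(nc - 1), each = nr)
  ys <- rep(0:(nr - 1), times = nc)
  src <- transform_points(tf, cbind(xs, ys))
  inside <- src[, 1] >= 0 & src[, 1] <= ncol(img) - 1 &
    src[, 2] >= 0 & src[, 2] <= nrow(img) - 1
  vals <- rep(fill, nr * nc)
  if (any(inside))
    vals[inside] <- bilinear_sample(img, src[inside, 1], src[inside, 2])
  matrix(vals, nr, nc)
}

# Least-squares similarity fit mapping src -> dst (complex formulation:
# dst ~ a * src + b with a = s * exp(i * phi)).
fit_similarity <- function(src, dst) {
  u <- complex(real = src[, 1], imaginary = src[, 2])
  v <- complex(real = dst[, 1], imaginary = dst[, 2])
  um <- mean(u); vm <- mean(v)
  du <- u - um
  denom <- sum(Mod(du)^2)
  if (denom < 1e-12) return(NULL)   # coincident source points
  a <- sum(Conj(du) * (v - vm)) / denom
  if (Mod(a) < 1e-12) return(NULL)
  b <- vm - a * um
  similarity_transform(Mod(a), Arg(a), Re(b), Im(b))
}
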