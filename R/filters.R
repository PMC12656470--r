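# ---------------------------------------------------------------------------
# Image convention used throughout the package:
#   * an image is a plain numeric matrix, nrow = height, ncol = width;
#   * pixel (x, y) is 0-based, x = column, y = row, origin at the top-left,
#     so value at (x, y) is m[y + 1, x + 1];
#   * angles are measured counter-clockwise from +x with +y pointing DOWN
#     image rows.
# ---------------------------------------------------------------------------

#' Parameters of one even-symmetric Gabor kernel
#'
#' A Gabor filter is a Gaussian envelope multiplied by a cosine carrier,
#' `K(x, y) = gamma / (2 pi sigma^2) * exp(-(x_t^2 + gamma^2 y_t^2) /
#' (2 sigma^2)) * cos(2 pi f x_t)` with the rotated frame
#' `x_t = x cos(theta) + y sin(theta)`, `y_t = -x sin(theta) + y cos(theta)`.
#' The cosine carrier makes the kernel even-symmetric, `K(x, y) = K(-x, -y)`.
#'
#' @param f Centre frequency in cycles/pixel, `> 0`.
#' @param theta Orientation in radians, taken modulo `pi`.
#' @param sigma Scale (standard deviation) of the Gaussian envelope, pixels.
#' @param gamma Length-to-width aspect ratio of the envelope, `> 0`.
#' @param support Half-width of the square kernel in pixels; the kernel is
#'   `(2 * support + 1)` pixels on a side. Defaults to `ceiling(3 * sigma)`.
#' @return An object of class `gabor_params`.
#' @export
gabor_params <- function(f, theta, sigma, gamma = 0.5,
                         support = ceiling(3 * sigma)) {
  if (!is.numeric(f) || length(f) != 1L || !is.finite(f) || f <= 0)
    stop("gabor_params: 'f' must be a positive finite scalar", call. = FALSE)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("gabor_params: 'sigma' must be positive", call. = FALSE)
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0)
    stop("gabor_params: 'gamma' must be positive", call. = FALSE)
  support <- as.integer(support)
  if (support < 1L)
    stop("gabor_params: 'support' must be a positive integer", call. = FALSE)
  structure(list(f = f, theta = theta %% pi, sigma = sigma, gamma = gamma,
                 support = support),
            class = "gabor_params")
}

#' Build the discretized even-symmetric Gabor kernel
#'
#' @param params A [gabor_params()] object.
#' @return A `(2 * support + 1)` square numeric matrix; rows index y
#'   (downwards), columns index x.
#' @examples
#' k <- make_gabor_kernel(gabor_params(f = 0.25, theta = 0, sigma = 2, gamma = 1))
#' k[7, 7]  # centre value gamma / (2 pi sigma^2)
#' @export
make_gabor_kernel <- function(params) {
  stopifnot(inherits(params, "gabor_params"))
  s <- params$support
  xs <- seq(-s, s)
  x <- matrix(xs, nrow = 2 * s + 1, ncol = 2 * s + 1, byrow = TRUE)
  y <- matrix(xs, nrow = 2 * s + 1, ncol = 2 * s + 1)
  xt <- x * cos(params$theta) + y * sin(params$theta)
  yt <- -x * sin(params$theta) + y * cos(params$theta)
  amp <- params$gamma / (2 * pi * params$sigma^2)
  k <- amp * exp(-(xt^2 + params$gamma^2 * yt^2) / (2 * params$sigma^2)) *
    cos(2 * pi * params$f * xt)
  k
}

#' Default Gabor bank: 8 orientations by 3 envelope scales
#'
#' Orientations `theta = k * pi / 8` for `k = 0..7`; scales
#' `sigma in {2, 4, 8}` px with centre frequency `f = 0.75 / sigma`
#' (wavelength `4 sigma / 3`) and aspect ratio `gamma`. This `f * sigma`
#' product keeps the even filter's DC gain negligible (an illumination
#' offset then produces no response); the kernel support covers three
#' standard deviations of the envelope along both axes, i.e.
#' `3 * sigma / min(1, gamma)`.
#'
#' @param orientations Number of equally spaced orientations in `[0, pi)`.
#' @param sigmas Envelope scales in pixels.
#' @param gamma Envelope aspect ratio.
#' @return A list of [gabor_params()].
#' @export
default_gabor_bank <- function(orientations = 8L, sigmas = c(2, 4, 8),
                               gamma = 0.5) {
  thetas <- (seq_len(orientations) - 1L) * pi / orientations
  bank <- list()
  for (sg in sigmas)
    for (th in thetas)
      bank[[length(bank) + 1L]] <-
        gabor_params(f = 0.75 / sg, theta = th, sigma = sg, gamma = gamma,
                     support = ceiling(3 * sg / min(1, gamma)))
  bank
}

# 2-D convolution (true convolution: kernel flipped) with reflected borders.
# EBImage::filter2 is FFT-based true convolution but only supports
# circular/replicate padding, so the image is symmetrically padded first.
conv2_reflect <- function(img, kernel) {
  kr <- (nrow(kernel) - 1L) %/% 2L
  kc <- (ncol(kernel) - 1L) %/% 2L
  padded <- pad_reflect(img, kr, kc)
  out <- EBImage::filter2(padded, kernel, boundary = "circular")
  out <- as.matrix(out)
  out[(kr + 1L):(kr + nrow(img)), (kc + 1L):(kc + ncol(img)), drop = FALSE]
}

# Symmetric (mirror, edge included) padding by pr rows / pc cols on each
# side; pads larger than the image reflect repeatedly (period 2n).
pad_reflect <- function(img, pr, pc) {
  refl <- function(i, n) {
    m <- ((i - 1L) %% (2L * n) + 2L * n) %% (2L * n)
    ifelse(m < n, m + 1L, 2L * n - m)
  }
  nr <- nrow(img); nc <- ncol(img)
  img[refl(seq.int(1L - pr, nr + pr), nr),
      refl(seq.int(1L - pc, nc + pc), nc), drop = FALSE]
}

#' Construct a feature map object
#'
#' A `feature_map` wraps a real-valued 2-D field (same size as its source
#' image) together with the parameters that generated it.
#'
#' @param values Numeric matrix.
#' @param kind `"gabor-F"`, `"ordinal-S"`, or `"raw"`.
#' @param params Generating parameter list (bank and/or ordinal params).
#' @return A `feature_map` object.
#' @export
feature_map <- function(values, kind = c("gabor-F", "ordinal-S", "raw"),
                        params = list()) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop("feature_map: 'values' must be a numeric matrix", call. = FALSE)
  if (!all(is.finite(values)))
    stop("feature_map: values must all be finite", call. = FALSE)
  structure(list(values = values, kind = kind, params = params),
            class = "feature_map")
}

#' @export
print.feature_map <- function(x, ...) {
  cat(sprintf("<feature_map [%s] %d x %d, range [%.4g, %.4g]>\n",
              x$kind, nrow(x$values), ncol(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.feature_map <- function(x) dim(x$values)

#' Gabor contour feature map F
#'
#' Convolves the image with every kernel of the bank and reduces across the
#' bank by signed maximum magnitude: at each pixel the response with the
#' largest absolute value wins and keeps its sign, so contour polarity is
#' preserved for the downstream ordinal stage.
#'
#' @param image Numeric matrix (single channel, finite), or a `feature_map`.
#' @param bank List of [gabor_params()]; default [default_gabor_bank()].
#' @param normalize Scale the result so that `max(abs(F)) == 1` (flat maps
#'   are left untouched). Default `TRUE`.
#' @return A `feature_map` of kind `"gabor-F"`.
#' @export
gabor_feature_map <- function(image, bank = default_gabor_bank(),
                              normalize = TRUE) {
  if (inherits(image, "feature_map")) image <- image$values
  if (!is.matrix(image) || length(image) == 0L)
    stop("gabor_feature_map: image must be a non-empty matrix", call. = FALSE)
  if (!all(is.finite(image)))
    stop("gabor_feature_map: image must be finite", call. = FALSE)
  if (length(bank) == 0L)
    stop("gabor_feature_map: empty Gabor bank", call. = FALSE)
  best <- matrix(0, nrow(image), ncol(image))
  best_abs <- matrix(-1, nrow(image), ncol(image))
  for (p in bank) {
    r <- conv2_reflect(image, make_gabor_kernel(p))
    a <- abs(r)
    sel <- a > best_abs
    best[sel] <- r[sel]
    best_abs[sel] <- a[sel]
  }
  if (normalize) best <- normalize_map(best)
  feature_map(best, kind = "gabor-F", params = list(bank = bank))
}

# Symmetric normalization: divide by max|v| so the zero level of the
# band-pass response is preserved (plain min-max would shift it). Maps with
# no real contrast structure (max response below `floor`; genuine edges of
# a [0,1] image respond at ~0.1) are zeroed rather than having numerical
# residue amplified to full scale.
normalize_map <- function(v, floor = 1e-4) {
  m <- max(abs(v))
  if (m < floor) return(v * 0)
  v / m
}

#' Parameters of the ordinal (signed sum-of-Gaussians) filter
#'
#' The ordinal filter is `C_p * sum_i N(u; omega_pi, sigma_pi) -
#' C_n * sum_j N(u; omega_nj, sigma_nj)`: positive lobes minus negative
#' lobes, with the constant coefficients chosen so the lobes balance and the
#' kernel integrates to zero ("triple lobes" = one polarity centre, two
#' opposite-polarity flanks). Each `*_lobes` argument is a 2-column matrix
#' (or data.frame) with columns `omega` (centre offset, px) and `sigma`
#' (lobe scale, px).
#'
#' @param positive_lobes Matrix/data.frame of positive lobes. Default a
#'   single centre lobe at 0 with sigma 1.
#' @param negative_lobes Matrix/data.frame of negative lobes. Default two
#'   flanks at offsets -2 and +2 with sigma 1.
#' @param c_p,c_n Positive/negative coefficients. Defaults `1` and
#'   `c_p * N_p / N_n` so that `c_p * N_p == c_n * N_n` (zero-sum balance).
#' @return An `ordinal_params` object.
#' @export
ordinal_params <- function(positive_lobes = cbind(omega = 0, sigma = 1),
                           negative_lobes = cbind(omega = c(-2, 2),
                                                  sigma = c(1, 1)),
                           c_p = 1,
                           c_n = c_p * nrow(positive_lobes) /
                             nrow(negative_lobes)) {
  pl <- as.matrix(as.data.frame(positive_lobes))
  nl <- as.matrix(as.data.frame(negative_lobes))
  if (nrow(pl) < 1L || nrow(nl) < 1L)
    stop("ordinal_params: need at least one lobe of each sign", call. = FALSE)
  if (any(pl[, "sigma"] <= 0) || any(nl[, "sigma"] <= 0))
    stop("ordinal_params: all lobe sigmas must be > 0", call. = FALSE)
  structure(list(positive_lobes = pl, negative_lobes = nl,
                 c_p = c_p, c_n = c_n),
            class = "ordinal_params")
}

#' Discretized 1-D ordinal kernel
#'
#' Each Gaussian lobe is sampled on the integer support grid and normalized
#' to unit discrete mass, so a balanced parameter set (`c_p * N_p == c_n *
#' N_n`) yields a kernel summing to zero to machine precision.
#'
#' @param params An [ordinal_params()] object.
#' @param support Half-width of the kernel; must cover every lobe centre
#'   plus 3 lobe sigmas. Default: smallest such integer.
#' @return Numeric vector of length `2 * support + 1`.
#' @export
make_ordinal_kernel <- function(params, support = NULL) {
  stopifnot(inherits(params, "ordinal_params"))
  lobes <- rbind(params$positive_lobes, params$negative_lobes)
  need <- max(abs(lobes[, "omega"]) + 3 * lobes[, "sigma"])
  if (is.null(support)) support <- ceiling(need)
  support <- as.integer(support)
  if (support < need)
    stop("make_ordinal_kernel: support must cover all lobe centres ± 3 sigma",
         call. = FALSE)
  u <- seq(-support, support)
  lobe <- function(omega, sigma) {
    g <- exp(-(u - omega)^2 / (2 * sigma^2))
    g / sum(g)
  }
  k <- numeric(length(u))
  for (i in seq_len(nrow(params$positive_lobes)))
    k <- k + params$c_p * lobe(params$positive_lobes[i, "omega"],
                               params$positive_lobes[i, "sigma"])
  for (j in seq_len(nrow(params$negative_lobes)))
    k <- k - params$c_n * lobe(params$negative_lobes[j, "omega"],
                               params$negative_lobes[j, "sigma"])
  k
}

# Isotropic 2-D realization of the ordinal filter: positive centre Gaussian
# plus a negative ring realized as 4 negative Gaussians at +-omega on each
# axis, every lobe normalized to unit discrete mass so the kernel sums to 0.
make_ordinal_kernel_2d <- function(params) {
  stopifnot(inherits(params, "ordinal_params"))
  pos <- params$positive_lobes
  neg <- params$negative_lobes
  off <- unique(abs(neg[, "omega"]))
  sig_n <- neg[1L, "sigma"]
  need <- max(3 * pos[, "sigma"], off + 3 * sig_n)
  s <- as.integer(ceiling(need))
  xs <- seq(-s, s)
  x <- matrix(xs, 2 * s + 1, 2 * s + 1, byrow = TRUE)
  y <- matrix(xs, 2 * s + 1, 2 * s + 1)
  g2 <- function(cx, cy, sigma) {
    g <- exp(-((x - cx)^2 + (y - cy)^2) / (2 * sigma^2))
    g / sum(g)
  }
  k <- matrix(0, 2 * s + 1, 2 * s + 1)
  for (i in seq_len(nrow(pos)))
    k <- k + params$c_p * g2(0, 0, pos[i, "sigma"])
  ring <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  total_neg <- params$c_n * nrow(neg)        # balanced mass to distribute
  for (om in off) {
    w <- total_neg / (length(off) * 4)
    for (d in ring) k <- k - w * g2(om * d[1], om * d[2], sig_n)
  }
  k
}

#' Ordinal contour feature map S
#'
#' Convolves a Gabor feature map with the isotropic 2-D ordinal
#' (centre-surround) kernel, sharpening contour ridges and suppressing the
#' local mean.
#'
#' @param F A `feature_map` of kind `"gabor-F"` (or a plain matrix).
#' @param params An [ordinal_params()] object.
#' @param normalize Scale the result to `max(abs(S)) == 1`. Default `TRUE`.
#' @return A `feature_map` of kind `"ordinal-S"`.
#' @export
ordinal_feature_map <- function(F, params = ordinal_params(),
                                normalize = TRUE) {
  vals <- if (inherits(F, "feature_map")) {
    if (F$kind != "gabor-F")
      stop("ordinal_feature_map: expected a gabor-F feature map", call. = FALSE)
    F$values
  } else F
  k <- make_ordinal_kernel_2d(params)
  s <- conv2_reflect(vals, k)
  if (normalize) s <- normalize_map(s)
  feature_map(s, kind = "ordinal-S",
              params = c(if (inherits(F, "feature_map")) F$params,
                         list(ordinal = params)))
}

#' Full contour feature map of an image (Gabor bank then ordinal filter)
#'
#' @inheritParams gabor_feature_map
#' @param ordinal An [ordinal_params()] object.
#' @return A `feature_map` of kind `"ordinal-S"`.
#' @export
contour_feature_map <- function(image, bank = default_gabor_bank(),
                                ordinal = ordinal_params()) {
  ordinal_feature_map(gabor_feature_map(image, bank), ordinal)
}
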