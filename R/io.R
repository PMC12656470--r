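# Image and result I/O.

#' Read an image as a single-channel matrix in [0, 1]
#'
#' PNG/TIFF/JPEG via EBImage; colour images are converted to luminance,
#' 16-bit TIFF arrives already scaled to `[0, 1]`.
#'
#' @param path Image file path.
#' @return Numeric matrix, rows = image rows (y), columns = x.
#' @export
read_image <- function(path) {
  if (!file.exists(path))
    stop(sprintf("read_image: no such file '%s'", path), call. = FALSE)
  img <- EBImage::readImage(path)
  if (length(dim(img)) > 2L) img <- EBImage::channel(img, "gray")
  m <- t(EBImage::imageData(img))
  pmin(pmax(m, 0), 1)
}

#' Write a matrix or feature map as an image
#'
#' Feature maps (which live in `[-1, 1]`) are affinely rescaled to `[0, 1]`
#' for storage; plain matrices are clipped. TIFF output is written with
#' 32-bit samples for lossless inspection.
#'
#' @param x Numeric matrix or `feature_map`.
#' @param path Output path; format from the extension (png/tiff/jpeg).
#' @return The path, invisibly.
#' @export
write_image <- function(x, path) {
  v <- if (inherits(x, "feature_map")) (x$values + 1) / 2 else x
  v <- pmin(pmax(v, 0), 1)
  img <- EBImage::Image(t(v))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff"))
    EBImage::writeImage(img, path, type = "tiff", bits.per.sample = 32L)
  else EBImage::writeImage(img, path)
  invisible(path)
}

#' Write registration results to a directory
#'
#' Emits `transform.json` (kind, scale, rotation, translation, resolution
#' ratio), `matches.tsv` (one row per match, native-IR and visible-frame
#' coordinates, 6-decimal floats), `report.json` when metrics are present,
#' and optionally `overlay.png` (match lines over the visible image: green
#' inliers, purple rejects).
#'
#' @param result A `registration_result`.
#' @param dir Output directory (created if missing).
#' @param visible Visible image matrix; needed only for the overlay.
#' @param overlay Write `overlay.png`?
#' @return The directory, invisibly.
#' @export
write_result <- function(result, dir, visible = NULL, overlay = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tf <- result$transform
  jsonlite::write_json(
    list(kind = "similarity", s = tf$s, phi = tf$phi,
         tx = tf$tx, ty = tf$ty,
         resolution_ratio = result$resolution_ratio,
         counts = result$counts),
    file.path(dir, "transform.json"), auto_unbox = TRUE, digits = NA)
  write_matches(result$matches, file.path(dir, "matches.tsv"))
  if (!is.null(result$metrics)) {
    m <- result$metrics
    jsonlite::write_json(
      list(rmse = m$rmse, precision = m$precision, recall = m$recall,
           n_matches = m$n_matches, n_correct = m$n_correct,
           n_correspond = m$n_correspond),
      file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  if (overlay && !is.null(visible))
    write_overlay(result, visible, file.path(dir, "overlay.png"))
  invisible(dir)
}

#' Write a match table as TSV
#'
#' Columns `ir_x`, `ir_y` (native IR frame), `vis_x`, `vis_y` (visible
#' frame), `distance`, `stage`, `inlier`; UTF-8, LF, 6-decimal floats.
#'
#' @param matches Match data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_matches <- function(matches, path) {
  cols <- c("ir_x", "ir_y", "vis_x", "vis_y", "distance", "stage", "inlier")
  df <- matches[, cols, drop = FALSE]
  for (cl in c("ir_x", "ir_y", "vis_x", "vis_y", "distance"))
    df[[cl]] <- sprintf("%.6f", df[[cl]])
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(cols, collapse = "\t"), con, sep = "\n")
  if (nrow(df))
    writeLines(do.call(paste, c(unname(as.list(df)), sep = "\t")), con,
               sep = "\n")
  invisible(path)
}

#' Read a match table written by [write_matches()]
#' @param path TSV path.
#' @return Match data frame.
#' @export
read_matches <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (nrow(df)) df$inlier <- as.logical(df$inlier)
  df
}

# Rasterize match lines over the visible image (green inliers, purple
# rejects); IR endpoints are mapped through the recovered transform.
write_overlay <- function(result, visible, path) {
  h <- nrow(visible); w <- ncol(visible)
  rgb <- array(rep(pmin(pmax(visible, 0), 1), 3), dim = c(h, w, 3))
  m <- result$matches
  if (nrow(m)) {
    from <- transform_points(result$transform, cbind(m$ir_x, m$ir_y))
    for (i in seq_len(nrow(m))) {
      col <- if (isTRUE(m$inlier[i])) c(0.1, 0.9, 0.1) else c(0.6, 0.1, 0.7)
      rgb <- draw_line(rgb, from[i, 1], from[i, 2],
                       m$vis_x[i], m$vis_y[i], col)
    }
  }
  img <- EBImage::Image(aperm(rgb, c(2, 1, 3)), colormode = "Color")
  EBImage::writeImage(img, path)
  invisible(path)
}

# Simple Bresenham-style line rasterization into an h x w x 3 array.
draw_line <- function(rgb, x0, y0, x1, y1, col) {
  n <- max(2L, ceiling(max(abs(x1 - x0), abs(y1 - y0))) + 1L)
  xs <- round(seq(x0, x1, length.out = n))
  ys <- round(seq(y0, y1, length.out = n))
  ok <- xs >= 0 & xs < dim(rgb)[2] & ys >= 0 & ys < dim(rgb)[1]
  for (ch in 1:3)
    rgb[cbind(ys[ok] + 1, xs[ok] + 1, ch)] <- col[ch]
  rgb
}

#' Serialize keypoints and descriptors as TSV
#'
#' One row per descriptor: `x`, `y`, `orientation`, `scale`, then the 128
#' descriptor components.
#'
#' @param desc Result of [describe_all()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_descriptors <- function(desc, path) {
  v <- desc$vectors
  colnames(v) <- sprintf("d%03d", seq_len(ncol(v)))
  df <- cbind(desc$info[, c("x", "y", "orientation", "scale")], v)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
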