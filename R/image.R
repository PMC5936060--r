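# Densitometry of chromogenic ISH staining.
#
# Images live in memory as base-R integer matrices (grayscale, h x w) or
# h x w x 3 arrays (RGB), values 0..255.  The measurement pipeline is:
# invert to negative, convert to 8-bit grayscale, rasterize the hand-drawn
# signal and background polygons, and score each embryo as
# mean(signal ROI) - mean(background ROI).  Darker stain therefore maps to
# a higher score, and uniform illumination offsets cancel in the
# subtraction.

assert_gray <- function(img) {
  if (!is.matrix(img) || length(img) == 0L)
    stop("expected a non-empty grayscale image matrix")
  invisible(img)
}

#' Convert an image to 8-bit grayscale
#'
#' RGB pixels are collapsed with the unweighted channel mean — the ImageJ
#' default conversion — rounded half-to-even to an integer in 0..255.
#' Luminance (Rec. 601) weights are available via `weights`.
#' Already-grayscale input passes through unchanged.
#'
#' @param img Grayscale matrix or h x w x 3 RGB array, values 0..255.
#' @param weights Channel weights; `NULL` (default) = unweighted mean,
#'   `"luminance"` = c(0.299, 0.587, 0.114), or a numeric triple.
#' @return Integer grayscale matrix.
#' @export
to_grayscale_8bit <- function(img, weights = NULL) {
  if (length(img) == 0L) stop("empty image")
  if (is.matrix(img)) {
    storage.mode(img) <- "integer"
    return(img)
  }
  if (!(is.array(img) && length(dim(img)) == 3L && dim(img)[3] == 3L))
    stop("expected a grayscale matrix or an RGB array with 3 channels")
  if (is.null(weights)) {
    g <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  } else {
    if (identical(weights, "luminance")) weights <- c(0.299, 0.587, 0.114)
    weights <- weights / sum(weights)
    g <- img[, , 1] * weights[1] + img[, , 2] * weights[2] +
      img[, , 3] * weights[3]
  }
  g <- round(g)                       # round() is half-to-even in R
  dim(g) <- dim(img)[1:2]             # keep matrix shape for 1-pixel edges
  g[g < 0] <- 0L; g[g > 255] <- 255L
  storage.mode(g) <- "integer"
  g
}

#' Invert a grayscale image (photographic negative)
#'
#' @param img Grayscale matrix, values 0..255.
#' @return `255 - img`, integer matrix.  Involution: `invert(invert(x)) = x`.
#' @export
invert <- function(img) {
  assert_gray(img)
  out <- 255L - img
  storage.mode(out) <- "integer"
  out
}

#' Rasterize a polygon ROI to a pixel mask
#'
#' A pixel (row y, column x, 0-based) belongs to the mask iff its center
#' (x + 0.5, y + 0.5) lies inside the polygon under the even-odd rule,
#' decided by ray casting with the usual half-open edge convention, so
#' abutting polygons tile without overlap.
#'
#' @param vertices Two-column matrix (or list of `c(x, y)` pairs) of
#'   polygon vertices in pixel coordinates; x = column, y = row, 0-based.
#' @param height,width Image dimensions in pixels.
#' @return Logical height x width mask with at least one `TRUE` pixel.
#' @export
rasterize <- function(vertices, height, width) {
  v <- to_vertex_matrix(vertices)
  if (nrow(v) < 3L) stop("a polygon ROI needs at least 3 vertices")
  # candidate pixels: bounding box clipped to the image
  x0 <- max(0L, floor(min(v[, 1]))); x1 <- min(width - 1L, ceiling(max(v[, 1])))
  y0 <- max(0L, floor(min(v[, 2]))); y1 <- min(height - 1L, ceiling(max(v[, 2])))
  mask <- matrix(FALSE, height, width)
  if (x0 > x1 || y0 > y1) stop("degenerate ROI: polygon misses the image")
  px <- rep(seq.int(x0, x1) + 0.5, each = y1 - y0 + 1L)
  py <- rep(seq.int(y0, y1) + 0.5, times = x1 - x0 + 1L)
  inside <- rep(FALSE, length(px))
  n <- nrow(v)
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]; xj <- v[j, 1]; yj <- v[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  # matrix is filled column-major: rows y0..y1 within columns x0..x1
  mask[cbind(rep(seq.int(y0, y1) + 1L, times = x1 - x0 + 1L),
             rep(seq.int(x0, x1) + 1L, each = y1 - y0 + 1L))] <- inside
  if (!any(mask)) stop("degenerate ROI: rasterized area is 0 pixels")
  mask
}

to_vertex_matrix <- function(vertices) {
  if (is.list(vertices)) vertices <- do.call(rbind, lapply(vertices, as.numeric))
  v <- as.matrix(vertices)
  if (ncol(v) != 2L) stop("vertices must be (x, y) pairs")
  storage.mode(v) <- "double"
  v
}

#' Mean pixel intensity under a polygon ROI
#'
#' Arithmetic mean of the pixel values whose centers fall inside the
#' polygon, kept in full floating precision (only stored images are 8-bit).
#'
#' @param img Grayscale matrix.
#' @param roi Polygon vertices as in [rasterize()], or a logical mask.
#' @return The mean intensity (double).
#' @export
mean_intensity <- function(img, roi) {
  assert_gray(img)
  mask <- if (is.logical(roi) && is.matrix(roi)) roi
          else rasterize(roi, nrow(img), ncol(img))
  mean(img[mask])
}

#' Score one embryo: background-subtracted mean signal intensity
#'
#' The score is mean(signal ROI) - mean(background ROI) on the inverted
#' 8-bit image.  The two ROIs must enclose (nearly) the same pixel area —
#' the background polygon is a copy of the signal shape placed over
#' unstained tissue — enforced by `area_tolerance`.  Negative scores
#' (background darker than signal) are legitimate, flagged and retained.
#'
#' @param img Inverted grayscale matrix.
#' @param signal,background Polygon vertices for the stained and the
#'   unstained region.
#' @param embryo_id Identifier carried into the output record.
#' @param area_tolerance Maximum relative area mismatch
#'   `|A_sig - A_bg| / A_sig` (default 0.01).
#' @return A one-row data.frame: `embryo_id`, `signal_mean`,
#'   `background_mean`, `score`, `negative_flag`, `area_px`.
#' @export
score_embryo <- function(img, signal, background, embryo_id = NA_character_,
                         area_tolerance = 0.01) {
  assert_gray(img)
  m_sig <- rasterize(signal, nrow(img), ncol(img))
  m_bg <- rasterize(background, nrow(img), ncol(img))
  a_sig <- sum(m_sig); a_bg <- sum(m_bg)
  if (abs(a_sig - a_bg) / a_sig > area_tolerance)
    stop(sprintf(
      "unequal ROI areas: signal %d px vs background %d px (tolerance %.1f%%)",
      a_sig, a_bg, 100 * area_tolerance))
  s <- mean(img[m_sig]); b <- mean(img[m_bg])
  data.frame(embryo_id = as.character(embryo_id),
             signal_mean = s, background_mean = b,
             score = s - b, negative_flag = (s - b) < 0,
             area_px = a_sig,
             stringsAsFactors = FALSE)
}

#' Translate an ROI polygon
#'
#' Clones the signal polygon by an offset, guaranteeing an equal-area
#' background ROI by construction.
#'
#' @param vertices Polygon vertices.
#' @param dx,dy Offset in pixels.
#' @return Translated vertex matrix.
#' @export
translate_roi <- function(vertices, dx, dy) {
  v <- to_vertex_matrix(vertices)
  v[, 1] <- v[, 1] + dx
  v[, 2] <- v[, 2] + dy
  v
}

## ---- image and ROI file I/O -------------------------------------------

#' Read a PNG or TIFF image as 0..255 values
#' @param path Image path (`.png`, `.tif`, `.tiff`).
#' @return Grayscale matrix or RGB array, values 0..255.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                png = png::readPNG(path),
                tif = , tiff = tiff::readTIFF(path),
                stop("unsupported image format: .", ext))
  img <- round(raw * 255)
  if (length(dim(img)) == 3L && dim(img)[3] == 4L)
    img <- img[, , 1:3, drop = FALSE]      # drop alpha
  if (length(dim(img)) == 3L && dim(img)[3] == 1L)
    img <- img[, , 1]
  storage.mode(img) <- "integer"
  img
}

#' Write a 0..255 image to PNG or TIFF
#' @param img Grayscale matrix or RGB array, values 0..255.
#' @param path Output path; format chosen from the extension.
#' @export
write_image <- function(img, path) {
  x <- img / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(x, path),
         tif = , tiff = tiff::writeTIFF(x, path),
         stop("unsupported image format: .", ext))
  invisible(path)
}

#' Read embryo ROI definitions from JSON
#'
#' Accepts either one record
#' `{"embryo_id": ..., "signal": [[x,y],...], "background": [[x,y],...]}`
#' or an array of such records (one combined file per clutch).
#'
#' @param path JSON path.
#' @return List of records, each with `embryo_id` and two vertex matrices.
#' @export
read_roi_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyMatrix = TRUE,
                          simplifyDataFrame = FALSE)
  if (!is.null(x$embryo_id)) x <- list(x)
  lapply(x, function(r) list(embryo_id = as.character(r$embryo_id),
                             signal = to_vertex_matrix(r$signal),
                             background = to_vertex_matrix(r$background)))
}

#' Write embryo ROI definitions to JSON
#' @param rois List of records as returned by [read_roi_json()].
#' @param path Output path.
#' @export
write_roi_json <- function(rois, path) {
  jsonlite::write_json(
    lapply(rois, function(r)
      list(embryo_id = r$embryo_id,
           signal = unname(to_vertex_matrix(r$signal)),
           background = unname(to_vertex_matrix(r$background)))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Batch-convert a directory of images to inverted 8-bit grayscale
#'
#' Mirrors a Fiji batch macro: every readable PNG/TIFF in `input_dir` is
#' inverted, converted to 8-bit grayscale and written to `output_dir`
#' under the same file stem (as PNG).  Non-image files are skipped with a
#' warning.
#'
#' @param input_dir,output_dir Directories; `output_dir` is created.
#' @return Number of images converted (invisibly also the output paths).
#' @export
batch_convert <- function(input_dir, output_dir) {
  if (!dir.exists(input_dir)) stop("cannot read directory: ", input_dir)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  files <- list.files(input_dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  done <- character(0)
  for (f in files) {
    ext <- tolower(tools::file_ext(f))
    if (!ext %in% c("png", "tif", "tiff")) {
      warning("skipping non-image file: ", basename(f), call. = FALSE)
      next
    }
    img <- invert(to_grayscale_8bit(read_image(f)))
    out <- file.path(output_dir,
                     paste0(tools::file_path_sans_ext(basename(f)), ".png"))
    write_image(img, out)
    done <- c(done, out)
  }
  structure(length(done), paths = done)
}
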