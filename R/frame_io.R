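#' A single calibrated OCT cross-section
#'
#' Container for one grayscale frame of a pullback: a square intensity grid in
#' \[0, 1\], the frame's ordinal position, its calibration and the pixel
#' position of the imaging-catheter center (the polar origin). The catheter is
#' assumed at the image center unless a detected position is supplied.
#'
#' @param intensity square numeric matrix with finite values in \[0, 1\],
#'   indexed \[row, col\].
#' @param frame_index 0-based ordinal of the frame within its pullback.
#' @param calibration a [calibration_spec()].
#' @param center numeric `(row, col)` of the catheter center in pixel
#'   coordinates; default is the image center.
#' @return an object of class `oct_frame`.
#' @export
oct_frame <- function(intensity, frame_index = 0L,
                      calibration = calibration_spec(), center = NULL) {
  stopifnot(is.matrix(intensity), is.numeric(intensity))
  if (nrow(intensity) != ncol(intensity))
    stop_octlumen("frame intensity grid must be square", "octlumen_shape_error")
  if (!all(is.finite(intensity)) || min(intensity) < 0 || max(intensity) > 1)
    stop_octlumen("intensities must be finite and in [0, 1]", "octlumen_range_error")
  stopifnot(inherits(calibration, "calibration_spec"))
  n <- nrow(intensity)
  center <- center %||% c((n + 1) / 2, (n + 1) / 2)
  if (length(center) != 2L || any(center <= 1) || any(center >= n))
    stop_octlumen("catheter center must lie strictly inside the grid",
                  "octlumen_geometry_error")
  structure(list(intensity = intensity,
                 frame_index = as.integer(frame_index),
                 calibration = calibration,
                 center = as.numeric(center)),
            class = "oct_frame")
}

#' @export
print.oct_frame <- function(x, ...) {
  cat(sprintf("oct_frame %d: %dx%d px, %.4g mm/px, center (%.1f, %.1f)\n",
              x$frame_index, nrow(x$intensity), ncol(x$intensity),
              x$calibration$pixel_spacing_mm, x$center[1], x$center[2]))
  invisible(x)
}

#' NTSC grayscale conversion
#'
#' Converts an RGB image to grayscale by the NTSC 1953 luma weighted sum
#' `0.299 R + 0.587 G + 0.114 B`.
#'
#' @param rgb numeric array `height x width x 3` with channels in \[0, 1\].
#' @return numeric matrix of the same spatial size, values in \[0, 1\].
#' @examples
#' rgb_to_gray_ntsc(array(c(1, 0, 0), c(1, 1, 3)))  # 0.299
#' @export
rgb_to_gray_ntsc <- function(rgb) {
  if (!is.array(rgb) || length(dim(rgb)) != 3L || dim(rgb)[3] != 3L)
    stop_octlumen("expected an RGB array with 3 channels", "octlumen_shape_error")
  g <- 0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
  matrix(g, dim(rgb)[1], dim(rgb)[2])
}

#' Remove colored overlays
#'
#' Calibration markers, scale bars and text annotations are burned into OCT
#' exports as saturated color; the underlying tissue signal is achromatic.
#' Every pixel whose channel spread `max(R,G,B) - min(R,G,B)` exceeds the
#' saturation tolerance is replaced by background (0) in all channels.
#' The operation is idempotent.
#'
#' @param rgb numeric array `height x width x 3`, channels in a common
#'   \[0, 1\] range.
#' @param tolerance saturation tolerance as a fraction of full scale
#'   (default 0.1); spreads strictly above it mark a pixel as colored.
#' @return the overlay-free RGB array.
#' @export
remove_color_overlays <- function(rgb, tolerance = 0.1) {
  if (!is.array(rgb) || length(dim(rgb)) != 3L || dim(rgb)[3] != 3L)
    stop_octlumen("expected an RGB array with 3 channels", "octlumen_shape_error")
  spread <- pmax(rgb[, , 1], rgb[, , 2], rgb[, , 3]) -
    pmin(rgb[, , 1], rgb[, , 2], rgb[, , 3])
  colored <- spread > tolerance
  out <- rgb
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[colored] <- 0
    out[, , ch] <- plane
  }
  out
}

# read one raster file into a [row, col] matrix or [row, col, 3] array in [0,1]
read_raster <- function(path) {
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop_octlumen(
                    sprintf("cannot read image '%s': %s", path, conditionMessage(e)),
                    "octlumen_input_format_error"))
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) return(t(a))
  # EBImage stores (x, y, channel); drop alpha if present, transpose to [row, col]
  if (dim(a)[3] >= 3L) return(aperm(a[, , 1:3, drop = FALSE], c(2, 1, 3)))
  t(a[, , 1])
}

raw_frame_to_oct <- function(px, index, calibration, center, overlay_tolerance) {
  if (length(dim(px)) == 3L) {
    px <- remove_color_overlays(px, tolerance = overlay_tolerance)
    px <- rgb_to_gray_ntsc(px)
  }
  px[px < 0] <- 0; px[px > 1] <- 1
  oct_frame(px, frame_index = index, calibration = calibration, center = center)
}

#' Read an OCT pullback
#'
#' Reads a multiframe DICOM pullback, a directory of raster frames (PNG/TIFF,
#' in lexicographic order), or a single raster frame. RGB sources pass through
#' [remove_color_overlays()] and [rgb_to_gray_ntsc()]; grayscale sources are
#' rescaled to \[0, 1\]. When the DICOM header carries a pixel-spacing tag it
#' overrides the calibration's spacing.
#'
#' @param path file or directory path.
#' @param calibration a [calibration_spec()].
#' @param center optional catheter center `(row, col)` applied to every frame.
#' @param overlay_tolerance saturation tolerance for [remove_color_overlays()].
#' @return list of [oct_frame()] objects with contiguous 0-based indices.
#' @export
read_pullback <- function(path, calibration = calibration_spec(),
                          center = NULL, overlay_tolerance = 0.1) {
  if (!file.exists(path))
    stop_octlumen(sprintf("input '%s' does not exist", path),
                  "octlumen_input_format_error")
  raster_ext <- c("png", "tif", "tiff")
  if (dir.exists(path)) {
    files <- sort(list.files(path, full.names = TRUE,
                             pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE))
    if (length(files) == 0L)
      stop_octlumen("pullback directory contains no frames", "octlumen_empty_input_error")
    raw <- lapply(files, read_raster)
  } else if (tolower(tools::file_ext(path)) %in% raster_ext) {
    raw <- list(read_raster(path))
  } else {
    dcm <- read_dicom(path)
    if (!is.null(dcm$pixel_spacing_mm))
      calibration <- calibration_spec(
        pixel_spacing_mm = dcm$pixel_spacing_mm,
        catheter_gauge_french = calibration$catheter_gauge_french,
        catheter_diameter_mm = calibration$catheter_diameter_mm,
        french_to_mm = calibration$french_to_mm)
    raw <- dcm$frames
  }
  if (length(raw) == 0L)
    stop_octlumen("input contains zero frames", "octlumen_empty_input_error")
  lapply(seq_along(raw), function(i)
    raw_frame_to_oct(raw[[i]], i - 1L, calibration, center, overlay_tolerance))
}

#' Write a frame to disk
#'
#' `write_frame_tiff()` stores the full 16-bit intensity grid losslessly
#' (a frame quantized to the 16-bit grid reads back pixel-identical);
#' `write_frame_png()` writes an 8-bit PNG for quick inspection.
#'
#' @param frame an [oct_frame()].
#' @param path output path (`.tif` / `.png`).
#' @return `path`, invisibly.
#' @export
write_frame_tiff <- function(frame, path) {
  stopifnot(inherits(frame, "oct_frame"))
  tiff::writeTIFF(frame$intensity, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_frame_tiff
#' @export
write_frame_png <- function(frame, path) {
  stopifnot(inherits(frame, "oct_frame"))
  EBImage::writeImage(EBImage::Image(t(frame$intensity)), path, type = "png")
  invisible(path)
}
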