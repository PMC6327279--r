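#' Polar-resampled frame
#'
#' A frame resampled over (angle, radius) about the catheter center: row `a`
#' holds the A-line at angle `theta_a = 2*pi*(a-1)/n_angles` (angle 0 along
#' +x, counterclockwise), column `r` the sample at radius `r-1` bins from the
#' center. All segmentation happens in this domain, where the vessel wall is a
#' straightened, roughly vertical band.
#'
#' @param values numeric matrix, rows = angle bins, columns = radius bins.
#' @param radial_spacing_mm physical length of one radius bin in mm.
#' @param calibration a [calibration_spec()].
#' @return an object of class `polar_image`.
#' @export
polar_image <- function(values, radial_spacing_mm, calibration = calibration_spec()) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (nrow(values) < 8L || ncol(values) < 2L)
    stop_octlumen("polar grid needs >= 8 angles and >= 2 radii", "octlumen_shape_error")
  if (!all(is.finite(values)))
    stop_octlumen("polar values must be finite", "octlumen_range_error")
  stopifnot(is.numeric(radial_spacing_mm), radial_spacing_mm > 0,
            inherits(calibration, "calibration_spec"))
  structure(list(values = values,
                 n_angles = nrow(values),
                 n_radii = ncol(values),
                 radial_spacing_mm = radial_spacing_mm,
                 calibration = calibration),
            class = "polar_image")
}

#' @export
print.polar_image <- function(x, ...) {
  cat(sprintf("polar_image: %d angles x %d radii, %.4g mm/bin\n",
              x$n_angles, x$n_radii, x$radial_spacing_mm))
  invisible(x)
}

#' Per-angle lumen border
#'
#' The lumen border as a radius (in fractional bins) for each angle row of a
#' polar image, with a validity flag for angles where no border was found.
#'
#' @param radius_per_angle numeric vector of radii in bins (0-based,
#'   fractional allowed).
#' @param valid_mask logical vector of the same length; `FALSE` marks angles
#'   without a detected border.
#' @param n_radii radial extent of the source polar grid (for bounds checking);
#'   default: large enough for the data.
#' @return an object of class `polar_contour`.
#' @export
polar_contour <- function(radius_per_angle,
                          valid_mask = rep(TRUE, length(radius_per_angle)),
                          n_radii = NULL) {
  stopifnot(is.numeric(radius_per_angle), is.logical(valid_mask),
            length(valid_mask) == length(radius_per_angle))
  n_radii <- n_radii %||% (max(radius_per_angle[valid_mask], 0) + 1)
  r <- radius_per_angle[valid_mask]
  if (length(r) && (min(r) < 0 || max(r) > n_radii - 1))
    stop_octlumen("valid radii must lie in [0, n_radii - 1]", "octlumen_range_error")
  structure(list(radius_per_angle = as.numeric(radius_per_angle),
                 valid_mask = valid_mask,
                 n_angles = length(radius_per_angle),
                 n_radii = n_radii),
            class = "polar_contour")
}

#' @export
print.polar_contour <- function(x, ...) {
  cat(sprintf("polar_contour: %d angles, %d valid, radius %.1f-%.1f bins\n",
              x$n_angles, sum(x$valid_mask),
              min(x$radius_per_angle[x$valid_mask]),
              max(x$radius_per_angle[x$valid_mask])))
  invisible(x)
}

#' Cartesian-to-polar resampling
#'
#' Resamples a frame onto an (angle, radius) grid about the catheter center by
#' bilinear interpolation. The sample at angle row `a` and radius column `r`
#' is taken at `center + (r-1) * (cos theta_a, sin theta_a)` in pixel
#' coordinates, with `theta_a = 2*pi*(a-1)/n_angles` (x = column offset,
#' y = row offset). This straightens the circular vessel wall into a vertical
#' band with the catheter along the left edge.
#'
#' @param frame an [oct_frame()].
#' @param n_angles number of angle rows (default 360, i.e. 1-degree bins).
#' @param n_radii number of radius columns; default (and maximum) is the
#'   largest radius fully inside the image.
#' @return a [polar_image()] with `radial_spacing_mm` equal to the pixel
#'   spacing.
#' @export
to_polar <- function(frame, n_angles = 360L, n_radii = NULL) {
  stopifnot(inherits(frame, "oct_frame"), n_angles >= 8L)
  n <- nrow(frame$intensity)
  max_r <- floor(min(frame$center[1] - 1, n - frame$center[1],
                     frame$center[2] - 1, n - frame$center[2]))
  n_radii <- n_radii %||% (max_r + 1)
  if (n_radii - 1 > max_r)
    stop_octlumen("n_radii exceeds the distance from center to the image edge",
                  "octlumen_geometry_error")
  theta <- 2 * pi * (seq_len(n_angles) - 1) / n_angles
  rad <- seq_len(n_radii) - 1
  # sample positions: rows vary with angle, cols with radius
  col_s <- frame$center[2] + outer(cos(theta), rad)   # x = column offset
  row_s <- frame$center[1] + outer(sin(theta), rad)   # y = row offset
  vals <- bilinear_sample(frame$intensity, row_s, col_s)
  polar_image(vals, radial_spacing_mm = frame$calibration$pixel_spacing_mm,
              calibration = frame$calibration)
}

# vectorized bilinear interpolation of matrix m at fractional (row, col)
bilinear_sample <- function(m, row_s, col_s) {
  n <- nrow(m); k <- ncol(m)
  r0 <- pmin(pmax(floor(row_s), 1), n - 1); c0 <- pmin(pmax(floor(col_s), 1), k - 1)
  fr <- row_s - r0; fc <- col_s - c0
  fr <- pmin(pmax(fr, 0), 1); fc <- pmin(pmax(fc, 0), 1)
  idx <- function(r, c) m[cbind(as.vector(r), as.vector(c))]
  v <- (1 - fr) * (1 - fc) * idx(r0, c0) +
       (1 - fr) * fc       * idx(r0, c0 + 1) +
       fr       * (1 - fc) * idx(r0 + 1, c0) +
       fr       * fc       * idx(r0 + 1, c0 + 1)
  matrix(v, nrow = nrow(row_s), ncol = ncol(row_s))
}

#' Polar contour to Cartesian points
#'
#' Maps a fully valid polar contour back to an ordered, closed list of
#' Cartesian points in mm: point `a` is
#' `center_mm + radius_a * spacing * (cos theta_a, sin theta_a)`. The first
#' point is logically adjacent to the last (the polygon is closed without
#' repeating the first vertex).
#'
#' @param contour a [polar_contour()] with all angles valid.
#' @param frame the source [oct_frame()] (supplies center and pixel spacing).
#' @return data.frame with columns `angle_deg`, `radius_mm`, `x_mm`, `y_mm`.
#' @export
contour_to_cartesian <- function(contour, frame) {
  stopifnot(inherits(contour, "polar_contour"), inherits(frame, "oct_frame"))
  if (!all(contour$valid_mask))
    stop_octlumen("contour has invalid angles; fill gaps before back-transforming",
                  "octlumen_incomplete_contour_error")
  sp <- frame$calibration$pixel_spacing_mm
  theta <- 2 * pi * (seq_len(contour$n_angles) - 1) / contour$n_angles
  r_mm <- contour$radius_per_angle * sp
  data.frame(angle_deg = theta * 180 / pi,
             radius_mm = r_mm,
             x_mm = frame$center[2] * sp + r_mm * cos(theta),
             y_mm = frame$center[1] * sp + r_mm * sin(theta))
}

#' Export per-frame contours
#'
#' Writes contours of a pullback as one flat CSV (columns `frame_index`,
#' `angle_deg`, `radius_mm`, `x_mm`, `y_mm`) or one JSON document.
#'
#' @param contours named or unnamed list of data.frames as returned by
#'   [contour_to_cartesian()], one per frame in pullback order.
#' @param path output path; format from extension (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
export_contours <- function(contours, path) {
  tab <- do.call(rbind, lapply(seq_along(contours), function(i)
    cbind(frame_index = i - 1L, contours[[i]])))
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    write.csv(tab, path, row.names = FALSE)
  } else if (ext == "json") {
    jsonlite::write_json(contours, path, digits = NA, auto_unbox = TRUE)
  } else {
    stop_octlumen("contour export supports .csv and .json", "octlumen_parameter_error")
  }
  invisible(path)
}
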