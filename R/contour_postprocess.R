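#' Savitzky-Golay smoothing weights
#'
#' Derives the symmetric convolution weights of the Savitzky-Golay filter:
#' smoothing with them is exactly equivalent to a moving least-squares fit of
#' a degree-`order` polynomial over the window. The center-point weights are
#' obtained from the polynomial design matrix `X` on indices `-n..n`
#' (window = 2n+1) as the middle row of the hat matrix
#' `X (X'X)^-1 X'`; they are symmetric and sum to 1.
#'
#' @param window odd window width 2n+1 (default 35).
#' @param order polynomial order < window (default 2).
#' @return an object of class `savgol_spec` with fields `window`, `order` and
#'   normalized `coefficients` (length `window`).
#' @examples
#' savgol_coefficients(5, 2)$coefficients * 35  # (-3, 12, 17, 12, -3)
#' @export
savgol_coefficients <- function(window = 35L, order = 2L) {
  window <- as.integer(window); order <- as.integer(order)
  if (window < 1L || window %% 2L == 0L)
    stop_octlumen("window must be a positive odd integer", "octlumen_parameter_error")
  if (order < 0L || order >= window)
    stop_octlumen("polynomial order must satisfy 0 <= order < window",
                  "octlumen_parameter_error")
  n <- (window - 1L) %/% 2L
  X <- outer(-n:n, 0:order, `^`)
  h <- X %*% solve(crossprod(X), t(X))
  w <- as.numeric(h[n + 1L, ])
  w <- w / sum(w)                      # already 1 up to round-off
  structure(list(window = window, order = order, coefficients = w),
            class = "savgol_spec")
}

#' @export
print.savgol_spec <- function(x, ...) {
  cat(sprintf("Savitzky-Golay filter: window %d, order %d\n", x$window, x$order))
  invisible(x)
}

#' Smooth a closed lumen contour
#'
#' Applies the Savitzky-Golay filter to the radius-per-angle signal of a
#' closed contour. The angle axis is periodic, so the convolution wraps
#' around; the sequence length and mean radius are preserved exactly, and any
#' quadratic-in-index sequence would be reproduced exactly (the defining
#' property of the filter).
#'
#' @param contour a fully valid [polar_contour()].
#' @param spec a [savgol_spec()]; the window must be shorter than the number
#'   of angles.
#' @return the smoothed [polar_contour()].
#' @export
smooth_contour <- function(contour, spec = savgol_coefficients()) {
  stopifnot(inherits(contour, "polar_contour"), inherits(spec, "savgol_spec"))
  if (!all(contour$valid_mask))
    stop_octlumen("contour has invalid angles; fill gaps before smoothing",
                  "octlumen_incomplete_contour_error")
  if (spec$window >= contour$n_angles)
    stop_octlumen("window must be smaller than the number of angles",
                  "octlumen_parameter_error")
  r <- contour$radius_per_angle
  # symmetric weights: circular correlation == circular convolution
  rs <- as.numeric(stats::filter(r, spec$coefficients, method = "convolution",
                                 sides = 2, circular = TRUE))
  polar_contour(pmin(pmax(rs, 0), contour$n_radii - 1), n_radii = contour$n_radii)
}
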