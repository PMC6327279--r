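#' Preprocessing parameters
#'
#' @param median_window odd window side of the despeckling median filter
#'   (default 5, i.e. 5x5).
#' @param gaussian_sigma_bins standard deviation of the Gaussian smoothing
#'   stage, in bins (default 2: blurs residual speckle without displacing the
#'   intima leading edge by more than about one bin).
#' @param threshold_method automatic binarization rule; currently `"otsu"`.
#' @return an object of class `preprocess_params`.
#' @export
preprocess_params <- function(median_window = 5L, gaussian_sigma_bins = 2,
                              threshold_method = "otsu") {
  median_window <- as.integer(median_window)
  if (median_window < 3L || median_window %% 2L == 0L)
    stop_octlumen("median_window must be odd and >= 3", "octlumen_parameter_error")
  stopifnot(is.numeric(gaussian_sigma_bins), gaussian_sigma_bins > 0)
  threshold_method <- match.arg(threshold_method, "otsu")
  structure(list(median_window = median_window,
                 gaussian_sigma_bins = gaussian_sigma_bins,
                 threshold_method = threshold_method),
            class = "preprocess_params")
}

#' Remove the imaging-catheter ring
#'
#' The catheter sheath appears as a bright vertical band at known radius on
#' the left of the polar image. Its physical diameter is known from the
#' calibration, so the columns covering radii up to
#' `catheter_diameter_mm / 2 + margin_mm` are blanked in every angle row;
#' all other values are untouched.
#'
#' @param polar a [polar_image()].
#' @param calibration a [calibration_spec()]; defaults to the one carried by
#'   `polar`.
#' @param margin_mm extra radial margin beyond the physical catheter radius,
#'   covering the sheath's bright reflection (default 0.05 mm).
#' @return the blanked [polar_image()].
#' @export
remove_catheter <- function(polar, calibration = polar$calibration,
                            margin_mm = 0.05) {
  stopifnot(inherits(polar, "polar_image"), inherits(calibration, "calibration_spec"))
  w <- ceiling((calibration$catheter_diameter_mm / 2 + margin_mm) /
                 polar$radial_spacing_mm)
  if (w >= polar$n_radii)
    stop_octlumen("catheter region covers the whole radial extent",
                  "octlumen_geometry_error")
  if (w > 0) polar$values[, seq_len(w)] <- 0
  polar
}

#' Despeckle and smooth a polar image
#'
#' Residual-blood speckle is suppressed with a square median filter, then the
#' image is smoothed by Gaussian convolution. Both stages replicate the border
#' rows/columns, so no dark halo forms at the catheter-adjacent edge. The
#' median stage is computed on a 16-bit grid (quantization below 1e-4).
#'
#' @param polar a [polar_image()].
#' @param params a [preprocess_params()].
#' @return the filtered [polar_image()]; values stay within the input range.
#' @export
denoise <- function(polar, params = preprocess_params()) {
  stopifnot(inherits(polar, "polar_image"), inherits(params, "preprocess_params"))
  v <- polar$values
  p <- (params$median_window - 1L) %/% 2L
  vp <- pad_replicate(v, p)
  vm <- EBImage::medianFilter(vp, p)
  v <- vm[(p + 1):(p + nrow(v)), (p + 1):(p + ncol(v)), drop = FALSE]
  k <- gaussian_kernel(params$gaussian_sigma_bins)
  v <- EBImage::filter2(v, k, boundary = "replicate")
  # convex weights: clip only numerical overshoot
  lo <- min(polar$values); hi <- max(polar$values)
  polar$values <- pmin(pmax(v, lo), hi)
  polar
}

# normalized 2-D Gaussian kernel, radius 3*sigma
gaussian_kernel <- function(sigma) {
  r <- max(ceiling(3 * sigma), 1)
  g <- dnorm(-r:r, sd = sigma)
  k <- outer(g, g)
  k / sum(k)
}

#' Automatic thresholding of a polar image
#'
#' Binarizes the preprocessed polar image with an automatic global threshold.
#' The default rule is Otsu's between-class-variance maximization over a
#' 256-bin histogram of \[0, 1\]; pixels strictly above the threshold are
#' foreground (tissue).
#'
#' @param polar a [polar_image()] with values in \[0, 1\].
#' @param params a [preprocess_params()].
#' @return logical matrix of the polar grid size (`TRUE` = tissue), with the
#'   chosen threshold in attribute `"threshold"`.
#' @export
binarize <- function(polar, params = preprocess_params()) {
  stopifnot(inherits(polar, "polar_image"))
  v <- polar$values
  if (max(v) - min(v) < .Machine$double.eps * 8)
    stop_octlumen("image is constant; histogram is degenerate",
                  "octlumen_degenerate_histogram_error")
  th <- EBImage::otsu(v, range = c(0, 1), levels = 256L)
  structure(v > th, threshold = th)
}
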