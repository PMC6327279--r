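#' Imaging calibration
#'
#' Physical calibration of one OCT acquisition: the isotropic pixel spacing
#' and the outer diameter of the imaging catheter. The catheter diameter is
#' normally derived from its gauge (1 French = 1/3 mm), but the derived value
#' can be overridden when the vendor quotes a different physical diameter
#' (e.g. 0.91 mm for a 2.7 Fr imaging catheter).
#'
#' @param pixel_spacing_mm length of one pixel side in mm (isotropic).
#'   The default 0.01 mm/px is consistent with the 10-20 um axial
#'   resolution of intracoronary OCT.
#' @param catheter_gauge_french catheter gauge in French units.
#' @param catheter_diameter_mm physical catheter outer diameter in mm; when
#'   `NULL`, derived as `catheter_gauge_french * french_to_mm`.
#' @param french_to_mm French-to-mm conversion factor (default 1/3 mm per Fr).
#' @return an object of class `calibration_spec`.
#' @examples
#' calibration_spec()                               # 2.7 Fr -> 0.90 mm
#' calibration_spec(catheter_diameter_mm = 0.91)    # vendor-quoted diameter
#' @export
calibration_spec <- function(pixel_spacing_mm = 0.01,
                             catheter_gauge_french = 2.7,
                             catheter_diameter_mm = NULL,
                             french_to_mm = 1 / 3) {
  stopifnot(is.numeric(pixel_spacing_mm), length(pixel_spacing_mm) == 1L,
            is.finite(pixel_spacing_mm), pixel_spacing_mm > 0,
            is.numeric(catheter_gauge_french), catheter_gauge_french > 0,
            is.numeric(french_to_mm), french_to_mm > 0)
  derived <- is.null(catheter_diameter_mm)
  if (derived) catheter_diameter_mm <- catheter_gauge_french * french_to_mm
  stopifnot(is.numeric(catheter_diameter_mm), length(catheter_diameter_mm) == 1L,
            is.finite(catheter_diameter_mm), catheter_diameter_mm > 0)
  structure(list(pixel_spacing_mm = pixel_spacing_mm,
                 catheter_gauge_french = catheter_gauge_french,
                 catheter_diameter_mm = catheter_diameter_mm,
                 french_to_mm = french_to_mm,
                 diameter_derived = derived),
            class = "calibration_spec")
}

#' @export
print.calibration_spec <- function(x, ...) {
  cat(sprintf("OCT calibration: %.4g mm/px, catheter %.2g Fr = %.3g mm%s\n",
              x$pixel_spacing_mm, x$catheter_gauge_french, x$catheter_diameter_mm,
              if (x$diameter_derived) "" else " (explicit override)"))
  invisible(x)
}
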