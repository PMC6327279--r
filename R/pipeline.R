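#' Pipeline configuration
#'
#' Bundles every tunable of the segmentation pipeline. The defaults are the
#' method's standard operating point: 5x5 median window, Gaussian sigma 2
#' bins, Otsu thresholding, radius-5 disk for opening/closing, 2 mm
#' bifurcation cutoff, Savitzky-Golay window 35 / order 2, 360 angle bins.
#'
#' @param calibration a [calibration_spec()].
#' @param preprocess a [preprocess_params()].
#' @param morphology a [morphology_params()].
#' @param savgol a [savgol_coefficients()] spec.
#' @param n_angles polar angle bins (default 360).
#' @param n_radii polar radius bins; `NULL` = largest in-image radius.
#' @param bifurcation_cutoff_mm gap-length cutoff flagging bifurcations.
#' @param catheter_margin_mm extra blanking margin beyond the catheter radius.
#' @param min_component_area pre-bridging component floor in pixels;
#'   `NULL` = area of the structuring disk.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(calibration = calibration_spec(catheter_diameter_mm = 0.91),
                            preprocess = preprocess_params(),
                            morphology = morphology_params(),
                            savgol = savgol_coefficients(35L, 2L),
                            n_angles = 360L,
                            n_radii = NULL,
                            bifurcation_cutoff_mm = 2,
                            catheter_margin_mm = 0.05,
                            min_component_area = NULL) {
  stopifnot(inherits(calibration, "calibration_spec"),
            inherits(preprocess, "preprocess_params"),
            inherits(morphology, "morphology_params"),
            inherits(savgol, "savgol_spec"),
            n_angles >= 8L, bifurcation_cutoff_mm > 0, catheter_margin_mm >= 0)
  structure(list(calibration = calibration, preprocess = preprocess,
                 morphology = morphology, savgol = savgol,
                 n_angles = as.integer(n_angles),
                 n_radii = if (is.null(n_radii)) NULL else as.integer(n_radii),
                 bifurcation_cutoff_mm = bifurcation_cutoff_mm,
                 catheter_margin_mm = catheter_margin_mm,
                 min_component_area = min_component_area),
            class = "pipeline_config")
}

# flat key=value serialization of a config
config_to_keyvals <- function(config) {
  c(pixel_spacing_mm = config$calibration$pixel_spacing_mm,
    catheter_gauge_french = config$calibration$catheter_gauge_french,
    catheter_diameter_mm = config$calibration$catheter_diameter_mm,
    median_window = config$preprocess$median_window,
    gaussian_sigma_bins = config$preprocess$gaussian_sigma_bins,
    threshold_method = config$preprocess$threshold_method,
    disk_radius_bins = config$morphology$disk_radius_bins,
    savgol_window = config$savgol$window,
    savgol_order = config$savgol$order,
    n_angles = config$n_angles,
    n_radii = config$n_radii %||% "auto",
    bifurcation_cutoff_mm = config$bifurcation_cutoff_mm,
    catheter_margin_mm = config$catheter_margin_mm,
    min_component_area = config$min_component_area %||% "auto")
}

#' Write / read a pipeline configuration
#'
#' Plain `key=value` text format; `read_config(write_config(cfg, f))`
#' reproduces the configuration.
#'
#' @param config a [pipeline_config()].
#' @param path file path.
#' @return `write_config`: `path` invisibly; `read_config`: a
#'   [pipeline_config()].
#' @export
write_config <- function(config, path) {
  kv <- config_to_keyvals(config)
  writeLines(paste0(names(kv), "=", vapply(kv, format, character(1))), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln)) & !startsWith(trimws(ln), "#")]
  kv <- strsplit(ln, "=", fixed = TRUE)
  vals <- stats::setNames(trimws(vapply(kv, `[`, character(1), 2)),
                          trimws(vapply(kv, `[`, character(1), 1)))
  num <- function(key, default) if (key %in% names(vals)) as.numeric(vals[[key]]) else default
  auto <- function(key) if (!key %in% names(vals) || vals[[key]] == "auto") NULL
    else as.numeric(vals[[key]])
  pipeline_config(
    calibration = calibration_spec(
      pixel_spacing_mm = num("pixel_spacing_mm", 0.01),
      catheter_gauge_french = num("catheter_gauge_french", 2.7),
      catheter_diameter_mm = num("catheter_diameter_mm", NULL)),
    preprocess = preprocess_params(
      median_window = num("median_window", 5),
      gaussian_sigma_bins = num("gaussian_sigma_bins", 2),
      threshold_method = if ("threshold_method" %in% names(vals))
        vals[["threshold_method"]] else "otsu"),
    morphology = morphology_params(num("disk_radius_bins", 5)),
    savgol = savgol_coefficients(num("savgol_window", 35), num("savgol_order", 2)),
    n_angles = num("n_angles", 360),
    n_radii = auto("n_radii"),
    bifurcation_cutoff_mm = num("bifurcation_cutoff_mm", 2),
    catheter_margin_mm = num("catheter_margin_mm", 0.05),
    min_component_area = auto("min_component_area"))
}

#' Segment a single frame
#'
#' Runs the full stage sequence on one frame: polar transform, catheter
#' removal, despeckling, automatic thresholding, opening/closing, small-object
#' removal, component tracing, gap bridging, Sobel border extraction,
#' Savitzky-Golay smoothing, back-transformation and quantification.
#'
#' @param frame an [oct_frame()].
#' @param config a [pipeline_config()].
#' @param keep_intermediate keep per-stage images in the result (for
#'   inspection/debug dumps).
#' @return list with `contour` (smoothed [polar_contour()]), `contour_xy`
#'   (data.frame in mm), `metrics` ([lumen_metrics()]), `bridges`
#'   (data.frame), `log` (per-stage wall times), and optionally
#'   `intermediate`.
#' @export
segment_frame <- function(frame, config = pipeline_config(),
                          keep_intermediate = FALSE) {
  stopifnot(inherits(frame, "oct_frame"), inherits(config, "pipeline_config"))
  cal <- calibration_spec(
    pixel_spacing_mm = frame$calibration$pixel_spacing_mm,
    catheter_gauge_french = config$calibration$catheter_gauge_french,
    catheter_diameter_mm = config$calibration$catheter_diameter_mm)
  log <- list(); intermediate <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    out <- tryCatch(expr, error = function(e)
      stop_octlumen(sprintf("stage '%s': %s", name, conditionMessage(e)),
                    "octlumen_stage_error"))
    log[[name]] <<- proc.time()[3] - t0
    if (keep_intermediate) intermediate[[name]] <<- out
    out
  }
  polar <- stage("to_polar", to_polar(frame, config$n_angles, config$n_radii))
  polar <- stage("remove_catheter",
                 remove_catheter(polar, cal, margin_mm = config$catheter_margin_mm))
  polar <- stage("denoise", denoise(polar, config$preprocess))
  binary <- stage("binarize", binarize(polar, config$preprocess))
  binary <- stage("open_close", open_close(binary, config$morphology))
  min_area <- config$min_component_area %||%
    sum(disk_kernel(config$morphology$disk_radius_bins))
  binary <- stage("discard_small", discard_small_components(binary, min_area))
  comps <- stage("trace_components", trace_components(binary))
  bridged <- stage("bridge_gaps",
                   bridge_gaps(comps, binary, cal, config$bifurcation_cutoff_mm))
  border <- stage("extract_border", extract_border(bridged$binary))
  smoothed <- stage("smooth_contour", smooth_contour(border, config$savgol))
  xy <- stage("contour_to_cartesian", contour_to_cartesian(smoothed, frame))
  metrics <- stage("lumen_metrics", lumen_metrics(xy, check = FALSE))
  out <- list(contour = smoothed, contour_xy = xy, metrics = metrics,
              bridges = bridged$bridges, log = unlist(log))
  if (keep_intermediate) out$intermediate <- intermediate
  out
}

#' Segment a whole pullback
#'
#' Applies [segment_frame()] to every frame of a pullback in order. No frame
#' is skipped: per-frame failures are caught, logged with their failing stage,
#' and recorded as missing metric rows rather than aborting the run. The
#' pipeline has no unseeded randomness, so repeated runs are identical.
#'
#' @param input a path accepted by [read_pullback()] or a list of
#'   [oct_frame()] objects.
#' @param config a [pipeline_config()].
#' @param output_dir optional directory; when given, writes `metrics.csv`,
#'   `contours.csv`, `bridges.csv` and `run_log.txt`.
#' @return object of class `pullback_result`: list with `metrics`
#'   (data.frame: `frame_index`, `area_mm2`, `mean_diameter_mm`,
#'   `min_diameter_mm`, `max_diameter_mm`), `contours` (list of data.frames,
#'   `NULL` where failed), `bridges`, `failures` (data.frame), `log`
#'   (character vector, one line per stage per frame).
#' @export
segment_pullback <- function(input, config = pipeline_config(), output_dir = NULL) {
  frames <- if (is.character(input)) read_pullback(input, config$calibration)
  else input
  stopifnot(length(frames) >= 1L, all(vapply(frames, inherits, TRUE, "oct_frame")))
  metrics <- data.frame(frame_index = vapply(frames, `[[`, 0L, "frame_index"),
                        area_mm2 = NA_real_, mean_diameter_mm = NA_real_,
                        min_diameter_mm = NA_real_, max_diameter_mm = NA_real_)
  contours <- vector("list", length(frames))
  bridges <- list(); failures <- list(); log <- character()
  for (i in seq_along(frames)) {
    fi <- metrics$frame_index[i]
    res <- tryCatch(segment_frame(frames[[i]], config), error = function(e) e)
    if (inherits(res, "error")) {
      msg <- conditionMessage(res)
      failures[[length(failures) + 1L]] <- data.frame(frame_index = fi, reason = msg)
      log <- c(log, sprintf("frame %d FAILED: %s", fi, msg))
      next
    }
    metrics[i, -1] <- as.data.frame(res$metrics)
    contours[[i]] <- res$contour_xy
    if (nrow(res$bridges))
      bridges[[length(bridges) + 1L]] <- cbind(frame_index = fi, res$bridges)
    log <- c(log, sprintf("frame %d %s", fi,
                          paste(sprintf("%s=%.3fs", names(res$log), res$log),
                                collapse = " ")))
  }
  out <- structure(list(
    metrics = metrics,
    contours = contours,
    bridges = if (length(bridges)) do.call(rbind, bridges) else NULL,
    failures = if (length(failures)) do.call(rbind, failures)
    else data.frame(frame_index = integer(), reason = character()),
    log = log), class = "pullback_result")
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(out$metrics, file.path(output_dir, "metrics.csv"), row.names = FALSE)
    ok <- !vapply(contours, is.null, TRUE)
    if (any(ok))
      export_contours(contours[ok], file.path(output_dir, "contours.csv"))
    if (!is.null(out$bridges))
      write.csv(out$bridges, file.path(output_dir, "bridges.csv"), row.names = FALSE)
    writeLines(out$log, file.path(output_dir, "run_log.txt"))
  }
  out
}

#' @export
print.pullback_result <- function(x, ...) {
  cat(sprintf("pullback: %d frames, %d failed\n",
              nrow(x$metrics), nrow(x$failures)))
  print(head(x$metrics))
  invisible(x)
}

LUMEN_PARAMETERS <- c("area_mm2", "mean_diameter_mm",
                      "min_diameter_mm", "max_diameter_mm")

#' Compare two per-frame metric tables
#'
#' Computes the full agreement report (difference, RD, ARD, ICC with CI,
#' Bland-Altman limits) for each lumen parameter between two methods' metric
#' tables, aligned on `frame_index`.
#'
#' @param metrics_a,metrics_b CSV paths or data.frames with columns
#'   `frame_index` and the four lumen parameters. Method A is the
#'   first-listed method in all signed statistics.
#' @param output optional path prefix; writes `<output>.csv` and
#'   `<output>.json`.
#' @return named list of [agreement_report()] objects, one per parameter.
#' @export
compare_methods <- function(metrics_a, metrics_b, output = NULL) {
  a <- if (is.character(metrics_a)) read.csv(metrics_a) else metrics_a
  b <- if (is.character(metrics_b)) read.csv(metrics_b) else metrics_b
  for (tab in list(a, b))
    if (!all(c("frame_index", LUMEN_PARAMETERS) %in% names(tab)))
      stop_octlumen("metric tables need frame_index and the four lumen parameters",
                    "octlumen_parameter_error")
  only_a <- setdiff(a$frame_index, b$frame_index)
  only_b <- setdiff(b$frame_index, a$frame_index)
  if (length(only_a) || length(only_b))
    stop_octlumen(sprintf(
      "frame indices do not align (only in A: %s; only in B: %s)",
      paste(only_a, collapse = ","), paste(only_b, collapse = ",")),
      "octlumen_join_error")
  a <- a[order(a$frame_index), ]; b <- b[order(b$frame_index), ]
  keep <- stats::complete.cases(a[, LUMEN_PARAMETERS]) &
    stats::complete.cases(b[, LUMEN_PARAMETERS])
  reports <- lapply(LUMEN_PARAMETERS, function(p)
    agreement_report(a[[p]][keep], b[[p]][keep], parameter = p))
  names(reports) <- LUMEN_PARAMETERS
  if (!is.null(output)) {
    tab <- do.call(rbind, lapply(reports, as.data.frame))
    write.csv(tab, paste0(output, ".csv"), row.names = FALSE)
    jsonlite::write_json(lapply(reports, unclass), paste0(output, ".json"),
                         digits = NA, auto_unbox = TRUE)
  }
  reports
}

#' Reported per-method mean lumen measurements
#'
#' Mean lumen area and diameters reported by a 667-frame clinical comparison
#' of four analysis methods (this automated approach, two commercial analysis
#' systems, and expert manual contouring as ground truth). Shipped as
#' reference data for worked agreement-arithmetic examples.
#'
#' @return data.frame with columns `parameter`, `our_method`, `system1`,
#'   `system2`, `ground_truth`.
#' @export
reported_method_means <- function() {
  read.csv(system.file("extdata", "reported_method_means.csv",
                       package = "octlumen"), stringsAsFactors = FALSE)
}
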