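#' Morphology parameters
#'
#' @param disk_radius_bins radius R of the flat disk structuring element in
#'   bins (default 5). The disk preserves the circular character of the
#'   vessel wall while removing residual-blood clusters.
#' @return an object of class `morphology_params`.
#' @export
morphology_params <- function(disk_radius_bins = 5L) {
  disk_radius_bins <- as.integer(disk_radius_bins)
  if (disk_radius_bins < 1L)
    stop_octlumen("disk_radius_bins must be >= 1", "octlumen_parameter_error")
  structure(list(disk_radius_bins = disk_radius_bins), class = "morphology_params")
}

#' Morphological opening then closing
#'
#' Cleans the binarized polar image with a flat disk of radius R: opening
#' (erosion then dilation) removes foreground islands that cannot contain a
#' translate of the disk, closing (dilation then erosion) fills background
#' holes smaller than the disk. At the image border the structuring
#' neighborhood is clipped to the image domain. The composition is
#' idempotent.
#'
#' @param binary logical (or 0/1 numeric) matrix.
#' @param params a [morphology_params()].
#' @return logical matrix of the same size.
#' @export
open_close <- function(binary, params = morphology_params()) {
  stopifnot(is.matrix(binary), inherits(params, "morphology_params"))
  b <- matrix(as.numeric(binary), nrow(binary), ncol(binary))
  k <- disk_kernel(params$disk_radius_bins)
  b <- EBImage::closing(EBImage::opening(b, k), k)
  b > 0.5
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so labels that touch
# diagonally are merged by union-find
label_components8 <- function(binary) {
  lab <- EBImage::bwlabel(matrix(as.numeric(binary), nrow(binary), ncol(binary)))
  nl <- max(lab)
  if (nl == 0L) return(lab)
  parent <- seq_len(nl)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  unite <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  n <- nrow(lab); m <- ncol(lab)
  diag_pairs <- function(a, b) {
    sel <- a > 0 & b > 0 & a != b
    unique(cbind(a[sel], b[sel]))
  }
  prs <- rbind(diag_pairs(lab[-n, -m], lab[-1, -1]),
               diag_pairs(lab[-n, -1], lab[-1, -m]))
  if (nrow(prs)) for (q in seq_len(nrow(prs))) unite(prs[q, 1], prs[q, 2])
  root <- vapply(seq_len(nl), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

# Moore-neighbor boundary tracing of one component (closed 8-connected chain);
# mask must contain exactly the component's pixels. Terminates when the
# (pixel, backtrack) state returns to its initial value.
moore_trace <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  px <- which(mask, arr.ind = TRUE)
  start <- as.integer(px[order(px[, 1], px[, 2])[1], ])  # topmost, then leftmost
  # clockwise neighbor ring starting west
  ring <- rbind(c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1),
                c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  fg <- function(q) q[1] >= 1 && q[1] <= nr && q[2] >= 1 && q[2] <= nc &&
    mask[q[1], q[2]]
  prev0 <- start + c(0L, -1L)                         # west of start: background
  p <- start; prev <- prev0
  out <- matrix(start, ncol = 2)
  max_iter <- 4L * nrow(px) + 8L
  for (iter in seq_len(max_iter)) {
    dd <- prev - p
    b <- which(ring[, 1] == dd[1] & ring[, 2] == dd[2])
    nxt <- NULL
    for (s in 1:8) {
      d <- ((b - 1L + s) %% 8L) + 1L
      q <- p + ring[d, ]
      if (fg(q)) { nxt <- q; break }
    }
    if (is.null(nxt)) return(out)                     # isolated pixel
    # last background examined before nxt (the backtrack of the next step)
    prev_new <- p + ring[((b - 1L + s - 1L) %% 8L) + 1L, ]
    if (all(nxt == start) && all(prev_new == prev0)) break
    out <- rbind(out, nxt, deparse.level = 0)
    p <- nxt; prev <- prev_new
  }
  dimnames(out) <- NULL
  out
}

# the 8 extreme points of a pixel set, Fig.-style convention:
# ties broken toward the named corner
component_extrema <- function(bpx) {
  r <- unname(bpx[, 1]); c <- unname(bpx[, 2])
  pick <- function(primary, p_fun, secondary, s_fun) {
    sel <- which(primary == p_fun(primary))
    sel[which(secondary[sel] == s_fun(secondary[sel]))[1]]
  }
  idx <- c(top_left     = pick(r, min, c, min),
           top_right    = pick(r, min, c, max),
           right_top    = pick(c, max, r, min),
           right_bottom = pick(c, max, r, max),
           bottom_right = pick(r, max, c, max),
           bottom_left  = pick(r, max, c, min),
           left_bottom  = pick(c, min, r, max),
           left_top     = pick(c, min, r, min))
  m <- bpx[idx, , drop = FALSE]
  dimnames(m) <- list(names(idx), c("row", "col"))
  m
}

#' Trace connected components and their extreme points
#'
#' Labels the 8-connected foreground components of a binary polar image,
#' traces each exterior boundary as a closed 8-connected pixel chain
#' (Moore-neighbor tracing), and records the 8 boundary extreme points
#' (top-left, top-right, right-top, right-bottom, bottom-right, bottom-left,
#' left-bottom, left-top; ties broken toward the named corner). Components
#' are returned top to bottom by their minimal angle row.
#'
#' @param binary logical matrix (rows = angles).
#' @return list of `component_extrema` objects, each with fields
#'   `component_id`, `extrema` (8 x 2 matrix), `boundary` (ordered closed
#'   chain, first row adjacent to last), `pixel_count`, `row_range`.
#' @export
trace_components <- function(binary) {
  stopifnot(is.matrix(binary))
  binary <- binary > 0
  if (!any(binary))
    stop_octlumen("no foreground: nothing resembling tissue in the frame",
                  "octlumen_no_tissue_error")
  lab <- label_components8(binary)
  ids <- seq_len(max(lab))
  comps <- lapply(ids, function(id) {
    mask <- lab == id
    bnd <- moore_trace(mask)
    structure(list(component_id = id,
                   extrema = component_extrema(bnd),
                   boundary = bnd,
                   pixel_count = sum(mask),
                   row_range = range(which(rowSums(mask) > 0))),
              class = "component_extrema")
  })
  comps[order(vapply(comps, function(co) co$row_range[1], numeric(1)))]
}

#' Drop components smaller than a pixel-count floor
#'
#' Residual blood occasionally survives opening/closing near the image edges;
#' components smaller than the structuring-disk area are removed before gap
#' bridging.
#'
#' @param binary logical matrix.
#' @param min_area minimum component pixel count to keep; default is the area
#'   of the radius-5 disk.
#' @return logical matrix.
#' @export
discard_small_components <- function(binary, min_area = sum(disk_kernel(5))) {
  if (!any(binary)) return(binary > 0)
  lab <- label_components8(binary > 0)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area)
  out <- matrix(lab %in% keep, nrow(binary), ncol(binary))
  out
}

# polar pixel (row = angle bin, col = radius bin, both 1-based) -> Cartesian mm
polar_px_to_mm <- function(p, n_angles, spacing) {
  theta <- 2 * pi * (p[1] - 1) / n_angles
  rad <- (p[2] - 1) * spacing
  c(rad * cos(theta), rad * sin(theta))
}

#' Bridge guide-wire and bifurcation gaps
#'
#' Connects consecutive components (top to bottom in angle, cyclically across
#' the angular wrap-around) by straight foreground segments. For each gap the
#' upper component contributes its bottom-left extreme point and the lower
#' component its top-left or top-right point, whichever lies closer in
#' Euclidean distance measured in Cartesian mm. Endpoints are refined to the
#' first (innermost) white pixel of their angle row, then joined by a linearly
#' interpolated pixel line. Gaps longer than `bifurcation_cutoff_mm` are
#' flagged as bifurcations; both kinds are bridged.
#'
#' @param components list from [trace_components()].
#' @param binary the logical matrix the components were traced from.
#' @param calibration a [calibration_spec()] (supplies the radial bin size).
#' @param bifurcation_cutoff_mm gap length separating guide-wire gaps from
#'   bifurcations (default 2 mm).
#' @return list with `binary` (bridged matrix; foreground is only ever added)
#'   and `bridges` (data.frame: one row per bridged gap with the refined
#'   endpoints, `gap_length_mm` and `is_bifurcation`).
#' @export
bridge_gaps <- function(components, binary, calibration = calibration_spec(),
                        bifurcation_cutoff_mm = 2) {
  stopifnot(length(components) >= 1L, is.matrix(binary))
  binary <- binary > 0
  n_ang <- nrow(binary)
  sp <- calibration$pixel_spacing_mm
  empty <- data.frame(upper_row = integer(), upper_col = integer(),
                      lower_row = integer(), lower_col = integer(),
                      gap_length_mm = numeric(), is_bifurcation = logical())
  covered <- rowSums(binary) > 0
  if (length(components) == 1L && all(covered))
    return(list(binary = binary, bridges = empty))

  n_comp <- length(components)
  bridges <- empty
  for (i in seq_len(n_comp)) {
    upper <- components[[i]]
    lower <- components[[if (i == n_comp) 1L else i + 1L]]
    up <- upper$extrema["bottom_left", ]
    cand <- lower$extrema[c("top_left", "top_right"), , drop = FALSE]
    up_mm <- polar_px_to_mm(up, n_ang, sp)
    d_mm <- apply(cand, 1, function(q) sqrt(sum((polar_px_to_mm(q, n_ang, sp) - up_mm)^2)))
    lo <- cand[which.min(d_mm), ]
    # refine endpoints: first white pixel of the endpoint's angle row
    up[2] <- min(which(binary[up[1], ]))
    lo[2] <- min(which(binary[lo[1], ]))
    gap_mm <- sqrt(sum((polar_px_to_mm(lo, n_ang, sp) -
                          polar_px_to_mm(up, n_ang, sp))^2))
    # draw the segment in unwrapped row coordinates (cyclic angle axis)
    dr <- (lo[1] - up[1]) %% n_ang
    pts <- rasterize_segment(c(up[1], up[2]), c(up[1] + dr, lo[2]))
    pts[, 1] <- ((pts[, 1] - 1) %% n_ang) + 1
    binary[pts] <- TRUE
    bridges <- rbind(bridges, data.frame(
      upper_row = up[1], upper_col = up[2],
      lower_row = lo[1], lower_col = lo[2],
      gap_length_mm = gap_mm,
      is_bifurcation = gap_mm > bifurcation_cutoff_mm))
  }
  list(binary = binary, bridges = bridges)
}

sobel_x <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)  # gradient across cols

#' Extract the per-angle lumen border
#'
#' Applies the Sobel gradient-magnitude operator to the bridged binary image
#' and takes, for every angle row, the innermost (smallest-radius) edge
#' position on the foreground side: the lumen border is by definition the
#' inner boundary of the intima. Foreground added at radii beyond the existing
#' wall does not move the border.
#'
#' @param binary logical matrix; every row must contain foreground.
#' @return a [polar_contour()] with all angles valid (radii are 0-based bins).
#' @export
extract_border <- function(binary) {
  stopifnot(is.matrix(binary))
  b <- matrix(as.numeric(binary > 0), nrow(binary), ncol(binary))
  if (any(rowSums(b) == 0))
    stop_octlumen("some angle rows have no foreground; gap bridging incomplete",
                  "octlumen_incomplete_segmentation_error")
  gx <- EBImage::filter2(b, sobel_x, boundary = "replicate")
  gy <- EBImage::filter2(b, t(sobel_x), boundary = "replicate")
  mag <- sqrt(gx^2 + gy^2)
  edge <- mag > 0.5 & b > 0.5
  radius <- vapply(seq_len(nrow(b)), function(a) {
    cols <- which(edge[a, ])
    if (length(cols) == 0L) cols <- which(b[a, ] > 0.5)   # uniform row fallback
    min(cols) - 1
  }, numeric(1))
  polar_contour(radius, n_radii = ncol(b))
}
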