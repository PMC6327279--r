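#' Lumen area and diameters of a closed contour
#'
#' Area is computed by the shoelace polygon formula. Diameters are chord
#' lengths through the contour centroid: for each of `n_rays` equally spaced
#' directions the chord is the sum of the border distances along the ray and
#' its opposite; the mean, minimum and maximum over directions summarize the
#' lumen caliber. For a circle all three diameters equal `2*sqrt(area/pi)` up
#' to discretization.
#'
#' @param contour closed contour: a data.frame with `x_mm`, `y_mm` columns
#'   (as from [contour_to_cartesian()]) or a 2-column matrix, >= 8 points,
#'   non-self-intersecting, first point adjacent to last.
#' @param n_rays number of chord directions (default 180).
#' @param check check for self-intersection (default TRUE).
#' @return an object of class `lumen_metrics`: list with `area_mm2`,
#'   `mean_diameter_mm`, `min_diameter_mm`, `max_diameter_mm`.
#' @examples
#' th <- 2 * pi * (0:359) / 360
#' circ <- cbind(1.5 * cos(th), 1.5 * sin(th))
#' lumen_metrics(circ)  # area ~ pi * 1.5^2, diameters ~ 3 mm
#' @export
lumen_metrics <- function(contour, n_rays = 180L, check = TRUE) {
  xy <- as.matrix(if (is.data.frame(contour)) contour[, c("x_mm", "y_mm")] else contour)
  storage.mode(xy) <- "double"
  m <- nrow(xy)
  if (m < 8L)
    stop_octlumen("contour needs at least 8 points", "octlumen_geometry_error")
  if (check && polygon_self_intersects(xy))
    stop_octlumen("contour is self-intersecting", "octlumen_geometry_error")
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cross <- x * yn - xn * y
  area <- sum(cross) / 2
  cx <- sum((x + xn) * cross) / (6 * area)
  cy <- sum((y + yn) * cross) / (6 * area)
  area <- abs(area)
  if (area <= 0)
    stop_octlumen("contour encloses no area", "octlumen_geometry_error")
  phi <- pi * (seq_len(n_rays) - 1) / n_rays
  chords <- vapply(phi, function(a) {
    ray_distance(xy, c(cx, cy), a) + ray_distance(xy, c(cx, cy), a + pi)
  }, numeric(1))
  structure(list(area_mm2 = area,
                 mean_diameter_mm = mean(chords),
                 min_diameter_mm = min(chords),
                 max_diameter_mm = max(chords),
                 centroid_mm = c(cx, cy)),
            class = "lumen_metrics")
}

#' @export
print.lumen_metrics <- function(x, ...) {
  cat(sprintf("lumen: area %.3f mm^2, diameter %.3f mm (min %.3f, max %.3f)\n",
              x$area_mm2, x$mean_diameter_mm, x$min_diameter_mm, x$max_diameter_mm))
  invisible(x)
}

#' @export
as.data.frame.lumen_metrics <- function(x, ...) {
  data.frame(area_mm2 = x$area_mm2, mean_diameter_mm = x$mean_diameter_mm,
             min_diameter_mm = x$min_diameter_mm, max_diameter_mm = x$max_diameter_mm)
}

# distance from origin `o` to the polygon boundary along direction `angle`;
# farthest crossing (polygons here are star-shaped about the centroid, so the
# crossing is unique up to discretization)
ray_distance <- function(xy, o, angle) {
  u <- c(cos(angle), sin(angle))
  a <- sweep(xy, 2, o)                      # edge starts
  b <- rbind(a[-1, , drop = FALSE], a[1, , drop = FALSE])
  e <- b - a
  den <- u[1] * e[, 2] - u[2] * e[, 1]      # cross(u, e)
  ok <- abs(den) > 1e-14
  t <- (a[, 1] * e[, 2] - a[, 2] * e[, 1]) / den   # cross(a, e) / cross(u, e)
  s <- (a[, 1] * u[2] - a[, 2] * u[1]) / den       # position along the edge
  hit <- ok & t > 0 & s >= -1e-12 & s < 1 + 1e-12
  if (!any(hit))
    stop_octlumen("centroid ray misses the contour", "octlumen_geometry_error")
  max(t[hit])
}

# O(n^2) vectorized proper-crossing test between non-adjacent edges
polygon_self_intersects <- function(xy) {
  m <- nrow(xy)
  a <- xy; b <- rbind(xy[-1, , drop = FALSE], xy[1, , drop = FALSE])
  idx <- which(outer(seq_len(m), seq_len(m), function(i, j)
    j > i + 1 & !(i == 1 & j == m)), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  d1 <- b[i, ] - a[i, ]; d2 <- b[j, ] - a[j, ]
  den <- d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1]
  w <- a[j, ] - a[i, ]
  t <- (w[, 1] * d2[, 2] - w[, 2] * d2[, 1]) / den
  s <- (w[, 1] * d1[, 2] - w[, 2] * d1[, 1]) / den
  any(abs(den) > 1e-14 & t > 1e-12 & t < 1 - 1e-12 & s > 1e-12 & s < 1 - 1e-12)
}

check_series_pair <- function(first, second, positive = TRUE) {
  stopifnot(is.numeric(first), is.numeric(second))
  if (length(first) != length(second))
    stop_octlumen("paired series must have equal length", "octlumen_domain_error")
  if (positive && (any(first <= 0) || any(second <= 0)))
    stop_octlumen("relative differences need strictly positive measurements",
                  "octlumen_domain_error")
}

#' Relative difference between two measurement series (%)
#'
#' `RD = 100/N * sum((I_i - O_i) / max(O_i, I_i))` with `O` the first and `I`
#' the second series: each per-frame difference is normalized by the larger of
#' the two measurements. Antisymmetric under swapping the series.
#'
#' @param first,second numeric vectors of paired per-frame measurements,
#'   strictly positive.
#' @return the relative difference in percent.
#' @examples
#' relative_difference(c(2, 4), c(1, 5))  # -15
#' @export
relative_difference <- function(first, second) {
  check_series_pair(first, second)
  mean((second - first) / pmax(first, second)) * 100
}

#' Absolute relative difference between two measurement series (%)
#'
#' `ARD = 100/N * sum(|I_i - O_i| / max(O_i, I_i))`; the symmetric,
#' magnitude-only counterpart of [relative_difference()].
#'
#' @inheritParams relative_difference
#' @return the absolute relative difference in percent.
#' @examples
#' absolute_relative_difference(c(2, 4), c(1, 5))  # 35
#' @export
absolute_relative_difference <- function(first, second) {
  check_series_pair(first, second)
  mean(abs(second - first) / pmax(first, second)) * 100
}

#' Intraclass correlation ICC(2,1) for two-method agreement
#'
#' Two-way random-effects, absolute-agreement, single-measure intraclass
#' correlation computed from the two-way ANOVA mean squares (subjects x
#' methods), with the F-based 95% confidence interval and the F test against
#' ICC = 0.
#'
#' @param first,second numeric vectors of paired measurements (N >= 3,
#'   non-constant).
#' @param conf_level confidence level for the interval (default 0.95).
#' @return list with `icc`, `ci` (length-2 vector), `p_value`, `n`.
#' @export
icc <- function(first, second, conf_level = 0.95) {
  check_series_pair(first, second, positive = FALSE)
  n <- length(first)
  if (n < 3L)
    stop_octlumen("ICC needs at least 3 paired frames", "octlumen_domain_error")
  if (sd(first) == 0 || sd(second) == 0)
    stop_octlumen("both series are constant; variance decomposition degenerate",
                  "octlumen_degenerate_variance_error")
  k <- 2L
  y <- cbind(first, second)
  grand <- mean(y)
  row_m <- rowMeans(y); col_m <- colMeans(y)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_err <- sum((y - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + grand)^2)
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  val <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  # McGraw & Wong F-based interval for ICC(A,1); degenerate when agreement
  # is numerically perfect (MSE = 0)
  if (abs(1 - val) < 1e-12) {
    f0 <- msr / max(mse, .Machine$double.xmin)
    return(list(icc = val, ci = c(val, val),
                p_value = pf(f0, n - 1, (n - 1) * (k - 1), lower.tail = FALSE),
                n = n))
  }
  alpha <- 1 - conf_level
  a <- k * val / (n * (1 - val))
  b <- 1 + k * val * (n - 1) / (n * (1 - val))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- qf(1 - alpha / 2, n - 1, v)
  f_u <- qf(1 - alpha / 2, v, n - 1)
  lwr <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upr <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  f0 <- msr / mse
  p <- pf(f0, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  list(icc = val, ci = c(lwr, upr), p_value = p, n = n)
}

#' Bland-Altman analysis
#'
#' Per-pair differences `d_i = first_i - second_i`, their mean, and the
#' limits of agreement `mean(d) +/- 1.96 * sd(d)` (sample standard deviation).
#' The per-pair x-axis values for the plot are the pair means.
#'
#' @param first,second numeric vectors of paired measurements (N >= 2).
#' @return list with `mean_difference`, `loa_low`, `loa_high`, `sd_difference`
#'   and `pairs` (data.frame with `mean` and `difference` per pair).
#' @export
bland_altman <- function(first, second) {
  check_series_pair(first, second, positive = FALSE)
  if (length(first) < 2L)
    stop_octlumen("Bland-Altman needs at least 2 pairs", "octlumen_domain_error")
  d <- first - second
  md <- mean(d); s <- sd(d)
  list(mean_difference = md,
       sd_difference = s,
       loa_low = md - 1.96 * s,
       loa_high = md + 1.96 * s,
       pairs = data.frame(mean = (first + second) / 2, difference = d))
}

#' Full agreement report for one parameter
#'
#' Bundles the paired-series comparison of one lumen parameter between two
#' methods: mean difference (first minus second), relative and absolute
#' relative differences, ICC(2,1) with confidence interval, and Bland-Altman
#' limits of agreement.
#'
#' @inheritParams icc
#' @param parameter optional parameter name carried in the report.
#' @return an object of class `agreement_report`.
#' @export
agreement_report <- function(first, second, parameter = NA_character_,
                             conf_level = 0.95) {
  ic <- icc(first, second, conf_level)
  ba <- bland_altman(first, second)
  structure(list(parameter = parameter,
                 n = length(first),
                 mean_difference = ba$mean_difference,
                 rd_percent = relative_difference(first, second),
                 ard_percent = absolute_relative_difference(first, second),
                 icc = ic$icc, icc_ci = ic$ci, icc_p_value = ic$p_value,
                 loa_low = ba$loa_low, loa_high = ba$loa_high,
                 pairs = ba$pairs),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("agreement%s (N = %d):\n",
              if (is.na(x$parameter)) "" else paste0(" for ", x$parameter), x$n))
  cat(sprintf("  difference %.4g  RD %.4g%%  ARD %.4g%%\n",
              x$mean_difference, x$rd_percent, x$ard_percent))
  cat(sprintf("  ICC %.3f (%.3f-%.3f), p = %.3g\n",
              x$icc, x$icc_ci[1], x$icc_ci[2], x$icc_p_value))
  cat(sprintf("  limits of agreement [%.4g, %.4g]\n", x$loa_low, x$loa_high))
  invisible(x)
}

#' @export
as.data.frame.agreement_report <- function(x, ...) {
  data.frame(parameter = x$parameter, n = x$n,
             mean_difference = x$mean_difference,
             rd_percent = x$rd_percent, ard_percent = x$ard_percent,
             icc = x$icc, icc_ci_low = x$icc_ci[1], icc_ci_high = x$icc_ci[2],
             icc_p_value = x$icc_p_value,
             loa_low = x$loa_low, loa_high = x$loa_high)
}
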