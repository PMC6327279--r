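make_frame <- function(n, f, spacing = 0.01) {
  ctr <- (n + 1) / 2
  col_i <- matrix(rep(seq_len(n), each = n), n, n)
  row_i <- matrix(rep(seq_len(n), times = n), n, n)
  dx <- col_i - ctr; dy <- row_i - ctr
  v <- matrix(f(sqrt(dx^2 + dy^2), atan2(dy, dx) %% (2 * pi)), n, n)
  oct_frame(pmin(pmax(v, 0), 1),
            calibration = calibration_spec(pixel_spacing_mm = spacing))
}

test_that("circles map to constant-radius bands and uniforms stay uniform", {
  fr <- make_frame(128, function(r, th) as.numeric(abs(r - 40) <= 1.5))
  p <- to_polar(fr, n_angles = 90)
  expect_true(all(p$values[, 41] > 0.8))        # column 41 = radius 40 bins
  expect_true(all(p$values[, c(20, 60)] < 0.1))
  expect_equal(p$radial_spacing_mm, 0.01)

  fu <- oct_frame(matrix(0.37, 64, 64))
  pu <- to_polar(fu, n_angles = 45)
  expect_equal(max(abs(pu$values - 0.37)), 0, tolerance = 1e-12)
})

test_that("half-plane brightness lands on the matching angle rows", {
  n <- 128; ctr <- (n + 1) / 2
  v <- matrix(0, n, n)
  v[, seq_len(n) > ctr] <- 1                     # bright where x > 0
  fr <- oct_frame(v)
  p <- to_polar(fr, n_angles = 360)
  theta <- 2 * pi * (0:359) / 360
  at_r30 <- p$values[, 31]
  expect_true(all(at_r30[cos(theta) > 0.2] > 0.9))
  expect_true(all(at_r30[cos(theta) < -0.2] < 0.1))
})

test_that("n_radii beyond the in-image radius is a geometry error", {
  fr <- oct_frame(matrix(0.5, 64, 64))
  expect_error(to_polar(fr, n_radii = 64), class = "octlumen_geometry_error")
})

test_that("contour back-transformation reproduces analytic shapes", {
  fr <- oct_frame(matrix(0.5, 512, 512))
  # constant radius 100 bins at 0.01 mm/bin -> 1.0 mm circle about the center
  ct <- polar_contour(rep(100, 360), n_radii = 200)
  xy <- contour_to_cartesian(ct, fr)
  ctr_mm <- fr$center * 0.01
  rad <- sqrt((xy$x_mm - ctr_mm[2])^2 + (xy$y_mm - ctr_mm[1])^2)
  expect_equal(max(abs(rad - 1.0)), 0, tolerance = 1e-9)

  # four angles, radius 1 bin, 1 mm spacing -> the unit-axis points
  fr4 <- oct_frame(matrix(0.5, 8, 8),
                   calibration = calibration_spec(pixel_spacing_mm = 1))
  xy4 <- contour_to_cartesian(polar_contour(rep(1, 4), n_radii = 3), fr4)
  rel <- cbind(xy4$x_mm - 4.5, xy4$y_mm - 4.5)
  expect_equal(rel, cbind(c(1, 0, -1, 0), c(0, 1, 0, -1)), tolerance = 1e-12,
               ignore_attr = TRUE)

  # analytic ellipse in polar form is recovered on the ellipse
  a <- 2.0; b <- 1.0
  theta <- 2 * pi * (0:359) / 360
  r_mm <- a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
  cte <- polar_contour(r_mm / 0.01, n_radii = 250)
  xye <- contour_to_cartesian(cte, fr)
  resid <- ((xye$x_mm - ctr_mm[2]) / a)^2 + ((xye$y_mm - ctr_mm[1]) / b)^2 - 1
  expect_equal(max(abs(resid)), 0, tolerance = 1e-6)

  # gaps must be filled before back-transforming
  ct_bad <- polar_contour(rep(10, 16), valid_mask = c(rep(TRUE, 15), FALSE))
  expect_error(contour_to_cartesian(ct_bad, fr),
               class = "octlumen_incomplete_contour_error")
})

test_that("rotating the scene by whole angle bins shifts polar rows", {
  n_ang <- 90
  pattern <- function(shift) make_frame(128, function(r, th)
    0.4 + 0.3 * sin(3 * (th - shift)) * exp(-((r - 35) / 12)^2))
  p0 <- to_polar(pattern(0), n_angles = n_ang)
  k <- 7
  pk <- to_polar(pattern(k * 2 * pi / n_ang), n_angles = n_ang)
  shifted <- p0$values[c((n_ang - k + 1):n_ang, 1:(n_ang - k)), ]
  # interior radii only: bilinear grids of the two renderings differ slightly
  expect_equal(pk$values[, 5:55], shifted[, 5:55], tolerance = 2e-3)
})

test_that("a known radial border survives the polar round trip within a bin", {
  rho_bins <- function(th) 40 + 6 * sin(2 * th)
  fr <- make_frame(160, function(r, th) as.numeric(r >= rho_bins(th)))
  p <- to_polar(fr, n_angles = 120)
  border <- apply(p$values, 1, function(row) {
    j <- min(which(row >= 0.5))
    t <- (0.5 - row[j - 1]) / (row[j] - row[j - 1])   # subpixel crossing
    (j - 2) + t
  })
  theta <- 2 * pi * (0:119) / 120
  expect_true(all(abs(border - rho_bins(theta)) <= 1))
})

test_that("contour export writes flat CSV in mm", {
  fr <- oct_frame(matrix(0.5, 64, 64))
  xy <- contour_to_cartesian(polar_contour(rep(10, 12), n_radii = 30), fr)
  f <- tempfile(fileext = ".csv")
  export_contours(list(xy), f)
  back <- read.csv(f)
  expect_equal(nrow(back), 12L)
  expect_true(all(c("frame_index", "angle_deg", "radius_mm", "x_mm", "y_mm")
                  %in% names(back)))
})
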