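test_that("NTSC grayscale conversion matches the luma weighted sum", {
  expect_equal(rgb_to_gray_ntsc(array(c(1, 1, 1), c(1, 1, 3)))[1, 1], 1.0)
  expect_equal(rgb_to_gray_ntsc(array(c(0, 0, 0), c(1, 1, 3)))[1, 1], 0.0)
  expect_equal(rgb_to_gray_ntsc(array(c(1, 0, 0), c(1, 1, 3)))[1, 1], 0.299)
  expect_equal(rgb_to_gray_ntsc(array(c(0, 1, 0), c(1, 1, 3)))[1, 1], 0.587)
  # monotone: raising any channel never lowers the gray value
  set.seed(11)
  a <- array(runif(5 * 5 * 3), c(5, 5, 3))
  g0 <- rgb_to_gray_ntsc(a)
  for (ch in 1:3) {
    b <- a
    b[, , ch] <- pmin(b[, , ch] + 0.2, 1)
    expect_true(all(rgb_to_gray_ntsc(b) >= g0))
  }
  expect_error(rgb_to_gray_ntsc(matrix(0, 3, 3)), class = "octlumen_shape_error")
})

test_that("colored-overlay removal zeroes saturated pixels and is idempotent", {
  gray <- array(0.5, c(6, 6, 3))
  expect_identical(remove_color_overlays(gray), gray)

  red <- gray
  red[2, 3, ] <- c(1, 0, 0)
  out <- remove_color_overlays(red)
  expect_equal(out[2, 3, ], c(0, 0, 0))
  out[2, 3, ] <- 0.5
  expect_identical(out, gray)

  # colored strip: altered pixel count equals strip area
  img <- array(rep(runif(20 * 20), 3), c(20, 20, 3))  # achromatic field
  img[18:20, , 1] <- 1; img[18:20, , 2] <- 0.8; img[18:20, , 3] <- 0
  cleaned <- remove_color_overlays(img)
  altered <- which(apply(cleaned != img, c(1, 2), any))
  expect_equal(length(altered), 3 * 20)
  expect_true(all(cleaned[18:20, , ] == 0))
  expect_identical(remove_color_overlays(cleaned), cleaned)
})

test_that("frame construction enforces the geometry and range contracts", {
  expect_error(oct_frame(matrix(0.5, 4, 6)), class = "octlumen_shape_error")
  expect_error(oct_frame(matrix(2, 8, 8)), class = "octlumen_range_error")
  expect_error(oct_frame(matrix(0.5, 8, 8), center = c(0.5, 4)),
               class = "octlumen_geometry_error")
  fr <- oct_frame(matrix(0.5, 8, 8))
  expect_equal(fr$center, c(4.5, 4.5))
})

test_that("16-bit frame export round-trips pixel-identically", {
  ph <- generate_phantom(phantom_spec("circle", radius_mm = 0.8,
                                      image_size_px = 256, speckle_level = 0.2))
  f <- tempfile(fileext = ".tif")
  write_frame_tiff(ph$frame, f)
  back <- read_pullback(f, calibration = ph$frame$calibration)
  expect_length(back, 1L)
  expect_identical(back[[1]]$intensity, ph$frame$intensity)
})

test_that("a directory of rasters reads as an ordered pullback", {
  d <- tempfile()
  specs <- list(phantom_spec("circle", radius_mm = 1.0, image_size_px = 320),
                phantom_spec("circle", radius_mm = 1.2, image_size_px = 320))
  write_phantom_pullback(specs, d)
  fr <- read_pullback(d)
  expect_length(fr, 2L)
  expect_equal(vapply(fr, `[[`, 0L, "frame_index"), 0:1)
  expect_true(all(vapply(fr, function(f) max(f$intensity) <= 1, TRUE)))
  expect_error(read_pullback(tempfile()), class = "octlumen_input_format_error")
  empty <- tempfile(); dir.create(empty)
  expect_error(read_pullback(empty), class = "octlumen_empty_input_error")
})

test_that("multiframe DICOM pullbacks read in storage order with calibration", {
  f <- tempfile(fileext = ".dcm")
  skip_if_not(write_test_dicom(f, n_frames = 3L, rows = 24L, cols = 24L,
                               spacing = "0.012"),
              "pydicom unavailable to write the DICOM fixture")
  fr <- read_pullback(f)
  expect_length(fr, 3L)
  expect_equal(vapply(fr, `[[`, 0L, "frame_index"), 0:2)
  expect_equal(fr[[1]]$calibration$pixel_spacing_mm, 0.012)
  # values match the generating formula (8-bit, scaled to [0, 1])
  expected <- outer(0:23, 0:23, function(r, c) test_dicom_value(1, r, c)) / 255
  expect_equal(fr[[2]]$intensity, expected, tolerance = 1e-12)
})

test_that("RGB DICOM frames pass through overlay removal and NTSC conversion", {
  f <- tempfile(fileext = ".dcm")
  skip_if_not(write_test_dicom(f, n_frames = 2L, rows = 16L, cols = 16L,
                               rgb = TRUE),
              "pydicom unavailable to write the DICOM fixture")
  fr <- read_pullback(f)
  expect_length(fr, 2L)
  # fixture is achromatic, so gray equals the channel value
  expected <- outer(0:15, 0:15, function(r, c) test_dicom_value(0, r, c)) / 255
  expect_equal(fr[[1]]$intensity, expected, tolerance = 1e-12)
})
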