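test_that("opening removes sub-disk islands and closing fills sub-disk holes", {
  b <- matrix(FALSE, 30, 30); b[10:12, 10:12] <- TRUE      # 3x3 island, R = 5
  expect_false(any(open_close(b)))

  b2 <- matrix(FALSE, 60, 60); b2[10:49, 10:49] <- TRUE
  b2[30:32, 30:32] <- FALSE                                # 3x3 hole
  out <- open_close(b2)
  expect_true(all(out[30:32, 30:32]))                      # hole filled
  expect_true(all(out[15:44, 15:44]))                      # interior preserved
  expect_false(any(out[1:8, ]))                            # no spill
})

test_that("open_close equals the brute-force Minkowski composition and is idempotent", {
  k <- disk_kernel(5)
  for (seed in c(101, 202, 303)) {
    b <- random_blob_image(64, seed)
    ours <- open_close(b)
    expect_identical(ours, bf_open_close(b, k))
    expect_identical(open_close(ours), ours)
  }
})

test_that("component tracing orders by top row and nails rectangle extrema", {
  b <- matrix(FALSE, 40, 40)
  b[5:10, 8:20] <- TRUE                                    # upper rectangle
  b[25:32, 15:30] <- TRUE                                  # lower rectangle
  comps <- trace_components(b)
  expect_length(comps, 2L)
  expect_equal(comps[[1]]$row_range, c(5, 10))
  expect_equal(comps[[2]]$row_range, c(25, 32))
  ex <- comps[[1]]$extrema
  # rectangle: the 8 extrema collapse pairwise onto the 4 corners
  expect_equal(unname(ex["top_left", ]), c(5, 8))
  expect_equal(unname(ex["left_top", ]), c(5, 8))
  expect_equal(unname(ex["top_right", ]), c(5, 20))
  expect_equal(unname(ex["right_top", ]), c(5, 20))
  expect_equal(unname(ex["bottom_left", ]), c(10, 8))
  expect_equal(unname(ex["left_bottom", ]), c(10, 8))
  expect_equal(unname(ex["bottom_right", ]), c(10, 20))
  expect_equal(unname(ex["right_bottom", ]), c(10, 20))
  expect_error(trace_components(matrix(FALSE, 5, 5)),
               class = "octlumen_no_tissue_error")
})

test_that("extrema of irregular components match exhaustive search", {
  b <- matrix(FALSE, 30, 30)
  b[5:20, 5:9] <- TRUE; b[16:20, 5:25] <- TRUE             # L-shape
  comps <- trace_components(b)
  expect_length(comps, 1L)
  px <- which(b, arr.ind = TRUE)
  expect_equal(unname(comps[[1]]$extrema), unname(bf_extrema(px)))

  # boundary is a closed 8-connected chain on the component
  bd <- comps[[1]]$boundary
  steps <- rbind(diff(bd), bd[1, ] - bd[nrow(bd), ])
  expect_true(all(pmax(abs(steps[, 1]), abs(steps[, 2])) == 1))
  expect_true(all(b[bd]))
})

test_that("8-connectivity links diagonal pixels into one component", {
  b <- matrix(FALSE, 10, 10)
  b[2, 2] <- TRUE; b[3, 3] <- TRUE; b[4, 4] <- TRUE
  expect_length(trace_components(b), 1L)
})

test_that("gap bridging joins aligned components and leaves full rings alone", {
  cal <- calibration_spec(pixel_spacing_mm = 0.01)
  full <- matrix(FALSE, 40, 60); full[, 20:30] <- TRUE     # full-height band
  comps <- trace_components(full)
  res <- bridge_gaps(comps, full, cal)
  expect_identical(res$binary, full)
  expect_equal(nrow(res$bridges), 0L)

  b <- matrix(FALSE, 60, 60)
  b[1:20, 20:30] <- TRUE                                   # aligned in radius,
  b[31:60, 20:30] <- TRUE                                  # 10-row gap
  res2 <- bridge_gaps(trace_components(b), b, cal)
  expect_true(all(rowSums(res2$binary) > 0))               # every row covered
  expect_length(trace_components(res2$binary), 1L)         # now connected
  expect_true(all(res2$binary[b]))                         # only adds foreground
  expect_equal(nrow(res2$bridges), 2L)                     # gap + wrap-around
})

test_that("gaps longer than the cutoff are flagged as bifurcations", {
  cal <- calibration_spec(pixel_spacing_mm = 0.01)
  # two arcs on opposite sides at radius 150 bins = 1.5 mm: the wrap chords
  # approach the 3 mm diameter, far beyond the 2 mm cutoff
  b <- matrix(FALSE, 360, 200)
  b[1:60, 148:160] <- TRUE
  b[181:240, 148:160] <- TRUE
  res <- bridge_gaps(trace_components(b), b, cal)
  expect_equal(nrow(res$bridges), 2L)
  expect_true(all(res$bridges$gap_length_mm > 2))
  expect_true(all(res$bridges$is_bifurcation))
  expect_true(all(rowSums(res$binary) > 0))
})

test_that("phantom bifurcation gap length matches the analytic chord", {
  spec <- phantom_spec("circle", radius_mm = 1.5, bifurcation = c(45, 30))
  ph <- generate_phantom(spec)
  p <- denoise(remove_catheter(to_polar(ph$frame, 360)))
  bin <- discard_small_components(open_close(binarize(p)))
  res <- bridge_gaps(trace_components(bin), bin, ph$frame$calibration)
  expect_gte(nrow(res$bridges), 1L)
  chord <- 2 * 1.5 * sin(15 * pi / 180)
  gap <- res$bridges$gap_length_mm[which.max(res$bridges$gap_length_mm)]
  expect_lt(abs(gap - chord), 2 * 0.01 + 0.03)   # within ~2 radial bins
  expect_false(any(res$bridges$is_bifurcation))  # 0.78 mm < 2 mm cutoff
})

test_that("border extraction takes the innermost intima edge per angle row", {
  b <- matrix(FALSE, 36, 120); b[, 51:120] <- TRUE
  ct <- extract_border(b)
  expect_true(all(abs(ct$radius_per_angle - 50) <= 1))
  expect_true(all(ct$valid_mask))

  # sine-wave border recovered within a bin
  r0 <- 60 + round(10 * sin(2 * pi * (0:35) / 36))
  bs <- matrix(FALSE, 36, 120)
  for (a in 1:36) bs[a, (r0[a] + 1):120] <- TRUE
  cts <- extract_border(bs)
  expect_true(all(abs(cts$radius_per_angle - r0) <= 1))

  # nested rings: the inner ring's inner edge wins, and foreground added
  # beyond the wall does not move the border
  bn <- matrix(FALSE, 36, 120); bn[, 40:55] <- TRUE; bn[, 80:95] <- TRUE
  ctn <- extract_border(bn)
  expect_true(all(abs(ctn$radius_per_angle - 39) <= 1))
  bn2 <- bn; bn2[, 110:120] <- TRUE
  expect_equal(extract_border(bn2)$radius_per_angle, ctn$radius_per_angle)

  expect_error(extract_border(matrix(c(TRUE, FALSE), 2, 10)),
               class = "octlumen_incomplete_segmentation_error")
})
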