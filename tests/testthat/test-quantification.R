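circle_contour <- function(r, n = 360, ctr = c(0, 0)) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind(ctr[1] + r * cos(th), ctr[2] + r * sin(th))
}

test_that("lumen metrics reproduce closed forms for circle and ellipse", {
  m <- lumen_metrics(circle_contour(1.5))
  expect_equal(m$area_mm2, pi * 1.5^2, tolerance = 1e-3)
  expect_equal(m$mean_diameter_mm, 3.0, tolerance = 1e-3)
  expect_equal(m$min_diameter_mm, 3.0, tolerance = 1e-3)
  expect_equal(m$max_diameter_mm, 3.0, tolerance = 1e-3)

  th <- 2 * pi * (0:719) / 720
  ell <- cbind(2 * cos(th), 1 * sin(th))
  me <- lumen_metrics(ell)
  expect_equal(me$area_mm2, 2 * pi, tolerance = 0.002 * 2 * pi)
  expect_equal(me$min_diameter_mm, 2.0, tolerance = 0.005 * 2)
  expect_equal(me$max_diameter_mm, 4.0, tolerance = 0.005 * 4)
})

test_that("rectangle metrics match brute-force centroid chords", {
  # 2 x 1 mm rectangle sampled densely along its perimeter
  tpts <- seq(0, 1, length.out = 200)[-200]
  side <- function(p0, p1) cbind(p0[1] + tpts * (p1[1] - p0[1]),
                                 p0[2] + tpts * (p1[2] - p0[2]))
  rect <- rbind(side(c(-1, -0.5), c(1, -0.5)), side(c(1, -0.5), c(1, 0.5)),
                side(c(1, 0.5), c(-1, 0.5)), side(c(-1, 0.5), c(-1, -0.5)))
  m <- lumen_metrics(rect)
  expect_equal(m$area_mm2, 2.0, tolerance = 1e-9)
  expect_equal(m$min_diameter_mm, 1.0, tolerance = 1e-6)
  expect_equal(m$max_diameter_mm, sqrt(5), tolerance = 0.005 * sqrt(5))
  # fine-sampled chord oracle
  fine <- vapply(seq(0, pi, length.out = 2000)[-2000], function(a) {
    octlumen:::ray_distance(rect, c(0, 0), a) +
      octlumen:::ray_distance(rect, c(0, 0), a + pi)
  }, numeric(1))
  expect_equal(m$min_diameter_mm, min(fine), tolerance = 1e-4)
  expect_equal(m$max_diameter_mm, max(fine), tolerance = 0.005 * max(fine))
})

test_that("metrics are stable under rotation about the centroid", {
  th <- 2 * pi * (0:359) / 360
  blob <- cbind((1.5 + 0.2 * cos(3 * th)) * cos(th),
                (1.5 + 0.2 * cos(3 * th)) * sin(th))
  a <- lumen_metrics(blob)
  rot <- pi / 7
  Rm <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2, 2)
  b <- lumen_metrics(blob %*% t(Rm))
  expect_equal(a$area_mm2, b$area_mm2, tolerance = 1e-9)
  expect_equal(a$mean_diameter_mm, b$mean_diameter_mm, tolerance = 1e-3)
  expect_equal(a$min_diameter_mm, b$min_diameter_mm, tolerance = 2e-3)
  expect_equal(a$max_diameter_mm, b$max_diameter_mm, tolerance = 2e-3)
})

test_that("self-intersecting and degenerate contours are rejected", {
  bowtie <- rbind(c(0, 0), c(1, 1), c(1, 0.8), c(1, 0), c(0, 1.05),
                  c(0.02, 1.2), c(-0.4, 1.1), c(-0.5, 0.4))
  expect_error(lumen_metrics(bowtie), class = "octlumen_geometry_error")
  expect_error(lumen_metrics(circle_contour(1)[1:5, ]),
               class = "octlumen_geometry_error")
})

test_that("relative differences evaluate termwise with the right symmetry", {
  expect_equal(relative_difference(c(3, 4), c(3, 4)), 0)
  expect_equal(relative_difference(2, 1), -50)
  expect_equal(relative_difference(c(2, 4), c(1, 5)), -15)
  expect_equal(absolute_relative_difference(c(3, 4), c(3, 4)), 0)
  expect_equal(absolute_relative_difference(2, 1), 50)
  expect_equal(absolute_relative_difference(c(2, 4), c(1, 5)), 35)

  set.seed(41)
  o <- runif(25, 1, 10); i <- o * runif(25, 0.7, 1.3)
  expect_equal(relative_difference(o, i), -relative_difference(i, o),
               tolerance = 1e-12)
  expect_equal(absolute_relative_difference(o, i),
               absolute_relative_difference(i, o), tolerance = 1e-12)
  expect_gte(absolute_relative_difference(o, i), abs(relative_difference(o, i)))
  expect_error(relative_difference(c(1, -1), c(1, 1)),
               class = "octlumen_domain_error")
  expect_error(relative_difference(1:3, 1:4), class = "octlumen_domain_error")
})

test_that("ICC(2,1) matches the ANOVA mean-squares oracle", {
  set.seed(42)
  subj <- rnorm(10, 6, 2)
  a <- subj + rnorm(10, 0, 0.4)
  b <- subj + 0.3 + rnorm(10, 0, 0.4)
  res <- icc(a, b)
  expect_equal(res$icc, bf_icc21(a, b), tolerance = 1e-10)
  expect_true(res$ci[1] <= res$icc && res$icc <= res$ci[2])
  expect_true(res$icc >= -1 && res$icc <= 1)

  # absolute agreement: a large constant offset pulls ICC well below the
  # Pearson correlation of 1
  off <- icc(a, a + 5)
  expect_lt(off$icc, 0.5)
  expect_equal(cor(a, a + 5), 1)

  # perfect agreement
  expect_equal(icc(a, a)$icc, 1)

  # invariance under a common affine rescaling
  res2 <- icc(3 * a + 2, 3 * b + 2)
  expect_equal(res2$icc, res$icc, tolerance = 1e-10)

  expect_error(icc(c(1, 2), c(1, 2)), class = "octlumen_domain_error")
  expect_error(icc(rep(1, 5), c(1, 2, 3, 4, 5)),
               class = "octlumen_degenerate_variance_error")
})

test_that("Bland-Altman limits follow the hand computations", {
  a <- c(5, 6, 7)
  ba0 <- bland_altman(a, a)
  expect_equal(ba0$mean_difference, 0)
  expect_equal(ba0$loa_low, 0); expect_equal(ba0$loa_high, 0)

  ba <- bland_altman(c(1, 3), c(2, 2))          # d = (-1, 1)
  expect_equal(ba$mean_difference, 0)
  expect_equal(ba$sd_difference, sqrt(2))
  expect_equal(ba$loa_low, -1.96 * sqrt(2))
  expect_equal(ba$loa_high, 1.96 * sqrt(2))
  expect_equal(ba$pairs$mean, c(1.5, 2.5))

  bc <- bland_altman(a, a - 0.7)                # constant shift
  expect_equal(bc$mean_difference, 0.7)
  expect_equal(bc$loa_low, 0.7); expect_equal(bc$loa_high, 0.7)
})

test_that("agreement reports satisfy their internal invariants", {
  set.seed(43)
  x <- runif(15, 4, 8); y <- x * runif(15, 0.9, 1.1)
  rep_ <- agreement_report(x, y, parameter = "area_mm2")
  expect_gte(rep_$ard_percent, abs(rep_$rd_percent))
  expect_lte(rep_$loa_low, rep_$mean_difference)
  expect_gte(rep_$loa_high, rep_$mean_difference)
  expect_true(rep_$icc >= -1 && rep_$icc <= 1)
  df <- as.data.frame(rep_)
  expect_equal(df$parameter, "area_mm2")
  expect_equal(df$mean_difference, mean(x - y))
})
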