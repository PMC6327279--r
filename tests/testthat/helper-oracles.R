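# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths they check.

# Otsu: exhaustive search of the between-class-variance criterion over all
# 256 histogram bin boundaries of [0, 1]
bf_otsu_threshold <- function(v, levels = 256L) {
  breaks <- seq(0, 1, length.out = levels + 1L)
  h <- hist(v, breaks = breaks, plot = FALSE)$counts
  n <- sum(h)
  mids <- (breaks[-1] + breaks[-(levels + 1L)]) / 2
  best <- -Inf; best_t <- NA_real_
  for (t in 1:(levels - 1L)) {
    w0 <- sum(h[1:t]); w1 <- n - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(h[1:t] * mids[1:t]) / w0
    mu1 <- sum(h[(t + 1):levels] * mids[(t + 1):levels]) / w1
    bcv <- w0 * w1 * (mu0 - mu1)^2
    if (bcv > best) { best <- bcv; best_t <- breaks[t + 1L] }
  }
  best_t
}

# between-class variance of [0,1]-data split at threshold t
bf_otsu_bcv <- function(v, t) {
  w0 <- sum(v <= t); w1 <- sum(v > t)
  if (w0 == 0 || w1 == 0) return(0)
  w0 * w1 * (mean(v[v <= t]) - mean(v[v > t]))^2
}

# Minkowski erosion/dilation by per-pixel neighborhood scan; out-of-image
# offsets are ignored (the neighborhood is clipped to the image domain)
bf_morph <- function(binary, kernel, op = c("erode", "dilate")) {
  op <- match.arg(op)
  R <- (nrow(kernel) - 1L) %/% 2L
  off <- which(kernel > 0, arr.ind = TRUE) - (R + 1L)
  n <- nrow(binary); m <- ncol(binary)
  out <- matrix(FALSE, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    ri <- i + off[, 1]; rj <- j + off[, 2]
    ok <- ri >= 1 & ri <= n & rj >= 1 & rj <= m
    v <- binary[cbind(ri[ok], rj[ok])]
    out[i, j] <- if (op == "erode") all(v) else any(v)
  }
  out
}

bf_open_close <- function(binary, kernel) {
  opened <- bf_morph(bf_morph(binary, kernel, "erode"), kernel, "dilate")
  bf_morph(bf_morph(opened, kernel, "dilate"), kernel, "erode")
}

# extreme points by direct search over a component's pixel set
bf_extrema <- function(px) {
  r <- px[, 1]; c <- px[, 2]
  at <- function(sel, secondary, fun) {
    cand <- which(sel)
    cand[which(secondary[cand] == fun(secondary[cand]))[1]]
  }
  rbind(top_left     = px[at(r == min(r), c, min), ],
        top_right    = px[at(r == min(r), c, max), ],
        right_top    = px[at(c == max(c), r, min), ],
        right_bottom = px[at(c == max(c), r, max), ],
        bottom_right = px[at(r == max(r), c, max), ],
        bottom_left  = px[at(r == max(r), c, min), ],
        left_bottom  = px[at(c == min(c), r, max), ],
        left_top     = px[at(c == min(c), r, min), ])
}

# ICC(2,1) from the two-way ANOVA table fitted by aov()
bf_icc21 <- function(first, second) {
  n <- length(first)
  d <- data.frame(y = c(first, second),
                  subj = factor(rep(seq_len(n), 2)),
                  meth = factor(rep(1:2, each = n)))
  ms <- summary(aov(y ~ subj + meth, data = d))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  k <- 2
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}

# Savitzky-Golay center weights from explicit least-squares fits of unit
# impulses (weight j = fitted value at the window center when the data are
# the j-th unit impulse)
bf_savgol_weights <- function(window, order) {
  n <- (window - 1L) %/% 2L
  x <- -n:n
  vapply(seq_len(window), function(j) {
    y <- numeric(window); y[j] <- 1
    fit <- lm(y ~ poly(x, order, raw = TRUE))
    unname(predict(fit, newdata = data.frame(x = 0)))
  }, numeric(1))
}

# blobby random binary image: thresholded smoothed white noise
random_blob_image <- function(n, seed, smooth = 2) {
  set.seed(seed)
  z <- matrix(rnorm(n * n), n, n)
  k <- outer(dnorm(-4:4, sd = smooth), dnorm(-4:4, sd = smooth))
  z <- EBImage::filter2(z, k / sum(k), boundary = "circular")
  z > quantile(z, 0.55)
}
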