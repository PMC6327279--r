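`%||%` <- function(x, y) if (is.null(x)) y else x

#' Flat disk structuring element
#'
#' Binary mask of the flat disk \eqn{\{(i,j): i^2 + j^2 \le R^2\}} on the
#' integer grid, as used for morphological opening and closing of the binarized
#' intimal layer.
#'
#' @param radius disk radius in pixels (bins), a positive integer.
#' @return a (2*radius+1) x (2*radius+1) numeric 0/1 matrix.
#' @export
disk_kernel <- function(radius) {
  stopifnot(is.numeric(radius), length(radius) == 1L, radius >= 1)
  radius <- as.integer(radius)
  o <- outer(-radius:radius, -radius:radius, function(i, j) i * i + j * j <= radius * radius)
  storage.mode(o) <- "double"
  o
}

# replicate-pad a matrix by p rows/cols on every side
pad_replicate <- function(m, p) {
  n <- nrow(m); k <- ncol(m)
  m[c(rep(1L, p), seq_len(n), rep(n, p)), c(rep(1L, p), seq_len(k), rep(k, p)), drop = FALSE]
}

# evaluate code under a seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# integer pixel coordinates on the segment p0 -> p1 (row, col), inclusive;
# sampled densely enough that every intermediate row and column is visited
rasterize_segment <- function(p0, p1) {
  n_steps <- max(abs(p1 - p0)) + 1L
  t <- seq(0, 1, length.out = max(n_steps, 2L))
  cbind(round(p0[1] + t * (p1[1] - p0[1])),
        round(p0[2] + t * (p1[2] - p0[2])))
}

stop_octlumen <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "octlumen_error")))
}
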