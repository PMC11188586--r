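# Separable correlation filters with reflect (half-sample symmetric)
# boundaries. Kernels are truncated at ceil(3*sigma); the chunked structure
# tensor relies on that exact support to guarantee chunking invariance.

gaussian_kernel <- function(sigma, radius = ceiling(3 * sigma)) {
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Derivative-of-Gaussian kernel, normalized so a unit ramp maps to 1.
gaussian_deriv_kernel <- function(sigma, radius = ceiling(3 * sigma)) {
  x <- seq(-radius, radius)
  k <- -x / sigma^2 * exp(-x^2 / (2 * sigma^2))
  k / sum(x * k)
}

# Central difference (response 1 on a unit ramp under correlation).
central_diff_kernel <- function() c(-0.5, 0, 0.5)

# 1-based reflect indexing: ... 2 1 | 1 2 ... n n | n n-1 ...
reflect_index <- function(i, n) {
  j <- (i - 1) %% (2L * n)
  ifelse(j < n, j + 1L, 2L * n - j)
}

# Dense correlation matrix: out[i] = sum_j w[j] * a[reflect(i + j - c)].
conv_matrix <- function(n, w) {
  r <- (length(w) - 1L) %/% 2L
  M <- matrix(0, n, n)
  i <- seq_len(n)
  for (j in seq(-r, r)) {
    idx <- reflect_index(i + j, n)
    M[cbind(i, idx)] <- M[cbind(i, idx)] + w[j + r + 1L]
  }
  M
}

# Correlate a 2D/3D array with a 1D kernel along one axis.
filter_axis <- function(a, w, axis) {
  d <- dim(a)
  nd <- length(d)
  if (axis < 1L || axis > nd) stop("filter_axis: bad axis")
  perm <- c(axis, setdiff(seq_len(nd), axis))
  ap <- aperm(a, perm)
  m <- conv_matrix(d[axis], w) %*% matrix(ap, nrow = d[axis])
  dim(m) <- d[perm]
  aperm(m, order(perm))
}

gauss_blur_2d <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- gaussian_kernel(sigma)
  filter_axis(filter_axis(img, k, 1L), k, 2L)
}

# Moving window sum over an n x n box (reflect boundary).
box_sum_2d <- function(img, n) {
  w <- rep(1, n)
  filter_axis(filter_axis(img, w, 1L), w, 2L)
}

# Bilinear interpolation of matrix values at fractional (row, col),
# 1-based coordinates, replicated borders. Vectorized over positions.
bilinear_interp <- function(img, row, col) {
  nr <- nrow(img)
  nc <- ncol(img)
  row <- pmin(pmax(row, 1), nr)
  col <- pmin(pmax(col, 1), nc)
  r0 <- pmin(floor(row), nr - 1L)
  c0 <- pmin(floor(col), nc - 1L)
  if (nr == 1L) r0 <- rep(1, length(row))
  if (nc == 1L) c0 <- rep(1, length(col))
  fr <- row - r0
  fc <- col - c0
  r1 <- pmin(r0 + 1L, nr)
  c1 <- pmin(c0 + 1L, nc)
  v00 <- img[cbind(r0, c0)]
  v01 <- img[cbind(r0, c1)]
  v10 <- img[cbind(r1, c0)]
  v11 <- img[cbind(r1, c1)]
  (1 - fr) * ((1 - fc) * v00 + fc * v01) + fr * ((1 - fc) * v10 + fc * v11)
}

# Block-average downsampling by an integer factor; partial edge blocks are
# averaged over the pixels they actually cover.
block_downsample <- function(img, f) {
  f <- as.integer(f)
  if (f == 1L) return(img)
  nr <- nrow(img)
  nc <- ncol(img)
  ri <- rep(seq_len(ceiling(nr / f)), each = f, length.out = nr)
  ci <- rep(seq_len(ceiling(nc / f)), each = f, length.out = nc)
  sums <- rowsum(img, ri)
  sums <- t(rowsum(t(sums), ci))
  cnt <- outer(tabulate(ri), tabulate(ci))
  out <- sums / cnt
  dimnames(out) <- NULL
  out
}

# Bilinear upsampling to an explicit target size (corner-aligned mapping).
resize_bilinear <- function(img, nrow_out, ncol_out) {
  sr <- if (nrow_out > 1L) (nrow(img) - 1) / (nrow_out - 1) else 0
  sc <- if (ncol_out > 1L) (ncol(img) - 1) / (ncol_out - 1) else 0
  rows <- 1 + (seq_len(nrow_out) - 1) * sr
  cols <- 1 + (seq_len(ncol_out) - 1) * sc
  grid_r <- matrix(rows, nrow_out, ncol_out)
  grid_c <- matrix(cols, nrow_out, ncol_out, byrow = TRUE)
  matrix(bilinear_interp(img, as.vector(grid_r), as.vector(grid_c)),
         nrow_out, ncol_out)
}

# Half-up rounding (round() in R rounds half to even).
round_half_up <- function(x) floor(x + 0.5)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Run code under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}
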