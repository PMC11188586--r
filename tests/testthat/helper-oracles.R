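# Independent brute-force oracles and small fixture builders used across
# the suite. The oracles deliberately re-derive quantities with plain
# loops / grids so they share no code with the implementation paths they
# check.

# -- reflect indexing, re-derived (half-sample symmetric, 1-based) --------
oracle_reflect <- function(i, n) {
  while (any(i < 1L | i > n)) {
    i <- ifelse(i < 1L, 1L - i, i)
    i <- ifelse(i > n, 2L * n + 1L - i, i)
  }
  i
}

# 1D kernels matching the definition (truncation at ceil(3 sigma)).
oracle_gauss <- function(sigma) {
  r <- ceiling(3 * sigma)
  x <- -r:r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}
oracle_dgauss <- function(sigma) {
  r <- ceiling(3 * sigma)
  x <- -r:r
  k <- -x / sigma^2 * exp(-x^2 / (2 * sigma^2))
  k / sum(x * k)
}

# Direct triple-loop correlation of a 3D volume with a separable kernel
# (kx along x/cols, ky along y/rows, kz along slices), reflect boundary.
oracle_filter3 <- function(vol, ky, kx, kz) {
  d <- dim(vol)
  ry <- (length(ky) - 1L) / 2L
  rx <- (length(kx) - 1L) / 2L
  rz <- (length(kz) - 1L) / 2L
  out <- array(0, d)
  for (y in seq_len(d[1])) for (x in seq_len(d[2])) for (z in seq_len(d[3])) {
    acc <- 0
    for (jy in -ry:ry) for (jx in -rx:rx) for (jz in -rz:rz) {
      yy <- oracle_reflect(y + jy, d[1])
      xx <- oracle_reflect(x + jx, d[2])
      zz <- oracle_reflect(z + jz, d[3])
      acc <- acc + ky[jy + ry + 1] * kx[jx + rx + 1] * kz[jz + rz + 1] *
        vol[yy, xx, zz]
    }
    out[y, x, z] <- acc
  }
  out
}

# Brute-force structure tensor: Gaussian-derivative gradients at sigma_n,
# then an explicit Gaussian-weighted windowed sum of the gradient outer
# products over the neighborhood at sigma_nb.
oracle_structure_tensor <- function(vol, sigma_n, sigma_nb) {
  g <- oracle_gauss(sigma_n)
  dg <- oracle_dgauss(sigma_n)
  Vy <- oracle_filter3(vol, dg, g, g)
  Vx <- oracle_filter3(vol, g, dg, g)
  Vz <- oracle_filter3(vol, g, g, dg)
  w <- oracle_gauss(sigma_nb)
  r <- (length(w) - 1L) / 2L
  d <- dim(vol)
  J <- array(0, c(d, 6))  # xx, xy, xz, yy, yz, zz
  for (y in seq_len(d[1])) for (x in seq_len(d[2])) for (z in seq_len(d[3])) {
    acc <- numeric(6)
    for (jy in -r:r) for (jx in -r:r) for (jz in -r:r) {
      yy <- oracle_reflect(y + jy, d[1])
      xx <- oracle_reflect(x + jx, d[2])
      zz <- oracle_reflect(z + jz, d[3])
      wt <- w[jy + r + 1] * w[jx + r + 1] * w[jz + r + 1]
      gx <- Vx[yy, xx, zz]; gy <- Vy[yy, xx, zz]; gz <- Vz[yy, xx, zz]
      acc <- acc + wt * c(gx * gx, gx * gy, gx * gz, gy * gy, gy * gz,
                          gz * gz)
    }
    J[y, x, z, ] <- acc
  }
  J
}

# Shared 11^3 fixture with its brute-force tensor (computed once per run;
# the triple loops are slow by design).
.oracle_memo <- new.env(parent = emptyenv())
oracle_fixture <- function() {
  if (is.null(.oracle_memo$fix)) {
    set.seed(11)
    vol <- array(rnorm(11^3, 100, 20), c(11, 11, 11))
    .oracle_memo$fix <- list(
      vol = vol,
      sigma_n = 1, sigma_nb = 1.2,
      J = oracle_structure_tensor(vol, 1, 1.2))
  }
  .oracle_memo$fix
}

sym3 <- function(j6) {
  matrix(c(j6[1], j6[2], j6[3],
           j6[2], j6[4], j6[5],
           j6[3], j6[5], j6[6]), 3, 3)
}

# Uniformly distributed random unit vectors.
random_unit_vectors <- function(n) {
  m <- matrix(stats::rnorm(3 * n), n, 3)
  m / sqrt(rowSums(m^2))
}

# Max angle (degrees) of any emitted streamline step from the z axis.
max_step_angle <- function(tract) {
  angs <- vapply(tract$streamlines, function(s) {
    p <- s$points
    if (nrow(p) < 2L) return(0)
    st <- diff(p)
    max(atan2(sqrt(st[, 1]^2 + st[, 2]^2), abs(st[, 3])) * 180 / pi)
  }, numeric(1))
  max(angs)
}

termination_reasons <- function(tract)
  vapply(tract$streamlines, `[[`, character(1), "termination_reason")

# Smooth band-limited test texture (blurred white noise, intensity-scaled).
bandlimited_texture <- function(n, sigma = 3, seed = 1) {
  set.seed(seed)
  base <- matrix(rnorm(n * n), n, n)
  tex <- fibertrack:::gauss_blur_2d(base, sigma)
  tex * 400 + 128
}

# Small two-fascicle straight phantom shared by several tests.
straight_phantom_spec <- function(depth = 60L, noise_sd = 0,
                                  pixel_size = 0.9, rng_seed = 3L) {
  phantom_spec(64, 64, depth,
               list(phantom_bundle("straight", 1, c(20, 32), n_fibers = 5,
                                   fiber_radius = 2.5, fascicle_radius = 10),
                    phantom_bundle("straight", 2, c(44, 32), n_fibers = 5,
                                   fiber_radius = 2.5, fascicle_radius = 10)),
               pixel_size_xy = pixel_size, slice_thickness = 3,
               noise_sd = noise_sd, rng_seed = rng_seed)
}

mean_dice_norm <- function(tract, gm, labels, slices, z0 = 0L) {
  vals <- c()
  for (l in labels) for (z in slices)
    vals <- c(vals, dice_norm(tract, gm, l, z, z0))
  mean(vals)
}
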