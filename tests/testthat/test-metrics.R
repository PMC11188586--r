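make_line_tract <- function(xs, roi = 1L, n_pts = 20L, dz = 3, px = 1,
                            width = 100L, height = 100L) {
  sl <- lapply(xs, function(x0) {
    list(points = cbind(rep(x0, n_pts), rep(50, n_pts),
                        (seq_len(n_pts) - 1) * dz),
         roi_label = as.integer(roi), termination_reason = "reached_end")
  })
  fibertrack:::new_tractogram(sl, list(algorithm = "synthetic",
                                       pixel_size_xy = px,
                                       slice_thickness = dz,
                                       width = width, height = height,
                                       depth = n_pts))
}

test_that("Dice satisfies its identities and formula", {
  a <- matrix(0L, 10, 10); a[2:5, 2:5] <- 1L
  expect_equal(dice(a, a), 1)
  b <- matrix(0L, 10, 10); b[7:9, 7:9] <- 1L
  expect_equal(dice(a, b), 0)
  # |A| = |B| = 16, overlap 8 -> 0.5
  c_ <- matrix(0L, 10, 10); c_[2:5, 4:7] <- 1L
  expect_equal(dice(a, c_), 0.5)
  expect_error(dice(matrix(0L, 4, 4), matrix(0L, 4, 4)), "empty")
  expect_error(dice(a, matrix(0L, 3, 3)), "differ")
})

test_that("tract slice rasterization sets one nearest pixel per point", {
  tr <- make_line_tract(c(10.2, 20.7, 30.5), n_pts = 5)
  m <- rasterize_tract_slice(tr, 2, 1L)
  expect_equal(sum(m), 3)
  expect_equal(m[51, 11], 1L)  # 10.2 rounds to pixel 10 (0-based)
  expect_equal(m[51, 22], 1L)  # 20.7 -> 21
  expect_equal(m[51, 32], 1L)  # 30.5 rounds half-up to 31
  # coincident points collapse to one foreground pixel
  tr2 <- make_line_tract(c(10.1, 10.2), n_pts = 5)
  expect_equal(sum(rasterize_tract_slice(tr2, 1, 1L)), 1)
  # a streamline truncated before z contributes nothing there
  tr3 <- make_line_tract(c(10, 40), n_pts = 6)
  tr3$streamlines[[2]]$points <- tr3$streamlines[[2]]$points[1:2, ]
  expect_equal(sum(rasterize_tract_slice(tr3, 4, 1L)), 1)
  expect_error(rasterize_tract_slice(tr, 1, 9L), "unknown roi_label")
})

test_that("normalized Dice is 1 at the seed slice and tracks overlap decay", {
  spec <- straight_phantom_spec(depth = 30L, pixel_size = 3)
  pv <- phantom_volume(spec)
  truth <- phantom_truth(spec)
  seeds <- sample_seeds(truth$seed_mask, density = 0.2, rng_seed = 4, z0 = 0)
  tr <- propagate(seeds, tensor_provider(pv$stack, 1, 3, 30), "forward", 75)
  gm <- truth$fiber_group_masks
  expect_equal(dice_norm(tr, gm, 1L, 0, 0), 1)
  # perfect tracking on the straight phantom keeps Dice_norm near 1
  for (z in c(10, 20, 29)) {
    expect_gte(dice_norm(tr, gm, 1L, z, 0), 0.9)
    expect_gte(dice_norm(tr, gm, 2L, z, 0), 0.9)
  }
  # a rigidly displaced tractogram has zero overlap
  shifted <- tr
  shifted$streamlines <- lapply(tr$streamlines, function(s) {
    s$points[, 1] <- s$points[, 1] + 60 * spec$pixel_size_xy
    s
  })
  mask <- rasterize_tract_slice(shifted, 10, 1L,
                                dim(gm$labels)[1], dim(gm$labels)[2])
  gmask <- gm$labels[, , 11] == 1L
  expect_equal(dice(mask, gmask), 0)
})

test_that("dice_norm is stable across seed densities", {
  spec <- straight_phantom_spec(depth = 30L, pixel_size = 3)
  pv <- phantom_volume(spec)
  truth <- phantom_truth(spec)
  tp <- tensor_provider(pv$stack, 1, 3, 30)
  gm <- truth$fiber_group_masks
  dn <- function(density) {
    seeds <- sample_seeds(truth$seed_mask, density, rng_seed = 4, z0 = 0)
    tr <- propagate(seeds, tp, "forward", 75)
    mean_dice_norm(tr, gm, 1:2, c(15, 29))
  }
  expect_lt(abs(dn(0.01) - dn(0.05)), 0.05)
})

test_that("streamline resampling is arc-length uniform and exact at ends", {
  seg <- rbind(c(0, 0, 0), c(2, 0, 0))
  r3 <- resample_streamline(seg, 3)
  expect_equal(r3, rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)))

  # identity on an already-uniform streamline
  uni <- cbind(seq(0, 9), 0, seq(0, 27, by = 3))
  expect_equal(resample_streamline(uni, 10), uni, tolerance = 1e-9)

  # arc length of a gentle helix preserved within 1% at K = 12
  t <- seq(0, 2 * pi, length.out = 200)
  helix <- cbind(20 * cos(t), 20 * sin(t), 300 * t / (2 * pi))
  true_len <- sum(sqrt(rowSums(diff(helix)^2)))
  r12 <- resample_streamline(helix, 12)
  len12 <- sum(sqrt(rowSums(diff(r12)^2)))
  expect_lt(abs(len12 - true_len) / true_len, 0.01)
  expect_equal(r12[1, ], helix[1, ])
  expect_equal(r12[12, ], helix[200, ])

  expect_error(resample_streamline(rbind(c(0, 0, 0)), 5), "at least 2")
})

test_that("QuickBundles clustering separates, merges and respects ROIs", {
  # two parallel bundles far beyond theta form exactly two clusters
  tr <- make_line_tract(c(rep(10, 5) + runif(5, -0.1, 0.1),
                          rep(90, 5) + runif(5, -0.1, 0.1)))
  cs <- quickbundles(tr, theta = 8, K = 12)
  expect_equal(length(cs$clusters), 2L)

  # a single streamline is its own centroid
  one <- make_line_tract(42)
  cs1 <- quickbundles(one, theta = 8, K = 12)
  expect_equal(length(cs1$clusters), 1L)
  expect_equal(cs1$clusters[[1]]$centroid,
               resample_streamline(one$streamlines[[1]]$points, 12))

  # duplicates collapse into one cluster with the shared centroid
  dup <- make_line_tract(c(33, 33, 33))
  csd <- quickbundles(dup, theta = 8, K = 12)
  expect_equal(length(csd$clusters), 1L)
  expect_equal(csd$clusters[[1]]$centroid,
               resample_streamline(dup$streamlines[[1]]$points, 12))

  # same geometry, different ROI labels: clusters never mix ROIs
  mixed <- make_line_tract(c(10, 10))
  mixed$streamlines[[2]]$roi_label <- 2L
  csm <- quickbundles(mixed, theta = 8, K = 12)
  expect_equal(length(csm$clusters), 2L)

  # cluster count is monotone non-increasing in theta
  set.seed(20)
  spread <- make_line_tract(runif(12, 10, 90))
  counts <- vapply(c(2, 10, 30, 100),
                   function(th) length(quickbundles(spread, th, 12)$clusters),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("MCN distance is symmetric, zero on self and exact on translates", {
  tr_a <- make_line_tract(c(10, 20, 30))
  expect_equal(mcn_dist(tr_a, tr_a, 50, 12), 0)

  # rigid x-translation of parallel straight streamlines by d um gives d
  d <- 7.25
  tr_b <- tr_a
  tr_b$streamlines <- lapply(tr_a$streamlines, function(s) {
    s$points[, 1] <- s$points[, 1] + d
    s
  })
  expect_equal(mcn_dist(tr_a, tr_b, 50, 12), d, tolerance = 1e-6)
  expect_identical(mcn_dist(tr_a, tr_b, 50, 12), mcn_dist(tr_b, tr_a, 50, 12))

  # ROI restriction: unmatched ROIs are skipped with a warning
  tr_c <- make_line_tract(c(10, 20), roi = 1L)
  tr_c$streamlines[[2]]$roi_label <- 2L
  tr_d <- make_line_tract(15, roi = 1L)
  expect_warning(mcn_dist(tr_c, tr_d, 50, 12), "skipped")
  tr_e <- make_line_tract(15, roi = 3L)
  expect_error(suppressWarnings(mcn_dist(tr_c, tr_e, 50, 12)), "share no")
})
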