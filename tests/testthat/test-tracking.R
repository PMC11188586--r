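test_that("tensor tracking keeps straight fibers vertical over 100 slices", {
  spec <- straight_phantom_spec(depth = 100L)
  pv <- phantom_volume(spec)
  truth <- phantom_truth(spec)
  seeds <- sample_seeds(truth$seed_mask, density = 0.1, rng_seed = 9, z0 = 0)
  tr <- propagate(seeds, tensor_provider(pv$stack, 1, 5, 100), "forward", 75)
  expect_equal(n_streamlines(tr), nrow(seeds))
  expect_true(all(termination_reasons(tr) == "reached_end"))
  lens <- vapply(tr$streamlines, function(s) nrow(s$points), integer(1))
  expect_true(all(lens == 100L))
  drift <- vapply(tr$streamlines, function(s) {
    p <- s$points
    sqrt(sum((p[nrow(p), 1:2] - p[1, 1:2])^2))
  }, numeric(1))
  expect_lt(max(drift), spec$pixel_size_xy)  # under one voxel

  # z is strictly monotone with one point per slice plane
  zs <- tr$streamlines[[1]]$points[, 3]
  expect_equal(diff(zs), rep(spec$slice_thickness, 99))
})

test_that("optic-flow tracking follows uniform in-plane drift", {
  spec <- phantom_spec(96, 96, 60,
    list(phantom_bundle("drift", 1, c(20, 48), n_fibers = 8,
                        fiber_radius = 2.5, fascicle_radius = 12,
                        drift = c(0.5, 0))),
    pixel_size_xy = 0.9, slice_thickness = 3, rng_seed = 4)
  pv <- phantom_volume(spec)
  truth <- phantom_truth(spec)
  seeds <- sample_seeds(truth$seed_mask, density = 0.1, rng_seed = 9, z0 = 0)
  tr <- propagate(seeds, flow_provider(pv$stack, 15, 2, 2), "forward", 75)
  slopes <- vapply(tr$streamlines, function(s) {
    p <- s$points
    (p[nrow(p), 1] - p[1, 1]) / (nrow(p) - 1) / spec$pixel_size_xy
  }, numeric(1))
  expect_lt(max(abs(slopes - 0.5)), 0.1)
})

test_that("tracking is deterministic and direction-consistent", {
  spec <- straight_phantom_spec(depth = 40L)
  pv <- phantom_volume(spec)
  truth <- phantom_truth(spec)
  tp <- tensor_provider(pv$stack, 1, 5, 40)

  seeds <- sample_seeds(truth$seed_mask, density = 0.2, rng_seed = 5, z0 = 0)
  t1 <- propagate(seeds, tp, "forward", 75)
  t2 <- propagate(seeds, tp, "forward", 75)
  expect_identical(t1$streamlines, t2$streamlines)

  # forward from slice 0 vs backward from the last slice: per-slice
  # Hausdorff distance under one voxel on a straight phantom
  seeds_all <- sample_seeds(truth$seed_mask, density = 1, rng_seed = 5, z0 = 0)
  fwd <- propagate(seeds_all, tp, "forward", 75)
  last_mask <- truth$fiber_group_masks$labels[, , 40]
  seeds_back <- sample_seeds(last_mask, density = 1, rng_seed = 5, z0 = 39)
  bwd <- propagate(seeds_back, tp, "backward", 75)
  pts_at <- function(tract, z) {
    do.call(rbind, lapply(tract$streamlines, function(s) {
      zi <- fibertrack:::round_half_up(s$points[, 3] / spec$slice_thickness)
      s$points[zi == z, 1:2, drop = FALSE]
    }))
  }
  hausdorff <- function(a, b) {
    dmat <- sqrt(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2)
    max(max(apply(dmat, 1, min)), max(apply(dmat, 2, min)))
  }
  for (z in c(10, 20, 30))
    expect_lt(hausdorff(pts_at(fwd, z), pts_at(bwd, z)), spec$pixel_size_xy)

  # a seed at the stack end pointing outward stops immediately
  out_tr <- propagate(seeds_back, tp, "forward", 75)
  expect_true(all(termination_reasons(out_tr) == "reached_end"))
  expect_true(all(vapply(out_tr$streamlines,
                         function(s) nrow(s$points), integer(1)) == 1L))
})

test_that("steep orientations terminate tracking with angle_exceeded", {
  spec <- phantom_spec(160, 48, 40,
    list(phantom_bundle("bend", 1, c(20, 24), n_fibers = 5,
                        fiber_radius = 2.5, fascicle_radius = 10,
                        bend_z = 30, bend_deg = 80)),
    pixel_size_xy = 3, slice_thickness = 3, rng_seed = 6)
  pv <- phantom_volume(spec)
  truth <- phantom_truth(spec)
  seeds <- sample_seeds(truth$seed_mask, density = 0.2, rng_seed = 9, z0 = 0)
  tr <- propagate(seeds, tensor_provider(pv$stack, 1, 3, 40), "forward", 75)
  expect_true(all(termination_reasons(tr) == "angle_exceeded"))
  # truncation happens at the bend, within the tensor smoothing support
  zend <- vapply(tr$streamlines,
                 function(s) s$points[nrow(s$points), 3] / 3, numeric(1))
  expect_true(all(abs(zend - 30) <= ceiling(3 * (1 + 3))))
  expect_lte(max_step_angle(tr), 75)
})

test_that("fascicle-mask constraints enforce anatomical closure", {
  # straight fibers with static masks; one drifting bundle escapes
  spec <- phantom_spec(96, 64, 40,
    list(phantom_bundle("straight", 1, c(20, 32), n_fibers = 5,
                        fiber_radius = 2.5, fascicle_radius = 10),
         phantom_bundle("drift", 2, c(60, 32), n_fibers = 5,
                        fiber_radius = 2.5, fascicle_radius = 10,
                        drift = c(0.6, 0))),
    pixel_size_xy = 3, slice_thickness = 3, rng_seed = 8)
  pv <- phantom_volume(spec)
  truth <- phantom_truth(spec)
  seeds <- sample_seeds(truth$seed_mask, density = 0.2, rng_seed = 3, z0 = 0)
  tr <- propagate(seeds, tensor_provider(pv$stack, 1, 3, 40), "forward", 75)

  # static masks: replicate the slice-0 fascicle mask through depth; the
  # drifting bundle leaves it while the straight one stays inside
  static <- truth$fascicle_masks
  static$labels <- array(rep(static$labels[, , 1], 40), dim(static$labels))

  all_inside <- function(tract, masks) {
    all(vapply(tract$streamlines, function(s) {
      vox <- fibertrack:::streamline_voxels(s$points, masks$meta)
      all(masks$labels[vox[, c("row", "col", "slice"), drop = FALSE]] > 0)
    }, logical(1)))
  }
  expect_false(all_inside(tr, static))

  trunc <- constrain_to_mask(tr, static, "truncate")
  expect_true(all_inside(trunc, static))
  expect_true("left_fascicle_mask" %in% termination_reasons(trunc))
  # only streamlines seeded outside the static mask may disappear entirely
  seed_in <- vapply(tr$streamlines, function(s) {
    vox <- fibertrack:::streamline_voxels(s$points[1, , drop = FALSE],
                                          static$meta)
    static$labels[vox[, c("row", "col", "slice"), drop = FALSE]] > 0
  }, logical(1))
  expect_equal(n_streamlines(trunc), sum(seed_in))

  rem <- constrain_to_mask(tr, static, "remove")
  expect_true(all_inside(rem, static))
  expect_lt(n_streamlines(rem), n_streamlines(tr))
  # surviving streamlines are exactly those that never left
  labs <- vapply(rem$streamlines, `[[`, integer(1), "roi_label")
  expect_true(all(labs == 1L))

  # all-foreground masks are the identity in both modes
  full <- truth$fascicle_masks
  full$labels[] <- 1L
  expect_identical(constrain_to_mask(tr, full, "truncate")$streamlines,
                   tr$streamlines)
  expect_identical(constrain_to_mask(tr, full, "remove")$streamlines,
                   tr$streamlines)
})

test_that("polygon editing deletes and creates streamlines", {
  spec <- straight_phantom_spec(depth = 40L, pixel_size = 3)
  pv <- phantom_volume(spec)
  truth <- phantom_truth(spec)
  tp <- tensor_provider(pv$stack, 1, 5, 40)
  seeds <- sample_seeds(truth$seed_mask, density = 0.2, rng_seed = 5, z0 = 0)
  tr <- propagate(seeds, tp, "forward", 75)

  # polygon covering the whole slice empties the tractogram
  whole <- cbind(c(-1, 64, 64, -1), c(-1, -1, 64, 64))
  emptied <- edit_delete(tr, whole, 0)
  expect_equal(n_streamlines(emptied), 0L)
  expect_equal(attr(emptied, "n_removed"), n_streamlines(tr))

  # a degenerate polygon removes nothing
  degen <- cbind(c(10, 20, 10), c(10, 10, 10))
  expect_equal(n_streamlines(edit_delete(tr, degen, 0)), n_streamlines(tr))

  # a polygon over one bundle removes exactly that bundle
  left <- cbind(c(0, 31, 31, 0), c(0, 0, 63, 63))
  part <- edit_delete(tr, left, 0)
  expect_true(all(vapply(part$streamlines, `[[`, integer(1),
                         "roi_label") == 2L))
  expect_error(edit_delete(tr, left, 99), "outside")

  # re-seeding the original ROI-1 pixels under the same rng_seed duplicates
  # its streamlines (modulo the fresh label)
  roi1 <- truth$seed_mask == 1L
  storage.mode(roi1) <- "integer"
  # polygon = bounding box of ROI 1 (covers the whole component)
  idx <- which(roi1 > 0, arr.ind = TRUE)
  bbox <- cbind(c(min(idx[, 2]) - 1.4, max(idx[, 2]) - 0.6,
                  max(idx[, 2]) - 0.6, min(idx[, 2]) - 1.4),
                c(min(idx[, 1]) - 1.4, min(idx[, 1]) - 1.4,
                  max(idx[, 1]) - 0.6, max(idx[, 1]) - 0.6))
  grown <- edit_create(part, bbox, z = 0, density = 0.2, rng_seed = 5,
                       provider = tp)
  expect_gt(n_streamlines(grown), n_streamlines(part))
  new_labs <- vapply(grown$streamlines, `[[`, integer(1), "roi_label")
  expect_true(3L %in% new_labs)

  # an empty polygon is the identity
  expect_identical(edit_create(part, degen, 0, 0.2, 5, tp)$streamlines,
                   part$streamlines)
})

test_that("tractogram files round-trip (JSON-lines exactly, trk to float32)", {
  spec <- straight_phantom_spec(depth = 20L)
  pv <- phantom_volume(spec)
  truth <- phantom_truth(spec)
  seeds <- sample_seeds(truth$seed_mask, density = 0.1, rng_seed = 2, z0 = 0)
  tr <- propagate(seeds, tensor_provider(pv$stack, 1, 2, 20), "forward", 75)

  path <- tempfile(fileext = ".jsonl")
  write_tractogram_jsonl(tr, path)
  back <- read_tractogram_jsonl(path)
  expect_equal(length(back$streamlines), length(tr$streamlines))
  for (i in seq_along(tr$streamlines)) {
    expect_identical(unname(back$streamlines[[i]]$points),
                     unname(tr$streamlines[[i]]$points))
    expect_identical(back$streamlines[[i]]$roi_label,
                     tr$streamlines[[i]]$roi_label)
    expect_identical(back$streamlines[[i]]$termination_reason,
                     tr$streamlines[[i]]$termination_reason)
  }

  trk <- tempfile(fileext = ".trk")
  write_tractogram_trk(tr, trk)
  got <- read_tractogram_trk(trk)
  expect_equal(got$voxel_size,
               c(spec$pixel_size_xy, spec$pixel_size_xy,
                 spec$slice_thickness), tolerance = 1e-6)
  expect_equal(length(got$streamlines), length(tr$streamlines))
  expect_equal(got$streamlines[[1]], unname(tr$streamlines[[1]]$points),
               tolerance = 1e-5)
})
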