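# Synthetic fiber phantoms emulating transverse serial block-face sections
# of peripheral nerve: bright tubular fiber cross-sections grouped into
# fascicles running roughly along z, with optional tilt, drift, helices,
# split/merge migration, sub-pixel in-plane motion and additive noise.
# All geometry is analytic, so ground-truth trajectories are exact.

#' Describe one fiber bundle (fascicle) of a phantom
#'
#' @param model centerline model: `"straight"`, `"tilted"` (constant tilt
#'   about the y axis, drift in x), `"drift"` (constant in-plane velocity),
#'   `"helical"`, `"bend"` (straight until `bend_z`, then tilted at
#'   `bend_deg` in the xz-plane), or `"merge"` (smoothstep migration toward
#'   a target, used for split/merge scenes).
#' @param roi positive integer ROI label.
#' @param center (x, y) centerline position at z = 0, in 0-based pixels.
#' @param n_fibers number of fibers in the bundle.
#' @param fiber_radius fiber cross-section radius in pixels.
#' @param fascicle_radius fascicle (mask) radius in pixels.
#' @param tilt_deg tilt from the z axis, for `"tilted"`.
#' @param drift (dx, dy) pixels per slice, for `"drift"`.
#' @param helix_radius,helix_pitch radius (px) and pitch (slices), for
#'   `"helical"`.
#' @param target (x, y) destination of the bundle center, for `"merge"`.
#' @param migrate_z (z1, z2) 0-based slice range over which the migration
#'   runs (smoothstep), for `"merge"`.
#' @param target_radius fascicle mask radius at the destination, for
#'   `"merge"`.
#' @param target_offset_center (x, y) offset added to the shrunken fiber
#'   offsets at the destination (keeps migrated groups disjoint inside the
#'   merged fascicle), for `"merge"`.
#' @return A `phantom_bundle` description.
#' @export
phantom_bundle <- function(model = c("straight", "tilted", "drift",
                                     "helical", "bend", "merge"),
                           roi, center, n_fibers = 8L, fiber_radius = 2,
                           fascicle_radius = 9, tilt_deg = 0,
                           bend_z = 0L, bend_deg = 80,
                           drift = c(0, 0), helix_radius = 5,
                           helix_pitch = 60, target = center,
                           migrate_z = c(0L, 1L), target_radius = fascicle_radius,
                           target_offset_center = c(0, 0)) {
  model <- match.arg(model)
  structure(list(model = model, roi = as.integer(roi), center = center,
                 n_fibers = as.integer(n_fibers),
                 fiber_radius = fiber_radius,
                 fascicle_radius = fascicle_radius, tilt_deg = tilt_deg,
                 bend_z = as.integer(bend_z), bend_deg = bend_deg,
                 drift = drift, helix_radius = helix_radius,
                 helix_pitch = helix_pitch, target = target,
                 migrate_z = migrate_z, target_radius = target_radius,
                 target_offset_center = target_offset_center),
            class = "phantom_bundle")
}

#' Describe a synthetic fiber phantom
#'
#' Defaults mirror a typical block-face imaging geometry: 0.9 um in-plane
#' pixels and 3 um slices.
#'
#' @param width,height,depth stack dimensions (pixels, pixels, slices).
#' @param bundles list of [phantom_bundle()]s; distinct fascicles must not
#'   overlap at the seed slice (z = 0).
#' @param pixel_size_xy,slice_thickness calibration in micrometers.
#' @param fiber_brightness,background intensity levels (0-255); fibers are
#'   rendered as anti-aliased bright disks.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param invert_contrast render dark fibers on a bright background
#'   (absorptive-stain appearance).
#' @param rng_seed integer; the phantom (including noise and fiber
#'   placement) is a deterministic function of the spec and this seed.
#' @param step_size chunk size recorded in the metadata.
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(width, height, depth, bundles,
                         pixel_size_xy = 0.9, slice_thickness = 3,
                         fiber_brightness = 200, background = 30,
                         noise_sd = 0, invert_contrast = FALSE,
                         rng_seed = 1L, step_size = 64L) {
  stopifnot(length(bundles) >= 1L)
  spec <- structure(list(width = as.integer(width),
                         height = as.integer(height),
                         depth = as.integer(depth), bundles = bundles,
                         pixel_size_xy = pixel_size_xy,
                         slice_thickness = slice_thickness,
                         fiber_brightness = fiber_brightness,
                         background = background, noise_sd = noise_sd,
                         invert_contrast = invert_contrast,
                         rng_seed = as.integer(rng_seed),
                         step_size = as.integer(step_size)),
                    class = "phantom_spec")
  check_phantom_spec(spec)
  spec
}

# Bundle centerline (x, y) in 0-based pixels at 0-based slice z (vectorized
# over z).
bundle_center <- function(b, z, spec) {
  px_per_slice <- spec$slice_thickness / spec$pixel_size_xy
  switch(b$model,
    straight = cbind(rep(b$center[1], length(z)), rep(b$center[2], length(z))),
    tilted = cbind(b$center[1] + tan(b$tilt_deg * pi / 180) * px_per_slice * z,
                   rep(b$center[2], length(z))),
    bend = cbind(b$center[1] + tan(b$bend_deg * pi / 180) * px_per_slice *
                   pmax(0, z - b$bend_z),
                 rep(b$center[2], length(z))),
    drift = cbind(b$center[1] + b$drift[1] * z,
                  b$center[2] + b$drift[2] * z),
    helical = cbind(b$center[1] + b$helix_radius *
                      (cos(2 * pi * z / b$helix_pitch) - 1),
                    b$center[2] + b$helix_radius *
                      sin(2 * pi * z / b$helix_pitch)),
    merge = {
      s <- smoothstep((z - b$migrate_z[1]) /
                        max(1, b$migrate_z[2] - b$migrate_z[1]))
      cbind(b$center[1] + s * (b$target[1] - b$center[1]),
            b$center[2] + s * (b$target[2] - b$center[2]))
    })
}

smoothstep <- function(t) {
  t <- clamp(t, 0, 1)
  t * t * (3 - 2 * t)
}

bundle_mask_radius <- function(b, z) {
  if (b$model != "merge") return(rep(b$fascicle_radius, length(z)))
  s <- smoothstep((z - b$migrate_z[1]) / max(1, b$migrate_z[2] - b$migrate_z[1]))
  b$fascicle_radius + s * (b$target_radius - b$fascicle_radius)
}

# Deterministic fiber offsets inside a fascicle: greedy dart throwing with a
# minimum separation so fiber cross-sections stay distinct.
fiber_offsets <- function(b, rng_seed) {
  rmax <- b$fascicle_radius - b$fiber_radius - 1
  if (rmax <= 0) stop("fascicle_radius too small for fiber_radius")
  # fibers in real fascicles nearly touch; allow slight overlap
  min_sep <- 1.8 * b$fiber_radius
  with_seed(rng_seed + 1000L + b$roi, {
    pts <- matrix(0, 0, 2)
    tries <- 0L
    while (nrow(pts) < b$n_fibers && tries < 4000L) {
      tries <- tries + 1L
      r <- rmax * sqrt(stats::runif(1))
      a <- stats::runif(1, 0, 2 * pi)
      cand <- c(r * cos(a), r * sin(a))
      if (nrow(pts) == 0L ||
          min(sqrt(rowSums((pts - matrix(cand, nrow(pts), 2,
                                         byrow = TRUE))^2))) >= min_sep)
        pts <- rbind(pts, cand)
    }
    if (nrow(pts) < b$n_fibers)
      stop("could not place ", b$n_fibers, " fibers in fascicle ", b$roi)
    unname(pts)
  })
}

# Per-fiber (x, y) positions at slice z for one bundle.
fiber_positions <- function(b, offsets, z, spec) {
  cen <- bundle_center(b, z, spec)
  if (b$model == "merge") {
    s <- smoothstep((z - b$migrate_z[1]) /
                      max(1, b$migrate_z[2] - b$migrate_z[1]))
    # keep fiber spacing nearly constant during migration (fiber
    # cross-sectional area is conserved along a nerve), shrinking only
    # slightly so migrated groups pack around their target_offset_center
    shrink <- 0.8
    tgt <- offsets * shrink +
      matrix(b$target_offset_center, nrow(offsets), 2, byrow = TRUE)
    off <- offsets + s * (tgt - offsets)
  } else {
    off <- offsets
  }
  cbind(cen[1] + off[, 1], cen[2] + off[, 2])
}

check_phantom_spec <- function(spec) {
  zs <- seq.int(0L, spec$depth - 1L)
  for (b in spec$bundles) {
    cen <- bundle_center(b, zs, spec)
    r <- bundle_mask_radius(b, zs)
    if (any(cen[, 1] - r < 0) || any(cen[, 1] + r > spec$width - 1) ||
        any(cen[, 2] - r < 0) || any(cen[, 2] + r > spec$height - 1))
      stop("bundle ", b$roi, " leaves the image bounds")
  }
  # fascicles must be disjoint at the seed slice
  n <- length(spec$bundles)
  if (n > 1L) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    bi <- spec$bundles[[i]]; bj <- spec$bundles[[j]]
    ci <- bundle_center(bi, 0L, spec); cj <- bundle_center(bj, 0L, spec)
    if (sqrt(sum((ci - cj)^2)) < bi$fascicle_radius + bj$fascicle_radius)
      stop("fascicles ", bi$roi, " and ", bj$roi, " overlap at the seed slice")
  }
  invisible(spec)
}

# Render one slice (no noise): background plus anti-aliased bright disks.
render_slice_clean <- function(spec, offsets_list, z) {
  img <- matrix(spec$background, spec$height, spec$width)
  amp <- spec$fiber_brightness - spec$background
  for (bi in seq_along(spec$bundles)) {
    b <- spec$bundles[[bi]]
    pos <- fiber_positions(b, offsets_list[[bi]], z, spec)
    for (k in seq_len(nrow(pos))) {
      cx <- pos[k, 1]; cy <- pos[k, 2]; r <- b$fiber_radius
      c0 <- max(0L, floor(cx - r - 1)); c1 <- min(spec$width - 1L, ceiling(cx + r + 1))
      r0 <- max(0L, floor(cy - r - 1)); r1 <- min(spec$height - 1L, ceiling(cy + r + 1))
      if (c1 < c0 || r1 < r0) next
      cols <- c0:c1
      rows <- r0:r1
      d <- sqrt(outer((rows - cy)^2, (cols - cx)^2, `+`))
      cov <- clamp(r + 0.5 - d, 0, 1)
      img[rows + 1L, cols + 1L] <- img[rows + 1L, cols + 1L] + amp * cov
    }
  }
  if (spec$invert_contrast) img <- 255 - img
  img
}

#' Render a phantom volume in memory
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` (H x W x depth array, integer intensities in
#'   0-255), the [stack_meta()], and a `stack` ([array_stack()]) view.
#' @export
phantom_volume <- function(spec) {
  offsets_list <- lapply(spec$bundles, fiber_offsets, rng_seed = spec$rng_seed)
  vol <- array(0, dim = c(spec$height, spec$width, spec$depth))
  with_seed(spec$rng_seed, {
    for (z in seq.int(0L, spec$depth - 1L)) {
      img <- render_slice_clean(spec, offsets_list, z)
      if (spec$noise_sd > 0)
        img <- img + matrix(stats::rnorm(length(img), 0, spec$noise_sd),
                            nrow(img), ncol(img))
      vol[, , z + 1L] <- clamp(round_half_up(img), 0, 255)
    }
  })
  meta <- stack_meta(spec$pixel_size_xy, spec$slice_thickness, ".png",
                     spec$depth, spec$step_size)
  list(volume = vol, meta = meta, stack = array_stack(vol, meta))
}

#' Ground truth of a phantom
#'
#' @param spec a [phantom_spec()].
#' The fiber-group masks emulate how ground truth is produced on real
#' stacks: a rater outlines each group of fibers as one filled region, so
#' per ROI the mask is the smallest enclosing disk of the group's fiber
#' cross-sections (not the individual fibers). Where two group envelopes
#' touch, each pixel goes to the group whose envelope it is deepest
#' inside.
#'
#' @return list with `tractogram` (exact analytic fiber centerlines, one
#'   point per slice), `fascicle_masks` and `fiber_group_masks` (both
#'   [mask_stack()]s), and the seed mask (the fiber-group label image at
#'   slice 0).
#' @export
phantom_truth <- function(spec) {
  offsets_list <- lapply(spec$bundles, fiber_offsets, rng_seed = spec$rng_seed)
  px <- spec$pixel_size_xy
  dz <- spec$slice_thickness
  zs <- seq.int(0L, spec$depth - 1L)
  streamlines <- list()
  for (bi in seq_along(spec$bundles)) {
    b <- spec$bundles[[bi]]
    for (k in seq_len(nrow(offsets_list[[bi]]))) {
      pts <- matrix(0, length(zs), 3)
      for (z in zs) {
        p <- fiber_positions(b, offsets_list[[bi]][k, , drop = FALSE], z, spec)
        pts[z + 1L, ] <- c(p[1, 1] * px, p[1, 2] * px, z * dz)
      }
      streamlines[[length(streamlines) + 1L]] <-
        list(points = pts, roi_label = b$roi,
             termination_reason = "reached_end")
    }
  }
  meta <- stack_meta(px, dz, ".png", spec$depth, spec$step_size)
  fasc <- array(0L, dim = c(spec$height, spec$width, spec$depth))
  grp <- array(0L, dim = c(spec$height, spec$width, spec$depth))
  gc_cols <- matrix(0:(spec$width - 1L), spec$height, spec$width, byrow = TRUE)
  gc_rows <- matrix(0:(spec$height - 1L), spec$height, spec$width)
  for (z in zs) {
    fs <- matrix(0L, spec$height, spec$width)
    gs <- matrix(0L, spec$height, spec$width)
    depth_in <- matrix(-Inf, spec$height, spec$width)
    for (bi in seq_along(spec$bundles)) {
      b <- spec$bundles[[bi]]
      cen <- bundle_center(b, z, spec)
      rad <- bundle_mask_radius(b, z)
      d <- sqrt((gc_cols - cen[1, 1])^2 + (gc_rows - cen[1, 2])^2)
      fs[d <= rad] <- 1L
      # group envelope: smallest enclosing disk of the fiber sections
      pos <- fiber_positions(b, offsets_list[[bi]], z, spec)
      gcen <- colMeans(pos)
      grad <- max(sqrt(rowSums((pos - matrix(gcen, nrow(pos), 2,
                                             byrow = TRUE))^2))) +
        b$fiber_radius + 0.5
      d <- sqrt((gc_cols - gcen[1])^2 + (gc_rows - gcen[2])^2)
      inside <- d <= grad & (grad - d) > depth_in
      gs[inside] <- b$roi
      depth_in[inside] <- (grad - d)[inside]
    }
    fasc[, , z + 1L] <- fs
    grp[, , z + 1L] <- gs
  }
  prov <- list(algorithm = "ground-truth", rng_seed = spec$rng_seed,
               pixel_size_xy = px, slice_thickness = dz,
               width = spec$width, height = spec$height, depth = spec$depth,
               seed_slice = 0L)
  list(tractogram = new_tractogram(streamlines, prov),
       fascicle_masks = mask_stack(fasc, meta),
       fiber_group_masks = mask_stack(grp, meta),
       seed_mask = grp[, , 1])
}

#' Render a phantom to disk
#'
#' Writes the PNG slice stack, the XML metadata file, the seed mask (the
#' fiber-group label image at slice 0), per-slice fascicle and fiber-group
#' mask PNGs, and the exact ground-truth tractogram in JSON-lines format.
#' Everything is a deterministic function of the spec.
#'
#' @param spec a [phantom_spec()].
#' @param out_dir output directory (created if needed).
#' @return list of output paths (`stack_dir`, `meta_xml`, `seed_mask`,
#'   `fascicle_mask_dir`, `fiber_group_mask_dir`, `ground_truth`),
#'   invisibly.
#' @export
render_phantom <- function(spec, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stack_dir <- file.path(out_dir, "stack")
  fdir <- file.path(out_dir, "fascicle_masks")
  gdir <- file.path(out_dir, "fiber_group_masks")
  for (d in c(stack_dir, fdir, gdir))
    dir.create(d, showWarnings = FALSE, recursive = TRUE)
  pv <- phantom_volume(spec)
  truth <- phantom_truth(spec)
  for (z in seq_len(spec$depth)) {
    png::writePNG(pv$volume[, , z] / 255,
                  file.path(stack_dir, sprintf("slice_%04d.png", z - 1L)))
    png::writePNG(truth$fascicle_masks$labels[, , z] / 255,
                  file.path(fdir, sprintf("mask_%04d.png", z - 1L)))
    png::writePNG(truth$fiber_group_masks$labels[, , z] / 255,
                  file.path(gdir, sprintf("mask_%04d.png", z - 1L)))
  }
  meta_xml <- file.path(out_dir, "meta.xml")
  write_metadata(pv$meta, meta_xml)
  seed_path <- file.path(out_dir, "seed_mask.png")
  png::writePNG(truth$seed_mask / 255, seed_path)
  gt_path <- file.path(out_dir, "ground_truth.jsonl")
  write_tractogram_jsonl(truth$tractogram, gt_path)
  invisible(list(stack_dir = stack_dir, meta_xml = meta_xml,
                 seed_mask = seed_path, fascicle_mask_dir = fdir,
                 fiber_group_mask_dir = gdir, ground_truth = gt_path))
}

#' Build a split/merge phantom scene
#'
#' Fibers from `n_fascicles` distinct fascicles migrate along smooth
#' (bounded-angle) trajectories into a single central fascicle, emulating
#' the fascicle merging events seen in peripheral nerve stacks: the
#' final-slice fascicle mask has one connected component containing fibers
#' from every source ROI, while the fiber-group masks keep the source
#' labels. Migration steeper than `max_migration_deg` from the stack axis
#' is rejected.
#'
#' @param depth number of slices (default 90).
#' @param n_fascicles number of source fascicles (>= 2, default 4).
#' @param width,height image size in pixels.
#' @param fibers_per_fascicle,fiber_radius,fascicle_radius bundle geometry
#'   in pixels.
#' @param migrate_frac (start, end) of the migration window as fractions of
#'   the stack depth.
#' @param pixel_size_xy,slice_thickness calibration in micrometers.
#' @param noise_sd additive noise standard deviation.
#' @param rng_seed phantom seed.
#' @param max_migration_deg migration angle bound in degrees (default 45,
#'   comfortably inside the 75-degree tracking envelope).
#' @return A `phantom_spec`.
#' @export
make_split_merge_scene <- function(depth = 90L, n_fascicles = 4L,
                                   width = 160L, height = 160L,
                                   fibers_per_fascicle = 10L,
                                   fiber_radius = 2, fascicle_radius = 16,
                                   migrate_frac = c(0.15, 0.85),
                                   pixel_size_xy = 0.9, slice_thickness = 3,
                                   noise_sd = 0, rng_seed = 1L,
                                   max_migration_deg = 45) {
  if (n_fascicles < 2L) stop("n_fascicles must be >= 2")
  cx <- (width - 1) / 2
  cy <- (height - 1) / 2
  target_radius <- fascicle_radius * 2
  ring <- 2.2 * fascicle_radius
  z1 <- round(migrate_frac[1] * (depth - 1))
  z2 <- round(migrate_frac[2] * (depth - 1))
  bundles <- vector("list", n_fascicles)
  for (i in seq_len(n_fascicles)) {
    ang <- 2 * pi * (i - 1) / n_fascicles + pi / n_fascicles
    start <- c(cx + ring * cos(ang), cy + ring * sin(ang))
    qr <- 0.85 * fascicle_radius
    qoff <- c(qr * cos(ang), qr * sin(ang))
    # steepest lateral speed of the smoothstep migration (at its midpoint)
    dist_px <- sqrt(sum((start - c(cx, cy))^2))
    vmax <- 1.5 * dist_px / max(1, z2 - z1)  # px per slice
    ang_deg <- atan2(vmax * pixel_size_xy, slice_thickness) * 180 / pi
    if (ang_deg > max_migration_deg)
      stop(sprintf("migration angle %.1f deg exceeds the %.0f deg bound",
                   ang_deg, max_migration_deg))
    bundles[[i]] <- phantom_bundle("merge", roi = i, center = start,
                                   n_fibers = fibers_per_fascicle,
                                   fiber_radius = fiber_radius,
                                   fascicle_radius = fascicle_radius,
                                   target = c(cx, cy),
                                   migrate_z = c(z1, z2),
                                   target_radius = target_radius,
                                   target_offset_center = qoff)
  }
  phantom_spec(width, height, depth, bundles,
               pixel_size_xy = pixel_size_xy,
               slice_thickness = slice_thickness,
               noise_sd = noise_sd, rng_seed = rng_seed)
}
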