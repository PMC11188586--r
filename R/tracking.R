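# Streamline propagation through either flow model.
#
# Streamline points are physical micrometers: x = col * pixel_size_xy,
# y = row * pixel_size_xy, z = slice * slice_thickness (0-based voxel
# indices). One point is recorded per crossed slice plane.

#' Optic-flow provider for tracking
#'
#' Wraps a stack with pyramidal Lucas-Kanade parameters; flow fields between
#' consecutive slice pairs are computed on demand and cached, so tracking a
#' whole stack computes each pair once.
#'
#' @param stack a `virtual_stack`.
#' @param window,levels,blur_sigma see [pyramidal_flow()].
#' @return A `flow_provider` object usable with [propagate()].
#' @export
flow_provider <- function(stack, window = 50L, levels = 2L, blur_sigma = 2) {
  cache <- new.env(parent = emptyenv())
  get_pair <- function(z_from, direction) {
    key <- sprintf("%d_%d", z_from, direction)
    if (!is.null(cache[[key]])) return(cache[[key]])
    ff <- pyramidal_flow(get_slice(stack, z_from),
                         get_slice(stack, z_from + direction),
                         window, levels, blur_sigma)
    cache[[key]] <- ff
    ff
  }
  structure(list(kind = "optic-flow", stack = stack, get_pair = get_pair,
                 params = list(window = window, levels = levels,
                               blur_sigma = blur_sigma)),
            class = "flow_provider")
}

#' Structure-tensor provider for tracking
#'
#' Computes the chunked orientation field (on the near-isotropic grid when
#' `auto_isotropize` is on and the anisotropy factor is >= 2) and exposes
#' nearest-neighbor orientation lookup in physical coordinates.
#'
#' @param stack a `virtual_stack`.
#' @param sigma_n,sigma_nb,step_size see [orientation_field_chunked()].
#' @param auto_isotropize resample in XY to near-isotropic voxels first
#'   (default `TRUE`).
#' @return A `tensor_provider` object usable with [propagate()].
#' @export
tensor_provider <- function(stack, sigma_n = 1, sigma_nb = 5,
                            step_size = stack$meta$step_size,
                            auto_isotropize = TRUE) {
  grid <- if (auto_isotropize) isotropize(stack) else stack
  f <- round(grid$meta$pixel_size_xy / stack$meta$pixel_size_xy)
  field <- orientation_field_chunked(grid, sigma_n, sigma_nb, step_size)
  structure(list(kind = "structure-tensor", stack = stack, field = field,
                 pixel_size = grid$meta$pixel_size_xy,
                 # physical coordinate of the center of coarse pixel (0,0)
                 origin_um = (f - 1) / 2 * stack$meta$pixel_size_xy,
                 params = list(sigma_n = sigma_n, sigma_nb = sigma_nb,
                               step_size = step_size,
                               auto_isotropize = auto_isotropize)),
            class = "tensor_provider")
}

# Deterministic categorical palette keyed by roi_label.
roi_palette <- function(labels) {
  base <- grDevices::hcl.colors(12, "Dark 3")
  stats::setNames(base[(labels - 1L) %% 12L + 1L], labels)
}

new_tractogram <- function(streamlines, provenance) {
  labels <- sort(unique(vapply(streamlines, `[[`, integer(1), "roi_label")))
  structure(list(streamlines = streamlines, provenance = provenance,
                 colors = if (length(labels)) roi_palette(labels)
                          else character(0)),
            class = "tractogram")
}

#' @export
print.tractogram <- function(x, ...) {
  ns <- length(x$streamlines)
  npts <- sum(vapply(x$streamlines, function(s) nrow(s$points), integer(1)))
  labs <- unique(vapply(x$streamlines, `[[`, integer(1), "roi_label"))
  cat(sprintf("tractogram: %d streamlines (%d points) in %d ROI(s) [%s]\n",
              ns, npts, length(labs),
              x$provenance$algorithm %||% "unknown"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Number of streamlines in a tractogram
#' @param tract a `tractogram`.
#' @return integer count.
#' @export
n_streamlines <- function(tract) length(tract$streamlines)

#' Propagate streamlines from seeds through a flow model
#'
#' Starting at each seed, the streamline is advanced one slice plane at a
#' time. In optic-flow mode the in-plane displacement `(Vx, Vy)` is sampled
#' at the current sub-pixel position by bilinear interpolation and the step
#' is `(Vx * px, Vy * px, +/- slice_thickness)`. In structure-tensor mode
#' the orientation unit vector is sampled by nearest-neighbor lookup,
#' sign-aligned with the tracking direction and scaled so the z-step equals
#' one slice thickness. Tracking stops, with the reason recorded, when the
#' step diverges from the stack axis (the anatomical long axis of the
#' nerve) by more than `max_angle_deg`, when the point leaves the image
#' bounds, when the flow is invalid at the location (in tensor mode the
#' previous direction is reused for at most 2 consecutive slices first), or
#' when the end of the stack is reached.
#'
#' @param seeds a `seed_set` from [sample_seeds()].
#' @param provider a [flow_provider()] or [tensor_provider()].
#' @param direction `"forward"` (increasing z) or `"backward"`.
#' @param max_angle_deg termination angle in degrees, in (0, 90);
#'   default 75.
#' @return A `tractogram`; each streamline has a point matrix (x, y, z in
#'   micrometers), its seed's `roi_label`, and a `termination_reason` in
#'   `reached_end`, `angle_exceeded`, `left_image`, `left_fascicle_mask`,
#'   `invalid_flow`.
#' @export
propagate <- function(seeds, provider, direction = c("forward", "backward"),
                      max_angle_deg = 75) {
  direction <- match.arg(direction)
  if (!is.numeric(max_angle_deg) || max_angle_deg <= 0 || max_angle_deg >= 90)
    stop("max_angle_deg must lie in (0, 90)")
  stack <- provider$stack
  meta <- stack$meta
  px <- meta$pixel_size_xy
  dz <- meta$slice_thickness
  dir <- if (direction == "forward") 1L else -1L
  z0 <- attr(seeds, "z0")
  depth <- stack$depth
  if (z0 < 0L || z0 >= depth) stop("seed slice outside the stack")
  max_x <- (stack$width - 1L) * px
  max_y <- (stack$height - 1L) * px
  ns <- nrow(seeds)
  x <- seeds$col * px
  y <- seeds$row * px
  pts <- vector("list", ns)
  for (i in seq_len(ns)) pts[[i]] <- list(c(x[i], y[i], z0 * dz))
  active <- rep(TRUE, ns)
  reason <- rep(NA_character_, ns)
  streak <- rep(0L, ns)       # consecutive invalid-orientation slices bridged
  last_ux <- rep(0, ns); last_uy <- rep(0, ns); last_uz <- rep(0, ns)
  has_last <- rep(FALSE, ns)
  cos_max <- cos(max_angle_deg * pi / 180)
  tensor_mode <- inherits(provider, "tensor_provider")
  z <- z0
  while (any(active)) {
    zn <- z + dir
    if (zn < 0L || zn >= depth) {
      reason[active] <- "reached_end"
      break
    }
    idx <- which(active)
    if (tensor_mode) {
      fld <- provider$field
      pxg <- provider$pixel_size
      org <- provider$origin_um
      gr <- clamp(round_half_up((y[idx] - org) / pxg) + 1, 1, dim(fld$ux)[1])
      gc <- clamp(round_half_up((x[idx] - org) / pxg) + 1, 1, dim(fld$ux)[2])
      vox <- cbind(gr, gc, z + 1)
      ok <- fld$valid[vox]
      ux <- fld$ux[vox]; uy <- fld$uy[vox]; uz <- fld$uz[vox]
      # bridge isolated invalid voxels with the previous direction
      bridge <- !ok & has_last[idx] & streak[idx] < 2L
      ux[bridge] <- last_ux[idx][bridge]
      uy[bridge] <- last_uy[idx][bridge]
      uz[bridge] <- last_uz[idx][bridge]
      dead <- !ok & !bridge
      if (any(dead)) {
        ii <- idx[dead]
        reason[ii] <- "invalid_flow"
        active[ii] <- FALSE
      }
      keep <- !dead
      ii <- idx[keep]
      if (length(ii) == 0L) { z <- zn; next }
      ux <- ux[keep]; uy <- uy[keep]; uz <- uz[keep]
      ok <- ok[keep]
      streak[ii] <- ifelse(ok, 0L, streak[ii] + 1L)
      # canonical uz >= 0; align with the tracking direction
      sgn <- ifelse(uz * dir >= 0, 1, -1)
      ux <- ux * sgn; uy <- uy * sgn; uz <- uz * sgn
      ang_ok <- abs(uz) >= cos_max
      if (any(!ang_ok)) {
        jj <- ii[!ang_ok]
        reason[jj] <- "angle_exceeded"
        active[jj] <- FALSE
      }
      ii <- ii[ang_ok]
      if (length(ii) == 0L) { z <- zn; next }
      sc <- dz / abs(uz[ang_ok])
      dx <- ux[ang_ok] * sc * sign(uz[ang_ok]) * dir
      dy <- uy[ang_ok] * sc * sign(uz[ang_ok]) * dir
      last_ux[ii] <- ux[ang_ok]; last_uy[ii] <- uy[ang_ok]
      last_uz[ii] <- uz[ang_ok]; has_last[ii] <- TRUE
    } else {
      ff <- provider$get_pair(z, dir)
      rr <- y[idx] / px + 1
      cc <- x[idx] / px + 1
      vx <- bilinear_interp(ff$Vx, rr, cc)
      vy <- bilinear_interp(ff$Vy, rr, cc)
      vr <- clamp(round_half_up(rr), 1, nrow(ff$valid))
      vc <- clamp(round_half_up(cc), 1, ncol(ff$valid))
      ok <- ff$valid[cbind(vr, vc)]
      if (any(!ok)) {
        ii <- idx[!ok]
        reason[ii] <- "invalid_flow"
        active[ii] <- FALSE
      }
      ii <- idx[ok]
      if (length(ii) == 0L) { z <- zn; next }
      dx <- vx[ok] * px
      dy <- vy[ok] * px
      ang_ok <- dz / sqrt(dx^2 + dy^2 + dz^2) >= cos_max
      if (any(!ang_ok)) {
        jj <- ii[!ang_ok]
        reason[jj] <- "angle_exceeded"
        active[jj] <- FALSE
      }
      ii <- ii[ang_ok]
      if (length(ii) == 0L) { z <- zn; next }
      dx <- dx[ang_ok]; dy <- dy[ang_ok]
    }
    nx <- x[ii] + dx
    ny <- y[ii] + dy
    inside <- nx >= 0 & nx <= max_x & ny >= 0 & ny <= max_y
    if (any(!inside)) {
      jj <- ii[!inside]
      reason[jj] <- "left_image"
      active[jj] <- FALSE
    }
    ii <- ii[inside]
    nx <- nx[inside]; ny <- ny[inside]
    x[ii] <- nx
    y[ii] <- ny
    for (k in seq_along(ii)) {
      i <- ii[k]
      pts[[i]][[length(pts[[i]]) + 1L]] <- c(nx[k], ny[k], zn * dz)
    }
    z <- zn
  }
  streamlines <- vector("list", ns)
  for (i in seq_len(ns)) {
    streamlines[[i]] <- list(
      points = do.call(rbind, pts[[i]]),
      roi_label = as.integer(seeds$roi_label[i]),
      termination_reason = reason[i])
  }
  prov <- list(algorithm = provider$kind,
               params = provider$params,
               direction = direction,
               max_angle_deg = max_angle_deg,
               seed_slice = z0,
               density = attr(seeds, "density"),
               rng_seed = attr(seeds, "rng_seed"),
               stack = stack$source,
               pixel_size_xy = px,
               slice_thickness = dz,
               width = stack$width,
               height = stack$height,
               depth = depth)
  new_tractogram(streamlines, prov)
}

#' Per-slice mask stack
#'
#' Per-slice label images aligned with a stack: fascicle foreground for
#' anatomically constrained tracking, or ground-truth fiber-group labels
#' for evaluation.
#'
#' @param arr H x W x depth integer array of labels (0 = background).
#' @param meta the [stack_meta()] of the aligned stack.
#' @return A `mask_stack`.
#' @export
mask_stack <- function(arr, meta) {
  stopifnot(length(dim(arr)) == 3L, inherits(meta, "stack_meta"))
  structure(list(labels = arr, meta = meta), class = "mask_stack")
}

#' Read a directory of mask PNGs as a mask stack
#'
#' @param dir directory of per-slice PNG label images (lexicographic
#'   z-order; gray value = label).
#' @param meta the [stack_meta()] of the aligned stack.
#' @return A `mask_stack`.
#' @export
read_mask_stack <- function(dir, meta) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0L) stop("no mask PNGs in ", dir)
  first <- read_mask(files[1], labelled = TRUE)
  arr <- array(0L, dim = c(nrow(first), ncol(first), length(files)))
  arr[, , 1] <- first
  for (i in seq_along(files)[-1]) arr[, , i] <- read_mask(files[i],
                                                          labelled = TRUE)
  mask_stack(arr, meta)
}

# (slice, row, col) nearest-pixel lookup of streamline points, 1-based.
streamline_voxels <- function(points, meta) {
  px <- meta$pixel_size_xy
  dz <- meta$slice_thickness
  cbind(row = round_half_up(points[, 2] / px) + 1,
        col = round_half_up(points[, 1] / px) + 1,
        slice = round_half_up(points[, 3] / dz) + 1)
}

#' Constrain a tractogram to fascicle masks
#'
#' Nerve fibers never leave fascicles for the epineurium, so streamline
#' points outside the fascicle mask are anatomically impossible. In
#' `truncate` mode each streamline is cut at its last consecutive in-mask
#' point counted from the seed (termination reason `left_fascicle_mask`);
#' in `remove` mode any streamline with an out-of-mask point is deleted
#' entirely. Streamlines left with no points are dropped.
#'
#' @param tract a `tractogram`.
#' @param masks a [mask_stack()] aligned with the tractogram's stack.
#' @param mode `"truncate"` or `"remove"`.
#' @return A constrained `tractogram`.
#' @export
constrain_to_mask <- function(tract, masks, mode = c("truncate", "remove")) {
  mode <- match.arg(mode)
  stopifnot(inherits(tract, "tractogram"), inherits(masks, "mask_stack"))
  dmask <- dim(masks$labels)
  if (dmask[3] != tract$provenance$depth)
    stop("mask stack depth does not match the tractogram's stack")
  out <- list()
  for (s in tract$streamlines) {
    vox <- streamline_voxels(s$points, masks$meta)
    inb <- vox[, "row"] >= 1 & vox[, "row"] <= dmask[1] &
      vox[, "col"] >= 1 & vox[, "col"] <= dmask[2] &
      vox[, "slice"] >= 1 & vox[, "slice"] <= dmask[3]
    inm <- inb
    inm[inb] <- masks$labels[vox[inb, , drop = FALSE][, c("row", "col", "slice"),
                                                     drop = FALSE]] > 0
    if (mode == "remove") {
      if (all(inm)) out[[length(out) + 1L]] <- s
    } else {
      keep <- if (all(inm)) nrow(s$points) else which(!inm)[1] - 1L
      if (keep >= 1L) {
        s2 <- s
        s2$points <- s$points[seq_len(keep), , drop = FALSE]
        if (keep < nrow(s$points))
          s2$termination_reason <- "left_fascicle_mask"
        out[[length(out) + 1L]] <- s2
      }
    }
  }
  res <- new_tractogram(out, tract$provenance)
  res$provenance$act_mode <- mode
  res
}

# Signed polygon area (shoelace); 0 for degenerate contours.
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  if (n < 3L) return(0)
  sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y) / 2
}

#' Delete streamlines passing through a polygon on one slice
#'
#' Streamlines whose point at slice `z` falls inside the polygon are
#' removed; the number of removed streamlines is reported as attribute
#' `n_removed`. A degenerate (zero-area) polygon removes nothing.
#'
#' @param tract a `tractogram`.
#' @param polygon N x 2 matrix of (x, y) vertices in pixel coordinates
#'   (0-based, x = column).
#' @param z 0-based slice index.
#' @return The edited `tractogram`.
#' @export
edit_delete <- function(tract, polygon, z) {
  stopifnot(inherits(tract, "tractogram"))
  if (z < 0 || z >= tract$provenance$depth)
    stop("slice index outside the stack")
  if (abs(polygon_area(polygon)) == 0) {
    res <- tract
    attr(res, "n_removed") <- 0L
    return(res)
  }
  px <- tract$provenance$pixel_size_xy
  dz <- tract$provenance$slice_thickness
  keep <- vapply(tract$streamlines, function(s) {
    zi <- round_half_up(s$points[, 3] / dz)
    hit <- which(zi == z)
    if (length(hit) == 0L) return(TRUE)
    p <- s$points[hit[1], ]
    !pracma::inpolygon(p[1] / px, p[2] / px, polygon[, 1], polygon[, 2],
                       boundary = TRUE)
  }, logical(1))
  res <- new_tractogram(tract$streamlines[keep], tract$provenance)
  attr(res, "n_removed") <- sum(!keep)
  res
}

# Rasterize a polygon (pixel coordinates, 0-based) to a binary mask.
rasterize_polygon <- function(polygon, height, width) {
  mask <- matrix(0L, height, width)
  if (abs(polygon_area(polygon)) == 0) return(mask)
  gc <- rep(0:(width - 1L), each = height)
  gr <- rep(0:(height - 1L), times = width)
  inside <- pracma::inpolygon(gc, gr, polygon[, 1], polygon[, 2],
                              boundary = TRUE)
  mask[cbind(gr + 1L, gc + 1L)[inside, , drop = FALSE]] <- 1L
  mask
}

#' Create new streamlines from a polygon on one slice
#'
#' The polygon is rasterized to a mask on slice `z`, seeded with the same
#' deterministic machinery as [sample_seeds()], propagated, and the new
#' streamlines are appended under a fresh ROI label. An empty (zero-area)
#' polygon is a no-op.
#'
#' @param tract a `tractogram`.
#' @param polygon N x 2 matrix of (x, y) vertices in pixel coordinates
#'   (0-based).
#' @param z 0-based slice index to seed on.
#' @param density,rng_seed see [sample_seeds()].
#' @param provider,direction,max_angle_deg see [propagate()].
#' @return The extended `tractogram`.
#' @export
edit_create <- function(tract, polygon, z, density, rng_seed, provider,
                        direction = "forward", max_angle_deg = 75) {
  stopifnot(inherits(tract, "tractogram"))
  if (z < 0 || z >= tract$provenance$depth)
    stop("slice index outside the stack")
  mask <- rasterize_polygon(polygon, tract$provenance$height,
                            tract$provenance$width)
  if (!any(mask > 0)) return(tract)
  labs <- vapply(tract$streamlines, `[[`, integer(1), "roi_label")
  fresh <- if (length(labs)) max(labs) + 1L else 1L
  # seed with label 1 (so the polygon reproduces an original ROI-1 selection
  # under the same rng_seed), then relabel the new streamlines
  seeds <- sample_seeds(mask, density, rng_seed, z)
  extra <- propagate(seeds, provider, direction, max_angle_deg)
  extra$streamlines <- lapply(extra$streamlines, function(s) {
    s$roi_label <- fresh
    s
  })
  new_tractogram(c(tract$streamlines, extra$streamlines), tract$provenance)
}
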