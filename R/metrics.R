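# Tractogram evaluation: normalized Dice overlap against ground-truth
# fiber-group masks, and a mean closest-neighbor distance between two
# tractograms computed over QuickBundles-style cluster centroids.

#' Rasterize a tractogram's points on one slice into a binary mask
#'
#' Every streamline of the given ROI that has a point at slice `z`
#' contributes its nearest pixel to the foreground (point cloud to mask
#' conversion).
#'
#' @param tract a `tractogram`.
#' @param z 0-based slice index.
#' @param roi_label ROI whose streamlines to rasterize.
#' @param height,width mask dimensions; defaults from the tractogram's
#'   provenance.
#' @return binary matrix (0/1).
#' @export
rasterize_tract_slice <- function(tract, z, roi_label,
                                  height = tract$provenance$height,
                                  width = tract$provenance$width) {
  stopifnot(inherits(tract, "tractogram"))
  labs <- vapply(tract$streamlines, `[[`, integer(1), "roi_label")
  if (!roi_label %in% labs) stop("unknown roi_label: ", roi_label)
  px <- tract$provenance$pixel_size_xy
  dz <- tract$provenance$slice_thickness
  mask <- matrix(0L, height, width)
  for (s in tract$streamlines[labs == roi_label]) {
    zi <- round_half_up(s$points[, 3] / dz)
    hit <- which(zi == z)
    if (length(hit) == 0L) next
    p <- s$points[hit[1], ]
    r <- round_half_up(p[2] / px) + 1
    c <- round_half_up(p[1] / px) + 1
    if (r >= 1 && r <= height && c >= 1 && c <= width) mask[r, c] <- 1L
  }
  mask
}

#' Dice overlap between two binary masks
#'
#' `2 |A n B| / (|A| + |B|)`. Both masks empty is an error (the metric is
#' undefined and usually indicates an evaluation mistake).
#'
#' @param a,b equal-shaped binary matrices.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  na <- sum(a > 0)
  nb <- sum(b > 0)
  if (na + nb == 0L) stop("Dice undefined: both masks are empty")
  2 * sum(a > 0 & b > 0) / (na + nb)
}

#' Normalized Dice overlap of a tractogram against ground truth
#'
#' The Dice overlap between the rasterized tractogram points and the
#' ground-truth mask of one ROI at slice `z`, normalized by the same
#' overlap at the seeding slice `z0`. Normalization removes the dependence
#' of the raw Dice value on seed density, so the metric measures how well
#' tracking follows the fiber group rather than how densely it was seeded;
#' `z = z0` gives 1 by construction.
#'
#' @param tract a `tractogram`.
#' @param gt a [mask_stack()] of ground-truth fiber-group labels whose
#'   positive values match the tractogram's ROI labels.
#' @param roi_label ROI to evaluate.
#' @param z 0-based evaluation slice.
#' @param z0 0-based seeding slice.
#' @return normalized Dice value (>= 0; 1 means overlap as good as at the
#'   seed slice).
#' @export
dice_norm <- function(tract, gt, roi_label, z, z0) {
  stopifnot(inherits(gt, "mask_stack"))
  gmask_z <- gt$labels[, , z + 1L] == roi_label
  gmask_z0 <- gt$labels[, , z0 + 1L] == roi_label
  h <- dim(gt$labels)[1]
  w <- dim(gt$labels)[2]
  d0 <- dice(rasterize_tract_slice(tract, z0, roi_label, h, w), gmask_z0)
  if (d0 == 0) stop("Dice at the seeding slice is zero; Dice_norm undefined")
  dz <- dice(rasterize_tract_slice(tract, z, roi_label, h, w), gmask_z)
  dz / d0
}

#' Resample a streamline to a fixed number of points
#'
#' Arc-length-uniform resampling by linear interpolation; the endpoints are
#' preserved exactly.
#'
#' @param points N x 3 point matrix (N >= 2).
#' @param K target point count (>= 2).
#' @return K x 3 matrix.
#' @export
resample_streamline <- function(points, K = 12L) {
  if (is.list(points) && !is.null(points$points)) points <- points$points
  if (!is.matrix(points) || nrow(points) < 2L)
    stop("streamline must have at least 2 points")
  K <- as.integer(K)
  if (K < 2L) stop("K must be >= 2")
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                         points[-nrow(points), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total == 0) return(matrix(points[1, ], K, 3, byrow = TRUE))
  target <- seq(0, total, length.out = K)
  out <- matrix(0, K, 3)
  for (j in 1:3)
    out[, j] <- stats::approx(s, points[, j], xout = target, ties = "ordered",
                              rule = 2)$y
  out[1, ] <- points[1, ]
  out[K, ] <- points[nrow(points), ]
  out
}

# Minimum direct-flip distance between two K x 3 resampled streamlines:
# the mean point-to-point Euclidean distance, minimized over traversal
# direction.
mdf_distance <- function(a, b) {
  direct <- mean(sqrt(rowSums((a - b)^2)))
  flipped <- mean(sqrt(rowSums((a - b[nrow(b):1, , drop = FALSE])^2)))
  min(direct, flipped)
}

#' QuickBundles-style streamline clustering
#'
#' Streamlines are processed in stored order, each resampled to `K` points.
#' A streamline joins the nearest existing cluster if its
#' minimum-direct-flip (MDF) distance to the cluster centroid is at most
#' `theta`, otherwise it opens a new cluster; the centroid is the running
#' mean of the flip-aligned member point arrays. Clustering is performed
#' independently per ROI label; clusters never mix ROIs.
#'
#' @param tract a `tractogram`.
#' @param theta clustering threshold in micrometers (default 50).
#' @param K resample point count (default 12).
#' @return A `cluster_set`: list of clusters, each with `centroid`
#'   (K x 3 matrix), `members` (streamline indices into the tractogram)
#'   and `roi_label`.
#' @export
quickbundles <- function(tract, theta = 50, K = 12L) {
  stopifnot(inherits(tract, "tractogram"))
  if (theta <= 0) stop("theta must be positive")
  clusters <- list()
  labs <- vapply(tract$streamlines, `[[`, integer(1), "roi_label")
  usable <- which(vapply(tract$streamlines,
                         function(s) nrow(s$points) >= 2L, logical(1)))
  for (l in sort(unique(labs[usable]))) {
    idx <- usable[labs[usable] == l]
    lcl <- list()  # each: sum (K x 3), n, members
    for (i in idx) {
      r <- resample_streamline(tract$streamlines[[i]]$points, K)
      best <- 0L
      best_d <- Inf
      best_flip <- FALSE
      for (ci in seq_along(lcl)) {
        cen <- lcl[[ci]]$sum / lcl[[ci]]$n
        direct <- mean(sqrt(rowSums((r - cen)^2)))
        flipped <- mean(sqrt(rowSums((r[K:1, , drop = FALSE] - cen)^2)))
        d <- min(direct, flipped)
        if (d < best_d) {
          best_d <- d
          best <- ci
          best_flip <- flipped < direct
        }
      }
      if (best > 0L && best_d <= theta) {
        radd <- if (best_flip) r[K:1, , drop = FALSE] else r
        lcl[[best]]$sum <- lcl[[best]]$sum + radd
        lcl[[best]]$n <- lcl[[best]]$n + 1L
        lcl[[best]]$members <- c(lcl[[best]]$members, i)
      } else {
        lcl[[length(lcl) + 1L]] <- list(sum = r, n = 1L, members = i)
      }
    }
    for (cl in lcl)
      clusters[[length(clusters) + 1L]] <-
        list(centroid = cl$sum / cl$n, members = cl$members, roi_label = l)
  }
  structure(list(clusters = clusters, theta = theta, K = K),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d clusters (theta %g um, K %d)\n",
              length(x$clusters), x$theta, x$K))
  invisible(x)
}

#' Mean closest-neighbor distance between two tractograms
#'
#' Both tractograms are reduced to QuickBundles cluster centroids; for each
#' centroid of A the MDF distance to the closest same-ROI centroid of B is
#' recorded, the mean over A's centroids gives `dist(A->B)`, and the
#' reported metric is the symmetrized mean
#' `(dist(A->B) + dist(B->A)) / 2` in micrometers. ROIs present in only
#' one tractogram are skipped with a warning.
#'
#' @param tract_a,tract_b `tractogram`s with matching ROI label semantics.
#' @param theta clustering threshold in micrometers (default 50).
#' @param K resample point count (default 12).
#' @return MCN distance in micrometers.
#' @export
mcn_dist <- function(tract_a, tract_b, theta = 50, K = 12L) {
  ca <- quickbundles(tract_a, theta, K)
  cb <- quickbundles(tract_b, theta, K)
  labs_a <- unique(vapply(ca$clusters, `[[`, integer(1), "roi_label"))
  labs_b <- unique(vapply(cb$clusters, `[[`, integer(1), "roi_label"))
  shared <- intersect(labs_a, labs_b)
  if (length(shared) == 0L) stop("tractograms share no ROI labels")
  only <- union(setdiff(labs_a, labs_b), setdiff(labs_b, labs_a))
  if (length(only))
    warning("ROI label(s) present in only one tractogram skipped: ",
            paste(only, collapse = ", "))
  one_way <- function(from, to) {
    ds <- c()
    for (cl in from$clusters) {
      if (!cl$roi_label %in% shared) next
      cand <- Filter(function(x) x$roi_label == cl$roi_label, to$clusters)
      ds <- c(ds, min(vapply(cand,
                             function(x) mdf_distance(cl$centroid, x$centroid),
                             numeric(1))))
    }
    mean(ds)
  }
  (one_way(ca, cb) + one_way(cb, ca)) / 2
}
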