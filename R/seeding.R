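#' Label connected regions of interest in a binary seed mask
#'
#' Connected-components labelling with 8-connectivity. Components are
#' numbered 1..K in order of their first-encountered pixel in a row-major
#' scan (row 1 left to right, then row 2, ...), so labels are stable for a
#' given mask.
#'
#' @param mask matrix; pixels > 0 are foreground.
#' @return integer matrix of the same shape, 0 = background, k = component k.
#' @export
label_rois <- function(mask) {
  stopifnot(is.matrix(mask))
  fg <- mask > 0
  if (!any(fg)) stop("seed mask has no foreground pixels")
  nr <- nrow(fg)
  nc <- ncol(fg)
  labels <- matrix(0L, nr, nc)
  dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  k <- 0L
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (!fg[r, c] || labels[r, c] != 0L) next
      k <- k + 1L
      # BFS flood fill
      queue <- matrix(c(r, c), ncol = 2)
      labels[r, c] <- k
      head <- 1L
      while (head <= nrow(queue)) {
        p <- queue[head, ]
        head <- head + 1L
        nrw <- p[1] + dr
        ncl <- p[2] + dc
        ok <- nrw >= 1L & nrw <= nr & ncl >= 1L & ncl <= nc
        nrw <- nrw[ok]; ncl <- ncl[ok]
        idx <- cbind(nrw, ncl)
        hit <- fg[idx] & labels[idx] == 0L
        if (any(hit)) {
          idx <- idx[hit, , drop = FALSE]
          labels[idx] <- k
          queue <- rbind(queue, idx)
        }
      }
    }
  }
  labels
}

#' Sample deterministic, ROI-labelled seed points from a label image
#'
#' For each component, foreground pixels are enumerated in row-major order,
#' permuted with a seeded pseudorandom generator (re-seeded per component
#' with `rng_seed + label`, so editing one ROI never perturbs seeds of the
#' others), and the first `max(1, floor(count * density))` pixels are taken.
#' The default density of 0.01 corresponds to 1 seed per 100 pixels; density
#' 1 seeds every foreground pixel.
#'
#' @param labels integer label matrix from [label_rois()] (or any label
#'   image whose positive values identify ROIs).
#' @param density seeds per pixel, in (0, 1].
#' @param rng_seed integer seed; identical inputs always yield the identical
#'   ordered seed list.
#' @param z0 0-based index of the slice the mask belongs to.
#' @return A `seed_set`: data frame with columns `row`, `col` (0-based pixel
#'   coordinates) and `roi_label`, with attributes `z0`, `density`,
#'   `rng_seed`.
#' @export
sample_seeds <- function(labels, density = 0.01, rng_seed = 42L, z0 = 0L) {
  stopifnot(is.matrix(labels))
  if (!is.numeric(density) || length(density) != 1L || is.na(density) ||
      density <= 0 || density > 1)
    stop("density must lie in (0, 1]")
  labs <- sort(unique(labels[labels > 0]))
  if (length(labs) == 0L) stop("label image has no foreground")
  out <- vector("list", length(labs))
  for (i in seq_along(labs)) {
    l <- labs[i]
    idx <- which(t(labels) == l)  # row-major enumeration
    nc <- ncol(labels)
    rows <- (idx - 1L) %/% nc     # 0-based
    cols <- (idx - 1L) %% nc
    n <- length(idx)
    take <- max(1L, floor(n * density))
    perm <- with_seed(rng_seed + l, sample.int(n))
    sel <- perm[seq_len(take)]
    out[[i]] <- data.frame(row = rows[sel], col = cols[sel],
                           roi_label = as.integer(l))
  }
  seeds <- do.call(rbind, out)
  structure(seeds, z0 = as.integer(z0), density = density,
            rng_seed = as.integer(rng_seed),
            class = c("seed_set", "data.frame"))
}

#' @export
print.seed_set <- function(x, ...) {
  cat(sprintf("seed_set: %d seeds in %d ROI(s) on slice %d (density %g)\n",
              nrow(x), length(unique(x$roi_label)), attr(x, "z0"),
              attr(x, "density")))
  invisible(x)
}

#' Read a seed mask image
#'
#' @param path PNG file; 0 = background. With `labelled = FALSE` (default)
#'   any positive value is foreground and components are found with
#'   [label_rois()]; with `labelled = TRUE` distinct gray values are taken as
#'   distinct ROI labels directly.
#' @param labelled whether the mask is pre-labelled.
#' @return integer label matrix.
#' @export
read_mask <- function(path, labelled = FALSE) {
  img <- png::readPNG(path)
  img <- to_grayscale(round_half_up(img * 255))
  if (labelled) matrix(as.integer(img), nrow(img), ncol(img))
  else label_rois(img)
}
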