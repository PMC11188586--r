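# Lucas-Kanade optic flow between consecutive slices.
#
# Image convention: matrices with rows = y, columns = x. Flow Vx is along
# columns (x), Vy along rows (y), in pixels, describing the in-plane motion
# of image content from slice_a to slice_b: a(x) ~ b(x + V(x)).

#' Spatial and inter-slice gradients for optic flow
#'
#' Both slices are blurred with a Gaussian of standard deviation
#' `blur_sigma` (reflect boundary) to suppress noise in the gradient
#' computation; `Ix`, `Iy` are central differences on the blurred first
#' slice and `Iz` is the blurred difference `slice_b - slice_a`.
#'
#' @param slice_a,slice_b equal-shaped grayscale matrices.
#' @param blur_sigma Gaussian standard deviation in pixels (default 2).
#' @return list with matrices `Ix`, `Iy`, `Iz` (class `gradient_triple`).
#' @export
compute_gradients <- function(slice_a, slice_b, blur_sigma = 2) {
  if (!identical(dim(slice_a), dim(slice_b)))
    stop("slice shapes differ")
  a <- gauss_blur_2d(slice_a, blur_sigma)
  b <- gauss_blur_2d(slice_b, blur_sigma)
  cd <- central_diff_kernel()
  structure(list(Ix = filter_axis(a, cd, 2L),
                 Iy = filter_axis(a, cd, 1L),
                 Iz = b - a),
            class = "gradient_triple")
}

#' Dense single-level Lucas-Kanade flow
#'
#' At each pixel the brightness-constancy equation
#' `Ix Vx + Iy Vy = -Iz` is assumed to hold with constant flow over an
#' n x n window, giving an overdetermined system of n^2 equations in two
#' unknowns, solved by least squares through the 2 x 2 normal equations.
#' Pixels where the normal matrix is near-singular (aperture problem; its
#' smaller eigenvalue below `1e-4 * n^2`) are marked invalid and given zero
#' flow.
#'
#' @param gradients a `gradient_triple` from [compute_gradients()].
#' @param window window side n in pixels (even values are incremented to
#'   center the window; minimum 3).
#' @return A `flow_field`: list with matrices `Vx`, `Vy`, logical `valid`,
#'   and the window actually used.
#' @export
lucas_kanade <- function(gradients, window = 50L) {
  stopifnot(inherits(gradients, "gradient_triple"))
  n <- as.integer(window)
  if (n %% 2L == 0L) n <- n + 1L
  if (n < 3L) stop("window must be >= 3 pixels")
  Ix <- gradients$Ix
  Iy <- gradients$Iy
  Iz <- gradients$Iz
  A11 <- box_sum_2d(Ix * Ix, n)
  A12 <- box_sum_2d(Ix * Iy, n)
  A22 <- box_sum_2d(Iy * Iy, n)
  b1 <- -box_sum_2d(Ix * Iz, n)
  b2 <- -box_sum_2d(Iy * Iz, n)
  tr <- A11 + A22
  disc <- sqrt(pmax((A11 - A22)^2 + 4 * A12^2, 0))
  lam_min <- (tr - disc) / 2
  valid <- lam_min >= 1e-4 * n^2
  det <- A11 * A22 - A12^2
  det[!valid] <- 1  # avoid 0/0; flow zeroed below
  Vx <- (A22 * b1 - A12 * b2) / det
  Vy <- (A11 * b2 - A12 * b1) / det
  Vx[!valid] <- 0
  Vy[!valid] <- 0
  structure(list(Vx = Vx, Vy = Vy, valid = valid, window = n),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("flow_field: %d x %d, window %d, %.1f%% valid\n",
              nrow(x$Vx), ncol(x$Vx), x$window, 100 * mean(x$valid)))
  invisible(x)
}

# Warp slice_b toward slice_a by the current flow estimate:
# b_w(x) = b(x + v(x)), bilinear, replicated borders.
warp_by_flow <- function(img, Vx, Vy) {
  nr <- nrow(img)
  nc <- ncol(img)
  grid_r <- matrix(seq_len(nr), nr, nc)
  grid_c <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  matrix(bilinear_interp(img, as.vector(grid_r + Vy), as.vector(grid_c + Vx)),
         nr, nc)
}

#' Coarse-to-fine pyramidal Lucas-Kanade flow
#'
#' Images are downsampled by factors of two into an `levels`-deep pyramid.
#' Flow is estimated at the coarsest level, upsampled (and doubled) to the
#' next level, used to warp `slice_b` toward `slice_a`, and refined with a
#' residual Lucas-Kanade estimate; the accumulated flow at the finest level
#' is returned. `levels = 1` reduces to [lucas_kanade()]. If the coarsest
#' level would be smaller than twice the window per side, the number of
#' levels is reduced with a warning.
#'
#' @param slice_a,slice_b equal-shaped grayscale matrices.
#' @param window Lucas-Kanade window in pixels (default 50).
#' @param levels pyramid depth (default 2).
#' @param blur_sigma Gaussian blur applied before gradient computation at
#'   each level (default 2 pixels).
#' @return A `flow_field` at the resolution of the input slices.
#' @export
pyramidal_flow <- function(slice_a, slice_b, window = 50L, levels = 2L,
                           blur_sigma = 2) {
  if (!identical(dim(slice_a), dim(slice_b))) stop("slice shapes differ")
  n <- as.integer(window)
  if (n %% 2L == 0L) n <- n + 1L
  levels <- as.integer(levels)
  if (levels < 1L) stop("levels must be >= 1")
  min_side <- min(dim(slice_a))
  max_levels <- max(1L, 1L + floor(log2(min_side / (2 * n))))
  if (levels > max_levels) {
    warning(sprintf("reducing pyramid levels from %d to %d for a %d-px image",
                    levels, max_levels, min_side))
    levels <- max_levels
  }
  pyr_a <- vector("list", levels)
  pyr_b <- vector("list", levels)
  pyr_a[[1]] <- slice_a
  pyr_b[[1]] <- slice_b
  if (levels > 1L) for (l in 2:levels) {
    pyr_a[[l]] <- block_downsample(pyr_a[[l - 1]], 2L)
    pyr_b[[l]] <- block_downsample(pyr_b[[l - 1]], 2L)
  }
  Vx <- NULL
  Vy <- NULL
  valid <- NULL
  for (l in seq(levels, 1L)) {
    a <- pyr_a[[l]]
    b <- pyr_b[[l]]
    if (is.null(Vx)) {
      Vx <- matrix(0, nrow(a), ncol(a))
      Vy <- matrix(0, nrow(a), ncol(a))
    } else {
      Vx <- 2 * resize_bilinear(Vx, nrow(a), ncol(a))
      Vy <- 2 * resize_bilinear(Vy, nrow(a), ncol(a))
    }
    b_w <- warp_by_flow(b, Vx, Vy)
    res <- lucas_kanade(compute_gradients(a, b_w, blur_sigma), n)
    Vx <- Vx + res$Vx
    Vy <- Vy + res$Vy
    valid <- res$valid
  }
  structure(list(Vx = Vx, Vy = Vy, valid = valid, window = n),
            class = "flow_field")
}
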