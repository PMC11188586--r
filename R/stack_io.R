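#' Stack metadata
#'
#' Physical calibration and reading parameters of a serial block-face stack.
#' Values normally come from the stack's XML metadata file (see
#' [load_metadata()]), but a `stack_meta` can also be built directly, e.g. for
#' synthetic phantoms.
#'
#' @param pixel_size_xy in-plane pixel size in micrometers (> 0).
#' @param slice_thickness distance between consecutive slices in micrometers
#'   (> 0).
#' @param image_type file suffix of the slice images, e.g. `".png"`.
#' @param num_images_to_read number of slices to load (>= 2).
#' @param step_size slices per processing chunk for the structure-tensor
#'   analysis (>= 1).
#' @return An object of class `stack_meta`.
#' @export
stack_meta <- function(pixel_size_xy, slice_thickness, image_type = ".png",
                       num_images_to_read = 2L, step_size = 64L) {
  pixel_size_xy <- as.numeric(pixel_size_xy)
  slice_thickness <- as.numeric(slice_thickness)
  num_images_to_read <- as.integer(num_images_to_read)
  step_size <- as.integer(step_size)
  if (!is.finite(pixel_size_xy) || pixel_size_xy <= 0)
    stop("pixel_size_xy must be a positive number")
  if (!is.finite(slice_thickness) || slice_thickness <= 0)
    stop("slice_thickness must be a positive number")
  if (is.na(num_images_to_read) || num_images_to_read < 2L)
    stop("num_images_to_read must be >= 2")
  if (is.na(step_size) || step_size < 1L)
    stop("step_size must be >= 1")
  structure(list(pixel_size_xy = pixel_size_xy,
                 slice_thickness = slice_thickness,
                 image_type = as.character(image_type),
                 num_images_to_read = num_images_to_read,
                 step_size = step_size),
            class = "stack_meta")
}

#' @export
print.stack_meta <- function(x, ...) {
  cat(sprintf(
    "stack_meta: %g um/px, %g um slices, %d images (%s), step_size %d\n",
    x$pixel_size_xy, x$slice_thickness, x$num_images_to_read,
    x$image_type, x$step_size))
  invisible(x)
}

#' Read stack metadata from an XML file
#'
#' Parses the metadata dialect used alongside block-face PNG stacks: a root
#' element whose children carry their value in a `name` attribute, e.g.
#' `<pixel_size_xy name="0.9"/>`. The five required fields are
#' `pixel_size_xy`, `image_slice_thickness`, `image_type`,
#' `num_images_to_read` and `step_size`; extra elements are ignored.
#'
#' @param xml_path path to the XML metadata file.
#' @return A [stack_meta()] object.
#' @export
load_metadata <- function(xml_path) {
  if (!file.exists(xml_path)) stop("metadata file not found: ", xml_path)
  doc <- xml2::read_xml(xml_path)
  get_field <- function(name) {
    node <- xml2::xml_find_first(doc, paste0("./", name))
    if (inherits(node, "xml_missing"))
      stop("metadata field missing: ", name)
    val <- xml2::xml_attr(node, "name")
    if (is.na(val)) stop("metadata field missing: ", name)
    val
  }
  num_field <- function(name) {
    v <- suppressWarnings(as.numeric(get_field(name)))
    if (is.na(v)) stop("metadata field not numeric: ", name)
    v
  }
  stack_meta(pixel_size_xy = num_field("pixel_size_xy"),
             slice_thickness = num_field("image_slice_thickness"),
             image_type = get_field("image_type"),
             num_images_to_read = num_field("num_images_to_read"),
             step_size = num_field("step_size"))
}

#' Write stack metadata to an XML file
#'
#' Inverse of [load_metadata()]; writes the `name`-attribute dialect.
#'
#' @param meta a [stack_meta()] object.
#' @param xml_path output path.
#' @return `xml_path`, invisibly.
#' @export
write_metadata <- function(meta, xml_path) {
  stopifnot(inherits(meta, "stack_meta"))
  lines <- c(
    "<?xml version=\"1.0\"?>",
    "<root>",
    sprintf("  <pixel_size_xy name=\"%g\"/>", meta$pixel_size_xy),
    sprintf("  <image_slice_thickness name=\"%g\"/>", meta$slice_thickness),
    sprintf("  <image_type name=\"%s\"/>", meta$image_type),
    sprintf("  <num_images_to_read name=\"%d\"/>", meta$num_images_to_read),
    sprintf("  <step_size name=\"%d\"/>", meta$step_size),
    "</root>")
  writeLines(lines, xml_path)
  invisible(xml_path)
}

#' Convert an RGB slice to grayscale
#'
#' Weighted sum of the red and green channels (50:50); the blue channel is
#' ignored. Output values are rounded half-up and clipped to \[0, 255\].
#' Single-channel input passes through unchanged.
#'
#' @param img matrix (grayscale, 0-255) or H x W x 3 array (0-255 per
#'   channel).
#' @return grayscale matrix with integer values in \[0, 255\].
#' @export
to_grayscale <- function(img) {
  if (is.matrix(img)) return(img)
  if (length(dim(img)) == 3L && dim(img)[3] >= 2L) {
    g <- 0.5 * img[, , 1] + 0.5 * img[, , 2]
    return(clamp(round_half_up(g), 0, 255))
  }
  if (length(dim(img)) == 3L && dim(img)[3] == 1L) return(img[, , 1])
  stop("expected a matrix or an H x W x 3 array")
}

#' Gamma-correct a grayscale slice
#'
#' `out = round(255 * (in / 255)^gamma)`, monotone in the input intensity.
#'
#' @param img grayscale matrix, values in \[0, 255\].
#' @param gamma positive exponent; `1` is the identity.
#' @return corrected matrix, integer values in \[0, 255\].
#' @export
gamma_correct <- function(img, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) ||
      gamma <= 0)
    stop("gamma must be a positive number")
  clamp(round_half_up(255 * (img / 255)^gamma), 0, 255)
}

# Internal constructor: a virtual stack is a reader closure plus metadata and
# a bounded FIFO cache of decoded slices.
new_virtual_stack <- function(reader, meta, depth, height, width,
                              source = NA_character_, cache_size = 8L) {
  env <- new.env(parent = emptyenv())
  env$cache <- new.env(parent = emptyenv())
  env$order <- character(0)
  structure(list(reader = reader, meta = meta, depth = as.integer(depth),
                 height = as.integer(height), width = as.integer(width),
                 source = source, cache_size = as.integer(cache_size),
                 state = env),
            class = "virtual_stack")
}

#' Open a directory of slice images as a virtual stack
#'
#' Slices are decoded lazily: at most `cache_size` decoded slices are held in
#' memory at any time, so stacks larger than RAM can be traversed. Slice order
#' is the ascending lexicographic order of filenames. All slices must share
#' the same height and width; RGB slices are converted to grayscale on read
#' (50:50 red/green).
#'
#' @param dir directory containing the slice images.
#' @param meta a [stack_meta()]; `meta$num_images_to_read` slices of type
#'   `meta$image_type` are exposed.
#' @param cache_size maximum number of decoded slices resident at once.
#' @param validate if `TRUE` (default) every slice is decoded once at open
#'   time to verify consistent dimensions.
#' @return A `virtual_stack`; read pixels with [get_slice()].
#' @export
open_stack <- function(dir, meta, cache_size = 8L, validate = TRUE) {
  stopifnot(inherits(meta, "stack_meta"))
  if (!dir.exists(dir)) stop("stack directory not found: ", dir)
  pat <- paste0("\\", meta$image_type, "$")
  files <- sort(list.files(dir, pattern = pat, full.names = TRUE))
  if (length(files) == 0L) stop("no ", meta$image_type, " slices in ", dir)
  if (length(files) < meta$num_images_to_read)
    stop(sprintf("num_images_to_read = %d but only %d slice files present",
                 meta$num_images_to_read, length(files)))
  files <- files[seq_len(meta$num_images_to_read)]
  read_file <- function(path) {
    img <- png::readPNG(path)
    to_grayscale(round_half_up(img * 255))
  }
  first <- read_file(files[1])
  if (validate && length(files) > 1L) {
    for (f in files[-1]) {
      img <- read_file(f)
      if (nrow(img) != nrow(first) || ncol(img) != ncol(first))
        stop("slice dimensions differ from the first slice: ", f)
    }
  }
  reader <- function(z) read_file(files[z + 1L])
  new_virtual_stack(reader, meta, depth = length(files),
                    height = nrow(first), width = ncol(first),
                    source = normalizePath(dir), cache_size = cache_size)
}

#' Build a virtual stack from an in-memory 3D array
#'
#' Convenience for phantoms and tests; shares the [get_slice()] interface
#' with [open_stack()].
#'
#' @param vol H x W x depth numeric array (grayscale intensities, 0-255).
#' @param meta a [stack_meta()] describing the calibration.
#' @return A `virtual_stack`.
#' @export
array_stack <- function(vol, meta) {
  stopifnot(length(dim(vol)) == 3L, inherits(meta, "stack_meta"))
  new_virtual_stack(function(z) vol[, , z + 1L], meta,
                    depth = dim(vol)[3], height = dim(vol)[1],
                    width = dim(vol)[2], source = "<array>",
                    cache_size = dim(vol)[3])
}

#' Read one slice from a virtual stack
#'
#' @param stack a `virtual_stack`.
#' @param z 0-based slice index in `[0, depth(stack))`.
#' @return grayscale matrix (rows = y, columns = x), values in \[0, 255\].
#' @export
get_slice <- function(stack, z) {
  stopifnot(inherits(stack, "virtual_stack"))
  z <- as.integer(z)
  if (is.na(z) || z < 0L || z >= stack$depth)
    stop("slice index out of range: ", z)
  key <- as.character(z)
  env <- stack$state
  if (!is.null(env$cache[[key]])) return(env$cache[[key]])
  img <- stack$reader(z)
  env$cache[[key]] <- img
  env$order <- c(env$order, key)
  while (length(env$order) > stack$cache_size) {
    rm(list = env$order[1], envir = env$cache)
    env$order <- env$order[-1]
  }
  img
}

#' @export
print.virtual_stack <- function(x, ...) {
  cat(sprintf("virtual_stack: %d x %d x %d (H x W x slices), %g um/px, %g um/slice\n",
              x$height, x$width, x$depth, x$meta$pixel_size_xy,
              x$meta$slice_thickness))
  invisible(x)
}

#' Stack depth (number of slices)
#' @param stack a `virtual_stack`.
#' @return integer slice count.
#' @export
stack_depth <- function(stack) stack$depth

#' Materialize a virtual stack (or a range of it) as a 3D array
#'
#' @param stack a `virtual_stack`.
#' @param z_range 0-based inclusive slice range, default the whole stack.
#' @return H x W x depth numeric array.
#' @export
as_volume <- function(stack, z_range = c(0L, stack$depth - 1L)) {
  zs <- seq.int(z_range[1], z_range[2])
  vol <- array(0, dim = c(stack$height, stack$width, length(zs)))
  for (i in seq_along(zs)) vol[, , i] <- get_slice(stack, zs[i])
  vol
}

#' Downsample a stack in-plane and/or along z
#'
#' In-plane (XY) downsampling is block averaging by an integer factor;
#' z-downsampling keeps every `z_keep_every`-th slice (those with
#' `z mod z_keep_every == 0`). Metadata is rescaled accordingly, so a 3 um
#' stack thinned by 2 becomes a 6 um stack. Used for downsampling-robustness
#' experiments and for near-isotropic resampling before structure-tensor
#' analysis.
#'
#' @param stack a `virtual_stack`.
#' @param xy_factor integer >= 1, in-plane block size.
#' @param z_keep_every integer >= 1, keep every this-many-th slice.
#' @return A derived `virtual_stack` (still lazy).
#' @export
downsample_stack <- function(stack, xy_factor = 1L, z_keep_every = 1L) {
  stopifnot(inherits(stack, "virtual_stack"))
  xy_factor <- as.integer(xy_factor)
  z_keep_every <- as.integer(z_keep_every)
  if (xy_factor < 1L || z_keep_every < 1L)
    stop("downsampling factors must be positive integers")
  if (xy_factor == 1L && z_keep_every == 1L) return(stack)
  new_depth <- (stack$depth - 1L) %/% z_keep_every + 1L
  if (new_depth < 2L) stop("downsampled stack would have fewer than 2 slices")
  new_h <- as.integer(ceiling(stack$height / xy_factor))
  new_w <- as.integer(ceiling(stack$width / xy_factor))
  meta <- stack_meta(stack$meta$pixel_size_xy * xy_factor,
                     stack$meta$slice_thickness * z_keep_every,
                     stack$meta$image_type, new_depth, stack$meta$step_size)
  parent <- stack
  reader <- function(z) {
    img <- get_slice(parent, z * z_keep_every)
    if (xy_factor > 1L) img <- block_downsample(img, xy_factor)
    img
  }
  new_virtual_stack(reader, meta, depth = new_depth, height = new_h,
                    width = new_w,
                    source = paste0(parent$source, sprintf("[xy/%d,z/%d]",
                                                           xy_factor, z_keep_every)),
                    cache_size = parent$cache_size)
}
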