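# Tractogram file formats: a JSON-lines text format (lossless, bit-exact
# round trip) and TrackVis .trk export for viewing in standard diffusion
# tractography tools.

#' Write a tractogram as JSON lines
#'
#' Line 1 is a provenance record (`{"provenance": ...}`); every following
#' line is one streamline: `roi_label`, `termination_reason`, and the
#' (x, y, z) point triplets in micrometers. Numbers are serialized at full
#' precision, so [read_tractogram_jsonl()] round-trips bit-exactly.
#'
#' @param tract a `tractogram`.
#' @param path output file (conventionally `.jsonl`).
#' @return `path`, invisibly.
#' @export
write_tractogram_jsonl <- function(tract, path) {
  stopifnot(inherits(tract, "tractogram"))
  con <- file(path, open = "w")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(list(provenance = tract$provenance),
                              auto_unbox = TRUE, digits = NA, null = "null"),
             con)
  # points are serialized at 17 significant digits so that reading the file
  # back reproduces every coordinate bit-exactly
  fmt_num <- function(x) sprintf("%.17g", x)
  lines <- vapply(tract$streamlines, function(s) {
    p <- s$points
    triplets <- paste0("[", fmt_num(p[, 1]), ",", fmt_num(p[, 2]), ",",
                       fmt_num(p[, 3]), "]", collapse = ",")
    sprintf('{"roi_label":%d,"termination_reason":"%s","points":[%s]}',
            s$roi_label, s$termination_reason, triplets)
  }, character(1))
  writeLines(lines, con)
  invisible(path)
}

#' Read a JSON-lines tractogram
#'
#' @param path file written by [write_tractogram_jsonl()].
#' @return A `tractogram`.
#' @export
read_tractogram_jsonl <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty tractogram file: ", path)
  prov <- NULL
  start <- 1L
  first <- jsonlite::fromJSON(lines[1], simplifyVector = TRUE)
  if (!is.null(first$provenance)) {
    prov <- first$provenance
    start <- 2L
  }
  streamlines <- vector("list", max(0L, length(lines) - start + 1L))
  j <- 0L
  for (i in seq.int(start, length.out = length(lines) - start + 1L)) {
    rec <- jsonlite::fromJSON(lines[i], simplifyVector = TRUE)
    j <- j + 1L
    pts <- rec$points
    if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3, byrow = TRUE)
    streamlines[[j]] <- list(points = pts,
                             roi_label = as.integer(rec$roi_label),
                             termination_reason = rec$termination_reason)
  }
  new_tractogram(streamlines[seq_len(j)], prov)
}

#' Export a tractogram as a TrackVis .trk file
#'
#' Writes a version-2 TrackVis file with the voxel size taken from the
#' stack metadata in the tractogram's provenance. Point coordinates are
#' stored in the TrackVis convention (voxel coordinates multiplied by the
#' voxel size); the micrometer is used where TrackVis assumes millimeters,
#' which viewers handle as an overall scale. One scalar-free, property-free
#' track is written per streamline. Note that .trk stores 32-bit floats, so
#' the round trip is close but not bit-exact; use the JSON-lines format for
#' lossless storage.
#'
#' @param tract a `tractogram` with stack calibration in its provenance.
#' @param path output `.trk` file.
#' @return `path`, invisibly.
#' @export
write_tractogram_trk <- function(tract, path) {
  stopifnot(inherits(tract, "tractogram"))
  p <- tract$provenance
  if (is.null(p$pixel_size_xy))
    stop("tractogram provenance lacks stack calibration")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw("TRACK"), con)
  writeBin(raw(1), con)
  writeBin(as.integer(c(p$width, p$height, p$depth)), con, size = 2)
  writeBin(as.numeric(c(p$pixel_size_xy, p$pixel_size_xy,
                        p$slice_thickness)), con, size = 4)
  writeBin(numeric(3), con, size = 4)            # origin
  writeBin(0L, con, size = 2)                    # n_scalars
  writeBin(raw(200), con)                        # scalar names
  writeBin(0L, con, size = 2)                    # n_properties
  writeBin(raw(200), con)                        # property names
  m <- diag(c(p$pixel_size_xy, p$pixel_size_xy, p$slice_thickness, 1))
  writeBin(as.numeric(t(m)), con, size = 4)      # vox_to_ras
  writeBin(raw(444), con)                        # reserved
  writeBin(c(charToRaw("RAS"), raw(1)), con)     # voxel_order
  writeBin(raw(4), con)                          # pad2
  writeBin(as.numeric(c(1, 0, 0, 0, 1, 0)), con, size = 4)
  writeBin(raw(2), con)                          # pad1
  writeBin(raw(6), con)                          # invert/swap flags
  writeBin(length(tract$streamlines), con, size = 4)
  writeBin(2L, con, size = 4)                    # version
  writeBin(1000L, con, size = 4)                 # hdr_size
  for (s in tract$streamlines) {
    writeBin(nrow(s$points), con, size = 4)
    writeBin(as.numeric(t(s$points)), con, size = 4)
  }
  invisible(path)
}

#' Read streamline points from a TrackVis .trk file
#'
#' Minimal reader for files written by [write_tractogram_trk()] (version 2,
#' no scalars or properties).
#'
#' @param path a `.trk` file.
#' @return list with `voxel_size` and `streamlines` (list of point
#'   matrices, float32 precision).
#' @export
read_tractogram_trk <- function(path) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 6)[1:5])
  if (magic != "TRACK") stop("not a TrackVis file: ", path)
  invisible(readBin(con, "integer", 3, size = 2))
  voxel_size <- readBin(con, "numeric", 3, size = 4)
  seek(con, 988)
  n_count <- readBin(con, "integer", 1, size = 4)
  invisible(readBin(con, "integer", 2, size = 4))
  streamlines <- vector("list", n_count)
  for (i in seq_len(n_count)) {
    np <- readBin(con, "integer", 1, size = 4)
    xyz <- readBin(con, "numeric", 3 * np, size = 4)
    streamlines[[i]] <- matrix(xyz, ncol = 3, byrow = TRUE)
  }
  list(voxel_size = voxel_size, streamlines = streamlines)
}
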