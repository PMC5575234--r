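# Minimal MRC2014 mode-2 (float32) volume I/O. Only the fields needed to
# exchange potential maps are interpreted: dimensions, mode, cell size.

#' Read an MRC volume as a potential map
#'
#' Supports MRC2014 mode 2 (32-bit float) volumes; the voxel size is taken
#' from the cell dimensions, and slices run along z (the slowest axis). The
#' volume is interpreted as the real part of the potential; the imaginary
#' part is zero.
#'
#' @param path Path to an MRC file.
#' @param slice_thickness Optional slice thickness in Angstrom; defaults to
#'   the z voxel size.
#' @return A `potential_map`.
#' @export
load_mrc_potential <- function(path, slice_thickness = NULL) {
  if (!file.exists(path)) stop(sprintf("MRC file not found: %s", path), call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_ints <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nx <- hdr_ints[1]; ny <- hdr_ints[2]; nz <- hdr_ints[3]; mode <- hdr_ints[4]
  if (length(hdr_ints) < 10 || any(is.na(hdr_ints))) {
    stop("truncated MRC header", call. = FALSE)
  }
  if (mode != 2L) {
    stop(sprintf("unsupported MRC mode %d (only mode 2, float32, is supported)", mode),
         call. = FALSE)
  }
  cella <- readBin(con, "double", n = 3, size = 4, endian = "little")
  voxel <- cella[1] / nx
  if (!is.finite(voxel) || voxel <= 0) {
    stop("non-positive voxel size in MRC header", call. = FALSE)
  }
  # skip the rest of the 1024-byte header (we have read 40 + 12 bytes)
  seek(con, where = 1024, origin = "start")
  n_vox <- as.double(nx) * ny * nz
  data <- readBin(con, "double", n = n_vox, size = 4, endian = "little")
  if (length(data) < n_vox) stop("truncated MRC data section", call. = FALSE)
  vol <- array(data, c(nx, ny, nz))
  if (is.null(slice_thickness)) slice_thickness <- cella[3] / nz
  potential_map(real = vol, voxel_size = voxel, slice_thickness = slice_thickness)
}

#' Write a 3D array as an MRC mode-2 volume
#'
#' @param volume 3D numeric array (nx, ny, nz).
#' @param voxel_size Voxel size in Angstrom (isotropic).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_mrc <- function(volume, voxel_size, path) {
  if (length(dim(volume)) == 2L) volume <- array(volume, c(dim(volume), 1L))
  stopifnot(length(dim(volume)) == 3L, voxel_size > 0)
  d <- dim(volume)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(c(d[1], d[2], d[3], 2L, 0L, 0L, 0L, d[1], d[2], d[3])),
           con, size = 4, endian = "little")
  writeBin(as.double(c(d * voxel_size, 90, 90, 90)), con, size = 4, endian = "little")
  writeBin(as.integer(c(1L, 2L, 3L)), con, size = 4, endian = "little")
  writeBin(as.double(c(min(volume), max(volume), mean(volume))), con,
           size = 4, endian = "little")
  writeBin(as.integer(c(0L, 0L)), con, size = 4, endian = "little") # ispg, nsymbt
  # pad header to 1024 bytes: 24 words written so far (4 bytes each)
  writeBin(raw(1024 - 24 * 4), con)
  writeBin(as.double(volume), con, size = 4, endian = "little")
  invisible(path)
}
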