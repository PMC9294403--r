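#' Read a cubic subtomogram volume from an MRC file
#'
#' Supports the MRC2014 layout with mode 2 (32-bit float) data, the format
#' subtomogram volumes are conventionally exchanged in. The voxel spacing
#' from the header (cell edge / sampling) is preserved as metadata.
#'
#' @param path path to an MRC file containing a cubic volume.
#' @return a list of class `fscc_subtomogram` with elements `volume`
#'   (cubic array), `voxel_size` (Angstrom or the file's unit), and
#'   `source_path`.
#' @export
read_subtomogram <- function(path) {
  if (!file.exists(path)) .fscc_stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "integer", n = 4, size = 4, endian = "little")
  if (length(hdr) < 4)
    .fscc_stop("MRC format error in ", path, ": truncated header")
  nx <- hdr[1]; ny <- hdr[2]; nz <- hdr[3]; mode <- hdr[4]
  if (any(c(nx, ny, nz) <= 0) || any(c(nx, ny, nz) > 4096) || mode != 2)
    .fscc_stop("MRC format error in ", path,
               ": unsupported header (mode must be 2, got ", mode, ")")
  if (nx != ny || ny != nz)
    .fscc_stop("MRC format error in ", path, ": volume is not cubic (",
               nx, "x", ny, "x", nz, ")")
  seek(con, 4 * 7)
  mxyz <- readBin(con, "integer", n = 3, size = 4, endian = "little")
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  seek(con, 4 * 23)
  nsymbt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  seek(con, 1024 + nsymbt)
  nvox <- as.numeric(nx) * ny * nz
  dat <- readBin(con, "numeric", n = nvox, size = 4, endian = "little")
  if (length(dat) < nvox)
    .fscc_stop("MRC format error in ", path, ": truncated data section (",
               length(dat), " of ", nvox, " voxels)")
  voxel <- if (mxyz[1] > 0 && cella[1] > 0) cella[1] / mxyz[1] else 1
  structure(list(volume = array(dat, dim = c(nx, ny, nz)),
                 voxel_size = voxel, source_path = path),
            class = "fscc_subtomogram")
}

#' Write a cubic volume as an MRC file
#'
#' Writes a standard MRC2014 header (mode 2, 32-bit float) followed by the
#' volume data, little-endian.
#'
#' @param volume cubic 3D array, or an `fscc_subtomogram`.
#' @param path destination path.
#' @param voxel_size voxel spacing recorded in the header (default 1).
#' @param overwrite allow replacing an existing file (default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_subtomogram <- function(volume, path, voxel_size = 1, overwrite = FALSE) {
  if (inherits(volume, "fscc_subtomogram")) {
    voxel_size <- volume$voxel_size
    volume <- volume$volume
  }
  d <- dim(volume)
  if (is.null(d) || length(d) != 3 || length(unique(d)) != 1)
    .fscc_stop("volume must be a cubic 3D array")
  if (file.exists(path) && !overwrite)
    .fscc_stop("refusing to overwrite existing file: ", path,
               " (set overwrite = TRUE)")
  if (any(!is.finite(volume))) .fscc_stop("volume contains non-finite values")
  g <- d[1]
  v <- as.vector(volume)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(c(g, g, g))              # nx ny nz
  wi(2)                       # mode 2: float32
  wi(c(0, 0, 0))              # nxstart
  wi(c(g, g, g))              # mx my mz
  wf(rep(g * voxel_size, 3))  # cella
  wf(c(90, 90, 90))           # cellb
  wi(c(1, 2, 3))              # mapc mapr maps
  wf(c(min(v), max(v), mean(v)))  # dmin dmax dmean
  wi(1)                       # ispg: volume
  wi(0)                       # nsymbt
  wi(rep(0, 25))              # extra
  wi(c(0, 0, 0))              # origin (words 50-52)
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(sd(v))                   # rms
  wi(0)                       # nlabl
  writeBin(raw(800), con)     # labels
  wf(v)
  invisible(path)
}
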