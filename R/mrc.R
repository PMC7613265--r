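# Minimal MRC2014 volume IO, mode 2 (float32) only, little-endian.
# No R package on this stack reads MRC, so the format is handled here;
# the voxel size in the header is authoritative and must be isotropic.

#' Read an MRC density volume
#'
#' Supports mode-2 (32-bit float) MRC2014 maps with isotropic voxels.
#'
#' @param path Path to an `.mrc` file.
#' @return A [density_volume()]; the header origin is preserved.
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", 10, size = 4, endian = "little")
  nx <- hdr_int[1]; ny <- hdr_int[2]; nz <- hdr_int[3]
  mode <- hdr_int[4]
  if (mode != 2) stop("unsupported MRC mode ", mode, " (only mode 2 float32)")
  mxyz <- hdr_int[8:10]
  cella <- readBin(con, "numeric", 3, size = 4, endian = "little")
  readBin(con, "numeric", 3, size = 4, endian = "little")          # cellb
  readBin(con, "integer", 3, size = 4, endian = "little")          # mapc/r/s
  readBin(con, "numeric", 3, size = 4, endian = "little")          # dmin/max/mean
  readBin(con, "integer", 2, size = 4, endian = "little")          # ispg nsymbt
  readBin(con, "raw", 100)                                         # extra
  origin <- readBin(con, "numeric", 3, size = 4, endian = "little")
  readBin(con, "raw", 1024 - 208)                                  # rest of header
  vox <- cella / mxyz
  if (any(vox <= 0) || max(abs(vox - vox[1])) > 1e-3 * vox[1])
    stop("anisotropic or invalid voxel size in MRC header: ",
         paste(signif(vox, 6), collapse = " x "))
  n <- nx * ny * nz
  dat <- readBin(con, "numeric", n, size = 4, endian = "little")
  if (length(dat) != n) stop("truncated MRC data block")
  density_volume(array(dat, c(nx, ny, nz)), vox[1], origin)
}

#' Write an MRC density volume
#'
#' Writes a mode-2 (float32) MRC2014 map with the volume's voxel size and
#' origin in the header.
#'
#' @param vol A [density_volume()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(vol, path) {
  stopifnot(inherits(vol, "density_volume"))
  d <- dim(vol$grid)
  g <- as.numeric(vol$grid)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(c(d, 2L, 0L, 0L, 0L, d)), con, size = 4, endian = "little")
  writeBin(as.numeric(c(d * vol$voxel, 90, 90, 90)), con, size = 4, endian = "little")
  writeBin(1:3, con, size = 4, endian = "little")
  writeBin(as.numeric(c(min(g), max(g), mean(g))), con, size = 4, endian = "little")
  writeBin(c(1L, 0L), con, size = 4, endian = "little")   # ispg, nsymbt
  writeBin(raw(100), con)
  writeBin(as.numeric(vol$origin), con, size = 4, endian = "little")
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)        # little-endian stamp
  writeBin(as.numeric(sd(g)), con, size = 4, endian = "little")
  writeBin(0L, con, size = 4, endian = "little")          # nlabl
  writeBin(raw(800), con)
  writeBin(g, con, size = 4, endian = "little")
  invisible(path)
}
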