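#' Read an MRC2014 volume (mode 2, float32)
#'
#' Minimal, strict reader for the interchange format used throughout the
#' pipeline.  Only mode 2 (32-bit float) single volumes/stacks are accepted;
#' the voxel size is taken from the cell dimensions divided by the grid
#' sampling.  Data are returned in `(z, y, x)` array order.
#'
#' @param path file to read.
#' @return A [density_volume()].
#' @export
read_mrc <- function(path) {
  size <- file.info(path)$size
  if (is.na(size) || size < 1024)
    stop("MRC format error: file shorter than the 1024-byte header")
  con <- file(path, "rb")
  on.exit(close(con))
  nxyz <- readBin(con, "integer", 3, size = 4, endian = "little")
  mode <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (any(nxyz < 1))
    stop("MRC format error: non-positive dimension in header field nx/ny/nz")
  if (mode != 2L)
    stop(sprintf("MRC format error: unsupported header field mode = %d (only mode 2/float32)", mode))
  readBin(con, "integer", 3, size = 4, endian = "little")       # nxstart..
  mxyz <- readBin(con, "integer", 3, size = 4, endian = "little")
  cella <- readBin(con, "numeric", 3, size = 4, endian = "little")
  readBin(con, "numeric", 3, size = 4, endian = "little")       # cellb
  readBin(con, "integer", 3, size = 4, endian = "little")       # mapc/mapr/maps
  readBin(con, "numeric", 3, size = 4, endian = "little")       # dmin/dmax/dmean
  readBin(con, "integer", 1, size = 4, endian = "little")       # ispg
  nsymbt <- readBin(con, "integer", 1, size = 4, endian = "little")
  readBin(con, "integer", 25, size = 4, endian = "little")      # extra 25..49
  origin <- readBin(con, "numeric", 3, size = 4, endian = "little") # x,y,z
  seek(con, 1024 + nsymbt)
  n <- prod(nxyz)
  expected <- 1024 + nsymbt + 4 * n
  if (size < expected)
    stop(sprintf("MRC format error: data block truncated (nx*ny*nz implies %d bytes, file has %d)",
                 expected, size))
  vals <- readBin(con, "numeric", n, size = 4, endian = "little")
  if (any(mxyz < 1)) mxyz <- nxyz
  vs <- cella / mxyz
  if (any(vs <= 0)) vs <- c(1, 1, 1)
  if (diff(range(vs)) > 1e-4 * vs[1])
    stop("MRC format error: anisotropic voxel size in header field cella")
  # file order: x fastest, then y, then z -> array (nx, ny, nz) -> (z, y, x)
  g <- aperm(array(vals, dim = nxyz), c(3, 2, 1))
  density_volume(g, vs[1], origin = rev(origin))
}

#' Write an MRC2014 volume (mode 2, float32)
#'
#' @param vol a [density_volume()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(vol, path) {
  d <- dim(vol$grid)                 # (nz, ny, nx)
  nxyz <- rev(d)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(nxyz); wi(2L)                                    # nx ny nz, mode
  wi(c(0L, 0L, 0L))                                   # nxstart
  wi(nxyz)                                            # mx my mz
  wf(nxyz * vol$voxel_size)                           # cella
  wf(c(90, 90, 90))                                   # cellb
  wi(c(1L, 2L, 3L))                                   # mapc mapr maps
  wf(c(min(vol$grid), max(vol$grid), mean(vol$grid))) # dmin dmax dmean
  wi(c(0L, 0L))                                       # ispg, nsymbt
  wi(c(0L, 0L))                                       # extra words 25, 26
  writeBin(charToRaw("MRC2"), con)                    # exttyp (word 27)
  wi(20140L)                                          # nversion (word 28)
  wi(rep(0L, 21))                                     # extra words 29..49
  wf(rev(vol$origin))                                 # origin x y z (50..52)
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)    # machst (little endian)
  wf(sd(as.numeric(vol$grid)))                        # rms
  wi(1L)                                              # nlabl
  lab <- sprintf("%-80s", "crystomo")
  writeChar(paste(rep(lab, 1), collapse = ""), con, 80, eos = NULL)
  writeBin(raw(720), con)                             # labels 2..10
  wf(as.numeric(aperm(vol$grid, c(3, 2, 1))))
  invisible(path)
}
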