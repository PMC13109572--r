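#' Construct a LiDAR point cloud
#'
#' A point cloud is a plain data frame with columns `x`, `y`, `z` (metres) and
#' optional `classification` (LAS codes; 2 = ground) and `return_number`
#' columns, carrying class `point_cloud`. All coordinates must be finite and
#' the columns of equal length.
#'
#' @param x,y,z Numeric coordinate vectors of equal length (metres).
#' @param classification Optional integer LAS classification codes (2 = ground).
#' @param return_number Optional integer return numbers.
#' @return A `point_cloud` data frame.
#' @export
point_cloud <- function(x = numeric(), y = numeric(), z = numeric(),
                        classification = NULL, return_number = NULL) {
  n <- length(x)
  if (length(y) != n || length(z) != n)
    stop_voxfpar("x, y, z must have equal length", "voxfpar_format_error")
  if (n > 0 && !all(is.finite(x) & is.finite(y) & is.finite(z)))
    stop_voxfpar("point coordinates must be finite", "voxfpar_format_error")
  pc <- data.frame(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z))
  if (!is.null(classification)) {
    stopifnot(length(classification) == n)
    pc$classification <- as.integer(classification)
  }
  if (!is.null(return_number)) {
    stopifnot(length(return_number) == n)
    pc$return_number <- as.integer(return_number)
  }
  class(pc) <- c("point_cloud", "data.frame")
  pc
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud: %d points>\n", nrow(x)))
  if (nrow(x) > 0) {
    cat(sprintf("  x: [%.3f, %.3f]  y: [%.3f, %.3f]  z: [%.3f, %.3f]\n",
                min(x$x), max(x$x), min(x$y), max(x$y), min(x$z), max(x$z)))
    if (!is.null(x$classification))
      cat(sprintf("  ground-classified points: %d\n", sum(x$classification == 2L)))
  }
  invisible(x)
}

# ---- LAS 1.2 binary I/O (point data record format 0) -----------------------
# Minimal codec: 227-byte header, 20-byte point records. Coordinates are
# stored as scaled 32-bit integers; the default scale of 0.001 m preserves
# millimetre precision, the LAS quantum asserted by the round-trip tests.

LAS_HEADER_SIZE <- 227L
LAS_POINT_SIZE <- 20L

#' Write a point cloud to a LAS file
#'
#' Writes LAS 1.2, point data format 0. Coordinates are quantized to
#' `scale` (default 1 mm); classification codes are preserved.
#'
#' @param pc A [point_cloud()].
#' @param path Output file path.
#' @param scale Coordinate quantum in metres.
#' @return `path`, invisibly.
#' @export
write_las <- function(pc, path, scale = 0.001) {
  n <- nrow(pc)
  off <- if (n > 0) c(min(pc$x), min(pc$y), min(pc$z)) else c(0, 0, 0)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("LASF", con, 4, eos = NULL)
  writeBin(rep(0L, 2), con, size = 2)              # source id, global encoding
  writeBin(rep(0L, 4), con, size = 4)              # 16-byte GUID block
  writeBin(c(1L, 2L), con, size = 1)               # version 1.2
  writeChar(formatC("voxfpar", width = 32), con, 32, eos = NULL)  # system id
  writeChar(formatC("voxfpar R package", width = 32), con, 32, eos = NULL)
  writeBin(c(1L, 2026L), con, size = 2)            # day, year
  writeBin(LAS_HEADER_SIZE, con, size = 2)         # header size
  writeBin(LAS_HEADER_SIZE, con, size = 4)         # offset to point data
  writeBin(0L, con, size = 4)                      # number of VLRs
  writeBin(0L, con, size = 1)                      # point format 0
  writeBin(LAS_POINT_SIZE, con, size = 2)          # point record length
  writeBin(n, con, size = 4)                       # number of points
  writeBin(rep(0L, 5), con, size = 4)              # points by return
  writeBin(c(scale, scale, scale), con, size = 8)  # scale factors
  writeBin(off, con, size = 8)                     # offsets
  rng <- function(v) if (n > 0) c(max(v), min(v)) else c(0, 0)
  writeBin(c(rng(pc$x), rng(pc$y), rng(pc$z)), con, size = 8)
  cls <- if (!is.null(pc$classification)) pc$classification else rep(0L, n)
  rn <- if (!is.null(pc$return_number)) pc$return_number else rep(1L, n)
  if (n > 0) {
    xi <- as.integer(round((pc$x - off[1]) / scale))
    yi <- as.integer(round((pc$y - off[2]) / scale))
    zi <- as.integer(round((pc$z - off[3]) / scale))
    # one raw matrix, 20 bytes per record, written in a single call
    rec <- matrix(as.raw(0), nrow = LAS_POINT_SIZE, ncol = n)
    pack4 <- function(v) writeBin(v, raw(), size = 4)
    rec[1:4, ] <- matrix(pack4(xi), nrow = 4)
    rec[5:8, ] <- matrix(pack4(yi), nrow = 4)
    rec[9:12, ] <- matrix(pack4(zi), nrow = 4)
    # bytes 13-14 intensity = 0; byte 15 return info
    rec[15, ] <- as.raw(bitwOr(bitwAnd(rn, 7L), bitwShiftL(1L, 3L)))
    rec[16, ] <- as.raw(bitwAnd(cls, 255L))        # classification
    writeBin(as.vector(rec), con)
  }
  invisible(path)
}

#' Read a LAS file
#'
#' Supports the subset written by [write_las()] (LAS 1.x, point formats 0-3;
#' only x/y/z, return number and classification are decoded).
#'
#' @param path LAS file path.
#' @return A [point_cloud()].
#' @export
read_las <- function(path) {
  if (!file.exists(path))
    stop_voxfpar(paste0("file not found: ", path), "voxfpar_io_error")
  sz <- file.info(path)$size
  if (is.na(sz) || sz < LAS_HEADER_SIZE)
    stop_voxfpar(sprintf("malformed LAS file (only %d bytes, header needs %d): %s",
                         sz, LAS_HEADER_SIZE, path), "voxfpar_format_error")
  con <- file(path, "rb")
  on.exit(close(con))
  sig <- readChar(con, 4, useBytes = TRUE)
  if (!identical(sig, "LASF"))
    stop_voxfpar(sprintf("malformed LAS file (bad signature at offset 0): %s", path),
                 "voxfpar_format_error")
  seek(con, 96)
  offset_to_points <- readBin(con, integer(), size = 4)
  seek(con, 104)
  pt_fmt <- readBin(con, integer(), size = 1)
  rec_len <- readBin(con, integer(), size = 2, signed = FALSE)
  n <- readBin(con, integer(), size = 4)
  seek(con, 131)
  scales <- readBin(con, numeric(), n = 3, size = 8)
  offs <- readBin(con, numeric(), n = 3, size = 8)
  if (rec_len < LAS_POINT_SIZE || n < 0)
    stop_voxfpar(sprintf("malformed LAS header (record length %d at offset 105): %s",
                         rec_len, path), "voxfpar_format_error")
  if (sz < offset_to_points + as.numeric(n) * rec_len)
    stop_voxfpar(sprintf("truncated LAS file: %d point records declared but data clipped at byte %d",
                         n, sz), "voxfpar_format_error")
  if (n == 0) return(point_cloud())
  seek(con, offset_to_points)
  rec <- matrix(readBin(con, raw(), n = as.numeric(n) * rec_len), nrow = rec_len)
  unpack4 <- function(rows) readBin(as.vector(rec[rows, ]), integer(), n = n, size = 4)
  xi <- unpack4(1:4); yi <- unpack4(5:8); zi <- unpack4(9:12)
  rn <- bitwAnd(as.integer(rec[15, ]), 7L)
  cls <- as.integer(rec[16, ])
  point_cloud(xi * scales[1] + offs[1], yi * scales[2] + offs[2],
              zi * scales[3] + offs[3], classification = cls, return_number = rn)
}
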