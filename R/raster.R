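# Raster containers.
#
# A `band_raster` stores values as a [nrow, ncol, nband] array in map
# orientation: column index increases with x, row index increases with y
# (row 1 is the southern edge). `origin` is the (x, y) of the lower-left
# corner of cell (1, 1) and `gsd` the square cell size in metres. On disk a
# raster is a float TIFF plus an ESRI world file (.tfw) carrying the
# georeferencing, the portable plain-format pair used throughout.

#' Create a multi-band raster
#'
#' @param values Numeric array `[nrow, ncol, nband]` (or a matrix for a single
#'   band). Rows index y from the southern edge, columns index x.
#' @param origin Length-2 numeric, map coordinates of the lower-left corner.
#' @param gsd Cell size in metres (> 0).
#' @param bands Optional character vector of band names.
#' @return A `band_raster` object.
#' @export
band_raster <- function(values, origin = c(0, 0), gsd = 1, bands = NULL) {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  stopifnot(length(dim(values)) == 3, gsd > 0, length(origin) == 2)
  if (is.null(bands)) bands <- paste0("band", seq_len(dim(values)[3]))
  stopifnot(length(bands) == dim(values)[3])
  structure(list(values = values, origin = as.numeric(origin),
                 gsd = as.numeric(gsd), bands = bands),
            class = "band_raster")
}

#' @export
print.band_raster <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<band_raster: %d x %d cells, %d band(s), gsd %g m, origin (%g, %g)>\n",
              d[1], d[2], d[3], x$gsd, x$origin[1], x$origin[2]))
  invisible(x)
}

#' Height raster (single band with no-data support)
#'
#' Thin wrapper over [band_raster()] for canopy height / surface models;
#' `NA` is the no-data sentinel.
#'
#' @inheritParams band_raster
#' @return A `band_raster` with a single `height` band.
#' @export
height_raster <- function(values, origin = c(0, 0), gsd = 1) {
  band_raster(values, origin, gsd, bands = "height")
}

raster_values <- function(r, band = 1) r$values[, , band]

# nearest-neighbour lookup: map coords -> values; outside extent -> NA
raster_sample <- function(r, x, y, band = seq_len(dim(r$values)[3])) {
  j <- bin_index(x, r$origin[1], r$gsd) + 1L
  i <- bin_index(y, r$origin[2], r$gsd) + 1L
  d <- dim(r$values)
  ok <- !is.na(i) & !is.na(j) & i >= 1L & i <= d[1] & j >= 1L & j <= d[2]
  out <- matrix(NA_real_, length(x), length(band))
  for (b in seq_along(band))
    out[ok, b] <- r$values[cbind(i[ok], j[ok], band[b])]
  colnames(out) <- r$bands[band]
  out
}

sidecar_paths <- function(path) {
  tfw <- sub("\\.tiff?$", ".tfw", path, ignore.case = TRUE)
  if (identical(tfw, path)) tfw <- paste0(path, ".tfw")
  list(tfw = tfw, meta = paste0(path, ".meta"))
}

#' Write a raster as TIFF + world file
#'
#' Samples are stored at 32-bit depth, which the TIFF writer treats as
#' integers normalized to [0, 1]; values are therefore affinely rescaled into
#' [0.1, 1] (`NA` encoded as 0) and the scaling recorded in a `.meta` YAML
#' sidecar, giving ~2e-10 relative quantization and exact round trips for
#' integer-valued rasters. An ESRI `.tfw` world file carries the
#' georeferencing.
#'
#' @param r A [band_raster()].
#' @param path Output path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_raster <- function(r, path) {
  v <- r$values
  nas <- is.na(v)
  vmin <- if (all(nas)) 0 else min(v, na.rm = TRUE)
  vmax <- if (all(nas)) 1 else max(v, na.rm = TRUE)
  vrange <- max(vmax - vmin, .Machine$double.eps)
  is_int <- !any(!nas & v != round(v))
  enc <- pmin(1, pmax(0, 0.1 + 0.9 * (v - vmin) / vrange))
  enc[nas] <- 0
  dim(enc) <- dim(v)
  # TIFF is top-down: flip y so row 1 becomes the northern edge; bands are
  # stored as one grayscale page each (directory order = band order)
  img <- enc[dim(enc)[1]:1, , , drop = FALSE]
  pages <- lapply(seq_len(dim(img)[3]), function(b) img[, , b])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  d <- dim(v)
  sp <- sidecar_paths(path)
  # world file: cell x size, rotations, -cell y size, center of upper-left cell
  writeLines(format(c(r$gsd, 0, 0, -r$gsd,
                      r$origin[1] + r$gsd / 2,
                      r$origin[2] + (d[1] - 0.5) * r$gsd),
                    digits = 15, scientific = FALSE, trim = TRUE), sp$tfw)
  yaml::write_yaml(list(vmin = vmin, vrange = vrange, integer = is_int,
                        bands = r$bands), sp$meta)
  invisible(path)
}

#' Read a raster written by [write_raster()]
#'
#' @param path TIFF path (matching `.tfw` and `.meta` sidecars must sit
#'   beside it).
#' @param bands Optional band names overriding the stored ones.
#' @return A [band_raster()].
#' @export
read_raster <- function(path, bands = NULL) {
  if (!file.exists(path))
    stop_voxfpar(paste0("file not found: ", path), "voxfpar_io_error")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  img <- array(unlist(pages), c(dim(pages[[1]])[1:2], length(pages)))
  sp <- sidecar_paths(path)
  if (!file.exists(sp$tfw))
    stop_voxfpar(paste0("world file missing: ", sp$tfw), "voxfpar_io_error")
  if (!file.exists(sp$meta))
    stop_voxfpar(paste0("metadata sidecar missing: ", sp$meta), "voxfpar_io_error")
  w <- as.numeric(readLines(sp$tfw))
  meta <- yaml::read_yaml(sp$meta)
  gsd <- w[1]
  nr <- dim(img)[1]
  origin <- c(w[5] - gsd / 2, w[6] - (nr - 0.5) * gsd)
  enc <- img[nr:1, , , drop = FALSE]
  v <- (enc - 0.1) / 0.9 * meta$vrange + meta$vmin
  v[enc < 0.05] <- NA
  if (isTRUE(meta$integer)) v <- round(v)
  band_raster(v, origin = origin, gsd = gsd,
              bands = bands %||% unlist(meta$bands))
}
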