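# Fusing the point-cloud frame with the orthomosaic frame: affine
# co-registration from control-point pairs, voxelization of the normalized
# cloud into vertical columns, and downward propagation of top-of-canopy
# reflectance ("highest point within column").

#' Fit a 2-D affine co-registration from control-point pairs
#'
#' Least-squares affine transform mapping point-cloud (x, y) to raster
#' (x, y): `x' = a1 + a2 x + a3 y`, `y' = b1 + b2 x + b3 y`.
#'
#' @param cloud_xy Two-column matrix/data frame of point-cloud coordinates.
#' @param raster_xy Two-column matrix/data frame of matching raster
#'   coordinates.
#' @return An `affine2d`: list with 2x3 coefficient matrix `coef` and `rmse`
#'   (root mean squared residual over the pairs, metres).
#' @export
fit_coregistration <- function(cloud_xy, raster_xy) {
  cloud_xy <- as.matrix(cloud_xy); raster_xy <- as.matrix(raster_xy)
  n <- nrow(cloud_xy)
  if (n < 3 || nrow(raster_xy) != n)
    stop_voxfpar("co-registration needs at least 3 control-point pairs",
                 "voxfpar_degenerate_error")
  X <- cbind(1, cloud_xy)
  if (qr(X)$rank < 3)
    stop_voxfpar("control points are collinear: affine fit is degenerate",
                 "voxfpar_degenerate_error")
  cf <- qr.solve(X, raster_xy)          # 3 x 2
  res <- raster_xy - X %*% cf
  A <- t(cf)                             # 2 x 3: rows = (x', y')
  if (abs(det(A[, 2:3])) < 1e-12)
    stop_voxfpar("fitted affine transform is singular", "voxfpar_degenerate_error")
  # per-pair residual = euclidean misregistration distance
  structure(list(coef = A, rmse = sqrt(mean(rowSums(res^2))), n = n),
            class = "affine2d")
}

#' Apply an affine transform to coordinates
#'
#' @param transform An `affine2d` from [fit_coregistration()], or `NULL` for
#'   the identity.
#' @param x,y Coordinate vectors.
#' @return Two-column matrix of transformed coordinates.
#' @export
apply_transform <- function(transform, x, y) {
  if (is.null(transform)) return(cbind(x = x, y = y))
  A <- transform$coef
  cbind(x = A[1, 1] + A[1, 2] * x + A[1, 3] * y,
        y = A[2, 1] + A[2, 2] * x + A[2, 3] * y)
}

#' @export
print.affine2d <- function(x, ...) {
  cat(sprintf("<affine2d: rmse %.4g m over %d control pairs>\n", x$rmse, x$n))
  invisible(x)
}

#' Voxelize a normalized point cloud into vertical columns
#'
#' Points are binned half-open: `i = floor((x - x0)/dx)`,
#' `j = floor((y - y0)/dy)`, `k = floor(z/dz)`. The per-column top point is
#' the point with the highest normalized height (ties: smallest point index).
#' The field-scale resolution (0.01 m x 0.01 m x 2 m) is available through
#' the arguments; the desk-scale default is 0.25 m horizontal.
#'
#' @param pc A normalized [point_cloud()].
#' @param dx,dy Horizontal resolutions in metres (> 0).
#' @param dz Vertical resolution in metres (> 0).
#' @param origin Optional fixed (x0, y0) grid origin; default snaps the
#'   minimum coordinate down to the cell grid.
#' @return A `voxel_grid`: list with `voxels` (i, j, k, count), `columns`
#'   (i, j, top_x, top_y, top_z), origin and resolutions.
#' @export
voxelize <- function(pc, dx = 0.25, dy = dx, dz = 2, origin = NULL) {
  stopifnot(dx > 0, dy > 0, dz > 0)
  if (nrow(pc) == 0) {
    return(structure(list(
      voxels = data.frame(i = integer(), j = integer(), k = integer(),
                          count = integer()),
      columns = data.frame(i = integer(), j = integer(), top_x = numeric(),
                           top_y = numeric(), top_z = numeric()),
      origin = c(0, 0), dx = dx, dy = dy, dz = dz), class = "voxel_grid"))
  }
  if (is.null(origin)) {
    ox <- grid_origin(min(pc$x), dx); oy <- grid_origin(min(pc$y), dy)
  } else {
    ox <- origin[1]; oy <- origin[2]
  }
  dt <- data.table::data.table(
    i = bin_index(pc$x, ox, dx), j = bin_index(pc$y, oy, dy),
    k = bin_index(pc$z, 0, dz), x = pc$x, y = pc$y, z = pc$z,
    idx = seq_len(nrow(pc)))
  vox <- dt[, list(count = .N), by = c("i", "j", "k")]
  data.table::setorder(vox, i, j, k)
  cols <- dt[order(-z, idx), list(top_x = x[1], top_y = y[1], top_z = z[1]),
             by = c("i", "j")]
  data.table::setorder(cols, i, j)
  structure(list(voxels = as.data.frame(vox), columns = as.data.frame(cols),
                 origin = c(ox, oy), dx = dx, dy = dy, dz = dz),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid: %d occupied voxels in %d columns (%g x %g x %g m)>\n",
              nrow(x$voxels), nrow(x$columns), x$dx, x$dy, x$dz))
  invisible(x)
}

#' Propagate top-of-canopy reflectance down each voxel column
#'
#' For every column, the five-band reflectance of the orthomosaic pixel at
#' the (transformed) horizontal location of the column's highest point is
#' sampled by nearest neighbour and duplicated to every occupied voxel in the
#' column. Columns whose top point falls outside the raster get missing
#' reflectance and `outside = TRUE`.
#'
#' @param grid A [voxelize()] result.
#' @param raster A five-band [band_raster()].
#' @param transform Optional `affine2d` mapping cloud to raster coordinates.
#' @return A `fused_voxels` data frame: one row per occupied voxel with
#'   voxel indices, centroid coordinates, point count, `R450`..`R840` and an
#'   `outside` flag.
#' @export
propagate_reflectance <- function(grid, raster, transform = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (dim(raster$values)[3] != 5)
    stop_voxfpar(sprintf("orthomosaic must have 5 bands, got %d",
                         dim(raster$values)[3]), "voxfpar_format_error")
  cols <- grid$columns
  bands <- c("R450", "R560", "R650", "R730", "R840")
  if (nrow(cols) > 0) {
    txy <- apply_transform(transform, cols$top_x, cols$top_y)
    refl <- raster_sample(raster, txy[, 1], txy[, 2])
    colnames(refl) <- bands
  } else refl <- matrix(numeric(), 0, 5, dimnames = list(NULL, bands))
  vox <- grid$voxels
  key <- match(paste(vox$i, vox$j), paste(cols$i, cols$j))
  out <- data.frame(i = vox$i, j = vox$j, k = vox$k,
                    x = grid$origin[1] + (vox$i + 0.5) * grid$dx,
                    y = grid$origin[2] + (vox$j + 0.5) * grid$dy,
                    z = (vox$k + 0.5) * grid$dz,
                    count = vox$count)
  for (b in bands) out[[b]] <- refl[key, b]
  out$outside <- is.na(out$R450)
  class(out) <- c("fused_voxels", "data.frame")
  attr(out, "resolution") <- c(dx = grid$dx, dy = grid$dy, dz = grid$dz)
  attr(out, "origin") <- grid$origin
  out
}
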