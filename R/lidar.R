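# Point-cloud processing: ground classification, height normalization,
# canopy height models and individual-tree segmentation.
#
# Grid conventions shared by every raster-facing operation: cells are
# half-open, lower-edge inclusive, and the grid origin is the floor of the
# minimum coordinate to the cell size, so points on interior edges are never
# double-counted.

#' Classify ground points
#'
#' Flags, within each `cell` x `cell` tile, every point whose elevation lies
#' within `tolerance` of the tile's minimum as ground (LAS class 2);
#' everything else becomes class 1. Simple minimum-plus-tolerance
#' classification is exact on the synthetic scenes used as oracle and is
#' deliberately parameter-light.
#'
#' @param pc A [point_cloud()].
#' @param cell Tile size in metres (> 0).
#' @param tolerance Vertical tolerance above the tile minimum (m).
#' @return The point cloud with a `classification` column (2 = ground).
#' @export
classify_ground <- function(pc, cell = 2, tolerance = 0.3) {
  stopifnot(cell > 0, tolerance >= 0)
  if (nrow(pc) < 3)
    stop_voxfpar("ground classification needs at least 3 points",
                 "voxfpar_data_error")
  ox <- grid_origin(min(pc$x), cell); oy <- grid_origin(min(pc$y), cell)
  key <- paste(bin_index(pc$x, ox, cell), bin_index(pc$y, oy, cell))
  zmin <- stats::ave(pc$z, key, FUN = min)
  pc$classification <- ifelse(pc$z <= zmin + tolerance, 2L, 1L)
  pc
}

# Digital terrain model from ground-classified points: per-cell median of
# ground elevations, NA cells filled from the nearest informed neighbours by
# iterative 3x3 mean dilation.
make_dtm <- function(pc, cell = 2) {
  g <- pc[pc$classification == 2L, , drop = FALSE]
  if (nrow(g) == 0)
    stop_voxfpar("no ground points: run classify_ground() first",
                 "voxfpar_data_error")
  ox <- grid_origin(min(pc$x), cell); oy <- grid_origin(min(pc$y), cell)
  nc <- bin_index(max(pc$x), ox, cell) + 1L
  nr <- bin_index(max(pc$y), oy, cell) + 1L
  m <- matrix(NA_real_, nr, nc)
  i <- bin_index(g$y, oy, cell) + 1L
  j <- bin_index(g$x, ox, cell) + 1L
  med <- tapply(g$z, paste(i, j), stats::median)
  ij <- do.call(rbind, lapply(strsplit(names(med), " "), as.integer))
  m[ij] <- med
  while (anyNA(m)) {
    fill <- neighbour_mean(m)
    isna <- is.na(m)
    m[isna] <- fill[isna]
    if (all(is.na(fill[isna]))) break
  }
  height_raster(m, origin = c(ox, oy), gsd = cell)
}

# mean over the 3x3 neighbourhood ignoring NA (used to dilate the DTM)
neighbour_mean <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  s <- matrix(0, nr, nc); cnt <- matrix(0, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    si <- max(1, 1 + di):min(nr, nr + di)
    ti <- max(1, 1 - di):min(nr, nr - di)
    sj <- max(1, 1 + dj):min(nc, nc + dj)
    tj <- max(1, 1 - dj):min(nc, nc - dj)
    v <- m[si, sj, drop = FALSE]
    ok <- !is.na(v)
    v[!ok] <- 0
    s[ti, tj] <- s[ti, tj] + v
    cnt[ti, tj] <- cnt[ti, tj] + ok
  }
  out <- s / cnt
  out[cnt == 0] <- NA
  out
}

# bilinear interpolation of a height raster at arbitrary coordinates,
# clamped to the raster's cell-centre hull
interp_bilinear <- function(r, x, y) {
  v <- raster_values(r)
  nr <- nrow(v); nc <- ncol(v)
  gx <- (x - r$origin[1]) / r$gsd - 0.5
  gy <- (y - r$origin[2]) / r$gsd - 0.5
  gx <- pmin(pmax(gx, 0), nc - 1)
  gy <- pmin(pmax(gy, 0), nr - 1)
  j0 <- pmin(floor(gx), nc - 2); j0 <- pmax(j0, 0)
  i0 <- pmin(floor(gy), nr - 2); i0 <- pmax(i0, 0)
  if (nc == 1) j0 <- rep(0, length(x))
  if (nr == 1) i0 <- rep(0, length(y))
  fx <- gx - j0; fy <- gy - i0
  j1 <- pmin(j0 + 1, nc - 1); i1 <- pmin(i0 + 1, nr - 1)
  vat <- function(i, j) v[cbind(i + 1, j + 1)]
  (1 - fx) * (1 - fy) * vat(i0, j0) + fx * (1 - fy) * vat(i0, j1) +
    (1 - fx) * fy * vat(i1, j0) + fx * fy * vat(i1, j1)
}

#' Normalize point heights above ground
#'
#' Subtracts a bilinearly interpolated ground surface (per-cell median of
#' ground-classified elevations) from every point. Points more than 0.1 m
#' below the interpolated ground are dropped; small negative residuals in
#' [-0.1, 0) are clamped to zero.
#'
#' @param pc A ground-classified [point_cloud()].
#' @param cell DTM cell size in metres.
#' @return The normalized point cloud (z = height above ground).
#' @export
normalize_heights <- function(pc, cell = 2) {
  if (is.null(pc$classification))
    stop_voxfpar("point cloud has no classification: run classify_ground() first",
                 "voxfpar_data_error")
  dtm <- make_dtm(pc, cell = cell)
  gz <- interp_bilinear(dtm, pc$x, pc$y)
  z <- pc$z - gz
  keep <- z >= -0.1
  pc <- pc[keep, , drop = FALSE]
  pc$z <- pmax(0, z[keep])
  class(pc) <- c("point_cloud", "data.frame")
  attr(pc, "dtm") <- dtm
  pc
}

#' Rasterize a canopy height model
#'
#' Each cell takes the maximum normalized height of the points falling in it
#' (half-open binning, lower edge inclusive); empty cells are `NA`.
#'
#' @param pc A normalized [point_cloud()].
#' @param gsd Cell size in metres (> 0).
#' @return A [height_raster()].
#' @export
rasterize_chm <- function(pc, gsd = 0.5) {
  stopifnot(gsd > 0)
  if (nrow(pc) == 0)
    return(height_raster(matrix(NA_real_, 1, 1), origin = c(0, 0), gsd = gsd))
  ox <- grid_origin(min(pc$x), gsd); oy <- grid_origin(min(pc$y), gsd)
  j <- bin_index(pc$x, ox, gsd) + 1L
  i <- bin_index(pc$y, oy, gsd) + 1L
  nr <- max(i); nc <- max(j)
  m <- matrix(NA_real_, nr, nc)
  mx <- tapply(pc$z, paste(i, j), max)
  ij <- do.call(rbind, lapply(strsplit(names(mx), " "), as.integer))
  m[ij] <- mx
  height_raster(m, origin = c(ox, oy), gsd = gsd)
}

# separable Gaussian smoothing; NA (no-data) cells are treated as height 0
gaussian_smooth <- function(m, sigma) {
  m[is.na(m)] <- 0
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  pad_conv <- function(v) {
    n <- length(v)
    vp <- c(rep(0, r), v, rep(0, r))
    out <- numeric(n)
    for (t in seq_along(k)) out <- out + k[t] * vp[seq_len(n) + (t - 1)]
    out
  }
  m2 <- apply(m, 2, pad_conv)
  t(apply(t(m2), 2, pad_conv))
}

# windowed maximum by shifting (window radius `rad` cells, chebyshev)
window_max <- function(m, rad) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  for (di in -rad:rad) for (dj in -rad:rad) {
    if (di == 0 && dj == 0) next
    si <- max(1, 1 + di):min(nr, nr + di)
    ti <- max(1, 1 - di):min(nr, nr - di)
    sj <- max(1, 1 + dj):min(nc, nc + dj)
    tj <- max(1, 1 - dj):min(nc, nc - dj)
    out[ti, tj] <- pmax(out[ti, tj], m[si, sj])
  }
  out
}

#' Segment individual trees from a canopy height model
#'
#' The CHM is Gaussian-smoothed, local maxima above `min_height` and
#' separated by at least `min_distance` cells become tree markers, and a
#' marker-controlled watershed on the inverted smoothed surface grows each
#' marker downslope. Cells below `min_height` are background (label 0).
#' Plateau and proximity ties always resolve to the lexicographically
#' smallest cell, so segmentation is deterministic.
#'
#' @param chm A [height_raster()] canopy height model.
#' @param smooth_sigma Gaussian sigma in cells (default 1).
#' @param min_height Minimum tree height in metres.
#' @param min_distance Minimum marker separation in cells.
#' @return A `tree_segmentation`: list with `labels` (integer label raster)
#'   and `trees` (tree_id, apex_x, apex_y, apex_height).
#' @export
segment_trees <- function(chm, smooth_sigma = 1, min_height = 2,
                          min_distance = 3) {
  v <- raster_values(chm)
  if (all(is.na(v)))
    stop_voxfpar("CHM is empty", "voxfpar_data_error")
  sm <- gaussian_smooth(v, smooth_sigma)
  mask <- !is.na(v) & v >= min_height
  empty <- function() {
    lab <- height_raster(matrix(0L, nrow(v), ncol(v)), chm$origin, chm$gsd)
    lab$bands <- "label"
    list(labels = lab,
         trees = data.frame(tree_id = integer(), apex_x = numeric(),
                            apex_y = numeric(), apex_height = numeric()))
  }
  if (!any(mask)) return(structure(empty(), class = "tree_segmentation"))
  # markers: cells attaining the windowed max, above min_height, with
  # lexicographic suppression of ties within min_distance
  wm <- window_max(sm, max(1L, as.integer(min_distance)))
  cand <- which(mask & sm >= wm - 1e-12, arr.ind = TRUE)
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  keep <- rep(TRUE, nrow(cand))
  for (a in seq_len(nrow(cand))) {
    if (!keep[a]) next
    if (a < nrow(cand)) {
      later <- (a + 1):nrow(cand)
      close_ <- abs(cand[later, 1] - cand[a, 1]) <= min_distance &
        abs(cand[later, 2] - cand[a, 2]) <= min_distance
      keep[later][close_] <- FALSE
    }
  }
  markers <- cand[keep, , drop = FALSE]
  lab <- matrix(0L, nrow(v), ncol(v))
  lab[markers] <- seq_len(nrow(markers))
  # watershed flood: visit masked cells in decreasing smoothed height
  # (= increasing height on the inverted surface); each unlabelled cell takes
  # the label of its highest labelled 8-neighbour
  ord <- which(mask)
  ord <- ord[order(-sm[ord], ((ord - 1) %% nrow(v)) + 1, (ord - 1) %/% nrow(v))]
  nr <- nrow(v); nc <- ncol(v)
  repeat {
    changed <- FALSE
    for (cell in ord) {
      if (lab[cell] > 0L) next
      i <- ((cell - 1) %% nr) + 1L
      j <- ((cell - 1) %/% nr) + 1L
      best <- 0L; besth <- -Inf
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        ii <- i + di; jj <- j + dj
        if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
        l2 <- lab[ii, jj]
        if (l2 > 0L) {
          h2 <- sm[ii, jj]
          if (h2 > besth || (h2 == besth && l2 < best)) {
            best <- l2; besth <- h2
          }
        }
      }
      if (best > 0L) {
        lab[cell] <- best
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  # any still-unlabelled masked component lost its maximum to suppression:
  # promote its highest cell to a new marker and flood once more
  while (any(lab[mask] == 0L)) {
    rem <- which(mask & lab == 0L)
    top <- rem[order(-sm[rem], ((rem - 1) %% nr) + 1, (rem - 1) %/% nr)][1]
    lab[top] <- max(lab) + 1L
    for (cell in ord) {
      if (lab[cell] > 0L) next
      i <- ((cell - 1) %% nr) + 1L
      j <- ((cell - 1) %/% nr) + 1L
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
        if (lab[ii, jj] > 0L) { lab[cell] <- lab[ii, jj]; break }
      }
    }
  }
  ids <- sort(unique(lab[lab > 0L]))
  trees <- do.call(rbind, lapply(ids, function(id) {
    cells <- which(lab == id)
    h <- v[cells]
    h[is.na(h)] <- -Inf
    apex <- cells[order(-h, ((cells - 1) %% nr) + 1, (cells - 1) %/% nr)][1]
    ai <- ((apex - 1) %% nr) + 1L
    aj <- ((apex - 1) %/% nr) + 1L
    data.frame(tree_id = id,
               apex_x = chm$origin[1] + (aj - 0.5) * chm$gsd,
               apex_y = chm$origin[2] + (ai - 0.5) * chm$gsd,
               apex_height = v[apex])
  }))
  labr <- height_raster(lab, chm$origin, chm$gsd)
  labr$bands <- "label"
  structure(list(labels = labr, trees = trees), class = "tree_segmentation")
}

#' @export
print.tree_segmentation <- function(x, ...) {
  cat(sprintf("<tree_segmentation: %d trees>\n", nrow(x$trees)))
  invisible(x)
}

#' Match segmented trees to reference stem positions
#'
#' Greedy nearest-apex matching within `max_dist`, used to link segmentation
#' labels to measured (or simulated) trees.
#'
#' @param segmentation A [segment_trees()] result.
#' @param reference Data frame with `tree_id`, `x`, `y`.
#' @param max_dist Maximum apex-to-stem distance in metres.
#' @return Data frame with `seg_id`, `tree_id`, `dist`.
#' @export
match_trees <- function(segmentation, reference, max_dist = 3) {
  seg <- segmentation$trees
  if (nrow(seg) == 0 || nrow(reference) == 0)
    return(data.frame(seg_id = integer(), tree_id = integer(),
                      dist = numeric()))
  d <- outer(seq_len(nrow(seg)), seq_len(nrow(reference)), function(a, b) {
    sqrt((seg$apex_x[a] - reference$x[b])^2 +
           (seg$apex_y[a] - reference$y[b])^2)
  })
  out <- list()
  while (TRUE) {
    m <- which(d == min(d), arr.ind = TRUE)[1, , drop = FALSE]
    if (d[m] > max_dist || !is.finite(d[m])) break
    out[[length(out) + 1]] <- data.frame(seg_id = seg$tree_id[m[1]],
                                         tree_id = reference$tree_id[m[2]],
                                         dist = d[m])
    d[m[1], ] <- Inf
    d[, m[2]] <- Inf
    if (all(!is.finite(d))) break
  }
  if (!length(out))
    return(data.frame(seg_id = integer(), tree_id = integer(),
                      dist = numeric()))
  do.call(rbind, out)
}
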