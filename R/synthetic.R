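# Synthetic plantation scenes with known geometry, reflectance and light
# extinction. Crowns are right circular cones (apex at tree height, base at
# the ground) with vertically uniform leaf-area density, so the cumulative
# leaf area above height z is L(z) = LAI * (h - z) / h and transmitted PAR
# follows Beer-Lambert extinction T(z) = exp(-k * L(z)).

# evaluate `code` under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Configuration of a synthetic plantation stand
#'
#' Defaults mirror a gridded conifer seed orchard: trees on a 6 m x 8 m
#' lattice, 20 half-sib families assigned in randomized blocks, canopy height
#' around 18 m. `lai_mean` and `extinction_k` set the Beer-Lambert light
#' climate; their defaults (5 m2/m2, 0.7) describe a dense needle-leaf canopy
#' whose per-layer absorbed fractions decrease monotonically from the upper
#' to the lower stratum.
#'
#' @param n_rows,n_cols Grid dimensions (0 allowed: empty stand).
#' @param spacing_x,spacing_y Tree spacing in metres (> 0).
#' @param n_families Number of half-sib families (>= 1).
#' @param height_mean,height_sd Tree height distribution (m).
#' @param crown_radius_ratio Crown radius as a fraction of tree height.
#' @param lai_mean Mean leaf area index (m2/m2).
#' @param extinction_k Beer-Lambert extinction coefficient (> 0).
#' @param seed Integer seed; all stand randomness flows from it.
#' @return A `stand_config` list.
#' @export
stand_config <- function(n_rows = 8, n_cols = 10, spacing_x = 6, spacing_y = 8,
                         n_families = 20, height_mean = 18, height_sd = 1,
                         crown_radius_ratio = 0.15, lai_mean = 5,
                         extinction_k = 0.7, seed = 1) {
  if (n_rows < 0 || n_cols < 0)
    stop_voxfpar("grid dimensions must be non-negative", "voxfpar_config_error")
  if (spacing_x <= 0 || spacing_y <= 0)
    stop_voxfpar("tree spacing must be positive", "voxfpar_config_error")
  if (height_sd < 0 || extinction_k <= 0 || n_families < 1 ||
      crown_radius_ratio <= 0 || lai_mean <= 0)
    stop_voxfpar("invalid stand configuration", "voxfpar_config_error")
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 spacing_x = spacing_x, spacing_y = spacing_y,
                 n_families = as.integer(n_families),
                 height_mean = height_mean, height_sd = height_sd,
                 crown_radius_ratio = crown_radius_ratio, lai_mean = lai_mean,
                 extinction_k = extinction_k, seed = as.integer(seed)),
            class = "stand_config")
}

# cumulative leaf area above z and Beer-Lambert transmittance for one tree
leaf_area_above <- function(z, height, lai) lai * pmax(0, height - pmax(z, 0)) / height
transmittance <- function(z, height, lai, k) exp(-k * leaf_area_above(z, height, lai))

# noiseless per-layer absorbed fractions at the three sensor heights,
# relative to incident PAR at the top sensor (albedo zero)
layer_fpar_true <- function(height, lai, k, sensor_heights) {
  tu <- transmittance(sensor_heights[1], height, lai, k)
  tm <- transmittance(sensor_heights[2], height, lai, k)
  tg <- transmittance(sensor_heights[3], height, lai, k)
  cbind(upper = (tu - tm) / tu, middle = (tm - tg) / tu, lower = tg / tu)
}

#' Generate a synthetic stand scene
#'
#' Trees sit on the configured lattice with positional jitter of at most 10%
#' of the spacing; families are assigned in randomized blocks of
#' `n_families` consecutive lattice positions. Each family carries a mean
#' chlorophyll level, each tree adds noise around it; tree LAI increases
#' monotonically with chlorophyll so that canopy reflectance and light
#' absorption are coupled. True per-stratum fPAR is the noiseless
#' Beer-Lambert layer absorption at the default quantum-sensor heights
#' (20, 10, 4 m).
#'
#' @param config A [stand_config()].
#' @param sensor_heights Heights (m, decreasing) at which true stratum fPAR
#'   is evaluated.
#' @param ground Ground plane `list(intercept, slope_x, slope_y)`; elevation
#'   is `intercept + slope_x * x + slope_y * y`.
#' @return A `stand_scene` with elements `trees`, `ground`, `extent`,
#'   `sensor_heights`, `true_stratum_fpar` and the `config`.
#' @export
generate_stand <- function(config,
                           sensor_heights = c(20, 10, 4),
                           ground = list(intercept = 0, slope_x = 0.004,
                                         slope_y = -0.003)) {
  stopifnot(inherits(config, "stand_config"))
  stopifnot(length(sensor_heights) == 3, all(diff(sensor_heights) < 0))
  n <- config$n_rows * config$n_cols
  with_seed(config$seed, {
    if (n == 0) {
      trees <- data.frame(tree_id = integer(), family_id = integer(),
                          x = numeric(), y = numeric(), height = numeric(),
                          crown_radius = numeric(), lai = numeric(),
                          chlorophyll_level = numeric())
    } else {
      ij <- expand.grid(col = seq_len(config$n_cols), row = seq_len(config$n_rows))
      x0 <- (ij$col - 0.5) * config$spacing_x
      y0 <- (ij$row - 0.5) * config$spacing_y
      jx <- runif(n, -0.1, 0.1) * config$spacing_x
      jy <- runif(n, -0.1, 0.1) * config$spacing_y
      # randomized blocks: consecutive runs of n_families positions each get
      # one tree of every family, in a block-specific random order
      fam <- integer(n)
      blocks <- split(seq_len(n), (seq_len(n) - 1) %/% config$n_families)
      for (b in blocks)
        fam[b] <- sample(config$n_families)[seq_along(b)]
      fam_chl <- runif(config$n_families, 0.45, 0.55)
      chl <- pmin(0.95, pmax(0.05, fam_chl[fam] + rnorm(n, 0, 0.02)))
      height <- pmax(1, rnorm(n, config$height_mean, config$height_sd))
      lai <- config$lai_mean * (0.85 + 0.3 * chl) * exp(rnorm(n, 0, 0.02))
      # per-tree visible-band illumination/background factor: scales the
      # 450/560/650 nm bands only, leaving red-edge indices clean
      brightness <- exp(rnorm(n, 0, 0.10))
      trees <- data.frame(tree_id = seq_len(n), family_id = fam,
                          x = x0 + jx, y = y0 + jy, height = height,
                          crown_radius = config$crown_radius_ratio * height,
                          lai = lai, chlorophyll_level = chl,
                          brightness = brightness)
    }
    margin <- if (n == 0) 2 else max(trees$crown_radius) + 1
    extent <- c(xmin = -margin, xmax = config$n_cols * config$spacing_x + margin,
                ymin = -margin, ymax = config$n_rows * config$spacing_y + margin)
    tf <- if (n == 0) {
      data.frame(tree_id = integer(), stratum = character(), fpar = numeric())
    } else {
      f <- layer_fpar_true(trees$height, trees$lai, config$extinction_k,
                           sensor_heights)
      data.frame(tree_id = rep(trees$tree_id, 3),
                 stratum = rep(c("upper", "middle", "lower"), each = n),
                 fpar = c(f[, "upper"], f[, "middle"], f[, "lower"]))
    }
    structure(list(trees = trees, ground = ground, extent = extent,
                   sensor_heights = sensor_heights, true_stratum_fpar = tf,
                   config = config),
              class = "stand_scene")
  })
}

#' @export
print.stand_scene <- function(x, ...) {
  cat(sprintf("<stand_scene: %d trees, %d families, extent %.0f x %.0f m>\n",
              nrow(x$trees), length(unique(x$trees$family_id)),
              diff(x$extent[1:2]), diff(x$extent[3:4])))
  invisible(x)
}

ground_elevation <- function(scene, x, y)
  scene$ground$intercept + scene$ground$slope_x * x + scene$ground$slope_y * y

#' Sample a LiDAR point cloud from a scene
#'
#' Returns are drawn on each cone's surface (Poisson count at `point_density`
#' over the crown footprint, plus one guaranteed apex return) and in its
#' interior (at 40% of the surface density, uniformly between 25% and 100% of
#' the local surface height), together with ground returns over the whole
#' extent. All elevations receive Gaussian vertical noise. Ground points are
#' written with LAS classification 2, which downstream tests use as the
#' ground-truth oracle.
#'
#' @param scene A [generate_stand()] scene.
#' @param point_density Returns per square metre (> 0).
#' @param noise_sd Vertical noise standard deviation (m).
#' @param seed Integer seed.
#' @return A [point_cloud()] in absolute elevations.
#' @export
sample_point_cloud <- function(scene, point_density = 30, noise_sd = 0.03,
                               seed = 1) {
  stopifnot(inherits(scene, "stand_scene"))
  if (point_density <= 0)
    stop_voxfpar("point density must be positive", "voxfpar_config_error")
  ex <- scene$extent
  with_seed(seed, {
    area <- diff(ex[1:2]) * diff(ex[3:4])
    ng <- rpois(1, point_density * area)
    gx <- runif(ng, ex[1], ex[2]); gy <- runif(ng, ex[3], ex[4])
    xs <- list(gx); ys <- list(gy)
    zs <- list(ground_elevation(scene, gx, gy))
    cls <- list(rep(2L, ng))
    for (t in seq_len(nrow(scene$trees))) {
      tr <- scene$trees[t, ]
      a <- pi * tr$crown_radius^2
      ns <- rpois(1, point_density * a)
      ni <- rpois(1, 0.4 * point_density * a)
      d <- tr$crown_radius * sqrt(runif(ns + ni))
      th <- runif(ns + ni, 0, 2 * pi)
      px <- tr$x + d * cos(th); py <- tr$y + d * sin(th)
      zsurf <- tr$height * (1 - d / tr$crown_radius)
      pz <- c(zsurf[seq_len(ns)],
              runif(ni, 0.25, 1) * zsurf[ns + seq_len(ni)])
      # guaranteed apex return
      px <- c(px, tr$x); py <- c(py, tr$y); pz <- c(pz, tr$height)
      keep <- px >= ex[1] & px <= ex[2] & py >= ex[3] & py <= ex[4]
      xs[[t + 1]] <- px[keep]; ys[[t + 1]] <- py[keep]
      zs[[t + 1]] <- pz[keep] + ground_elevation(scene, px[keep], py[keep])
      cls[[t + 1]] <- rep(1L, sum(keep))
    }
    x <- unlist(xs); y <- unlist(ys); z <- unlist(zs)
    z <- z + rnorm(length(z), 0, noise_sd)
    point_cloud(x, y, z, classification = unlist(cls),
                return_number = rep(1L, length(x)))
  })
}

# five-band foliage spectrum as a monotone function of effective chlorophyll
foliage_spectrum <- function(chl_eff) {
  cbind(R450 = 0.05 - 0.02 * chl_eff,
        R560 = 0.12 - 0.04 * chl_eff,
        R650 = 0.08 - 0.05 * chl_eff,
        R730 = 0.35 - 0.20 * chl_eff,
        R840 = 0.45 + 0.15 * chl_eff)
}

SOIL_SPECTRUM <- c(R450 = 0.10, R560 = 0.16, R650 = 0.22, R730 = 0.26,
                   R840 = 0.30)

#' Render a five-band orthomosaic of a scene
#'
#' Pixels inside a crown footprint take a foliage spectrum driven by the
#' tree's chlorophyll level scaled by relative surface height (sunlit apex
#' foliage expresses more chlorophyll than shaded crown edges), so the
#' red-edge chlorophyll index RECI increases with both chlorophyll level and
#' surface height. Background pixels take a fixed soil spectrum. Where crowns
#' overlap, the higher surface wins. Band centres: 450, 560, 650, 730,
#' 840 nm; all values lie in [0, 1].
#'
#' @param scene A [generate_stand()] scene.
#' @param gsd Ground sampling distance in metres (> 0).
#' @param noise_sd Multiplicative reflectance noise standard deviation
#'   (0 = noiseless).
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @return A [band_raster()] with bands R450, R560, R650, R730, R840.
#' @export
render_orthomosaic <- function(scene, gsd = 0.1, noise_sd = 0, seed = 1) {
  stopifnot(inherits(scene, "stand_scene"))
  if (gsd <= 0) stop_voxfpar("gsd must be positive", "voxfpar_config_error")
  ex <- scene$extent
  ncol_ <- max(1L, as.integer(round(diff(ex[1:2]) / gsd)))
  nrow_ <- max(1L, as.integer(round(diff(ex[3:4]) / gsd)))
  xc <- ex[1] + (seq_len(ncol_) - 0.5) * gsd
  yc <- ex[3] + (seq_len(nrow_) - 0.5) * gsd
  zsurf <- matrix(0, nrow_, ncol_)   # canopy surface height above ground
  chl_eff <- matrix(NA_real_, nrow_, ncol_)
  bright <- matrix(NA_real_, nrow_, ncol_)
  for (t in seq_len(nrow(scene$trees))) {
    tr <- scene$trees[t, ]
    jr <- which(xc >= tr$x - tr$crown_radius & xc <= tr$x + tr$crown_radius)
    ir <- which(yc >= tr$y - tr$crown_radius & yc <= tr$y + tr$crown_radius)
    if (!length(jr) || !length(ir)) next
    d <- sqrt(outer(yc[ir] - tr$y, xc[jr] - tr$x,
                    function(a, b) a^2 + b^2))
    zt <- tr$height * (1 - d / tr$crown_radius)
    zt[d >= tr$crown_radius] <- 0
    sub <- zsurf[ir, jr, drop = FALSE]
    win <- zt > sub
    if (any(win)) {
      sub[win] <- zt[win]
      zsurf[ir, jr] <- sub
      ce <- chl_eff[ir, jr, drop = FALSE]
      rel <- zt / tr$height
      # sunlit apex foliage expresses more chlorophyll than shaded edges
      ce[win] <- tr$chlorophyll_level * (0.15 + 0.85 * rel[win])
      chl_eff[ir, jr] <- ce
      br <- bright[ir, jr, drop = FALSE]
      br[win] <- if ("brightness" %in% names(tr)) tr$brightness else 1
      bright[ir, jr] <- br
    }
  }
  vals <- array(0, c(nrow_, ncol_, 5))
  soil <- is.na(chl_eff)
  fol <- foliage_spectrum(as.vector(chl_eff[!soil]))
  vis <- as.vector(bright[!soil])
  for (b in 1:5) {
    m <- matrix(SOIL_SPECTRUM[b], nrow_, ncol_)
    f <- fol[, b]
    if (b <= 3) f <- f * vis   # visible bands carry the brightness factor
    m[!soil] <- f
    vals[, , b] <- m
  }
  if (noise_sd > 0) {
    vals <- with_seed(seed, vals * (1 + array(rnorm(length(vals), 0, noise_sd),
                                              dim(vals))))
  }
  vals[] <- pmin(1, pmax(0, vals))
  band_raster(vals, origin = c(ex[1], ex[3]), gsd = gsd,
              bands = names(SOIL_SPECTRUM))
}

#' Simulate six-component quantum-sensor PAR readings
#'
#' For every tree and cardinal direction, incident PAR at the three sensor
#' heights follows Beer-Lambert extinction through the cumulative leaf area
#' above the sensor; reflected components are a fixed albedo fraction of the
#' local incident component. Each reading receives independent multiplicative
#' Gaussian noise. The attached `true_fpar` attribute holds the noiseless,
#' albedo-free per-layer absorbed fractions for these sensor heights.
#'
#' @param scene A [generate_stand()] scene.
#' @param incident_par Above-canopy PAR (umol m-2 s-1, > 0).
#' @param sensor_heights Upper, middle, lower sensor heights (m, strictly
#'   decreasing).
#' @param albedo Reflected fraction per level (default 0.05).
#' @param noise_sd Multiplicative noise standard deviation (0 = noiseless).
#' @param date Measurement date label carried into the output.
#' @param seed Integer seed.
#' @return A data frame with one row per tree x direction and columns
#'   `tree_id`, `date`, `direction`, `PAR_ci`, `PAR_cr`, `PAR_mi`, `PAR_mr`,
#'   `PAR_gi`, `PAR_gr`; attribute `true_fpar` holds the noiseless stratum
#'   fPAR table.
#' @export
simulate_par <- function(scene, incident_par = 1800,
                         sensor_heights = c(20, 10, 4), albedo = 0.05,
                         noise_sd = 0.05, date = "2024-06-15", seed = 1) {
  stopifnot(inherits(scene, "stand_scene"))
  if (incident_par <= 0)
    stop_voxfpar("incident PAR must be positive", "voxfpar_config_error")
  if (!all(diff(sensor_heights) < 0))
    stop_voxfpar("sensor heights must be strictly decreasing", "voxfpar_config_error")
  k <- scene$config$extinction_k
  trees <- scene$trees
  n <- nrow(trees)
  dirs <- c(0, 90, 180, 270)
  if (n == 0) {
    out <- data.frame(tree_id = integer(), date = character(),
                      direction = numeric(), PAR_ci = numeric(),
                      PAR_cr = numeric(), PAR_mi = numeric(),
                      PAR_mr = numeric(), PAR_gi = numeric(),
                      PAR_gr = numeric())
    attr(out, "true_fpar") <- data.frame(tree_id = integer(),
                                         stratum = character(),
                                         fpar = numeric())
    return(out)
  }
  ci0 <- incident_par * transmittance(sensor_heights[1], trees$height, trees$lai, k)
  mi0 <- incident_par * transmittance(sensor_heights[2], trees$height, trees$lai, k)
  gi0 <- incident_par * transmittance(sensor_heights[3], trees$height, trees$lai, k)
  base <- data.frame(tree_id = rep(trees$tree_id, each = 4),
                     date = date,
                     direction = rep(dirs, n),
                     PAR_ci = rep(ci0, each = 4),
                     PAR_cr = rep(albedo * ci0, each = 4),
                     PAR_mi = rep(mi0, each = 4),
                     PAR_mr = rep(albedo * mi0, each = 4),
                     PAR_gi = rep(gi0, each = 4),
                     PAR_gr = rep(albedo * gi0, each = 4))
  if (noise_sd > 0) {
    base <- with_seed(seed, {
      for (cc in c("PAR_ci", "PAR_cr", "PAR_mi", "PAR_mr", "PAR_gi", "PAR_gr"))
        base[[cc]] <- pmax(0, base[[cc]] * (1 + rnorm(nrow(base), 0, noise_sd)))
      base
    })
  }
  f <- layer_fpar_true(trees$height, trees$lai, k, sensor_heights)
  attr(base, "true_fpar") <- data.frame(
    tree_id = rep(trees$tree_id, 3),
    stratum = rep(c("upper", "middle", "lower"), each = n),
    fpar = c(f[, "upper"], f[, "middle"], f[, "lower"]))
  base
}

#' Write PAR measurements as a long-format CSV
#'
#' Columns: `tree_id`, `date`, `direction_deg`, `level` (top/middle/base),
#' `orientation` (incident/reflected), `par_value`.
#'
#' @param par Wide table from [simulate_par()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_par_csv <- function(par, path) {
  comp <- c(PAR_ci = "top.incident", PAR_cr = "top.reflected",
            PAR_mi = "middle.incident", PAR_mr = "middle.reflected",
            PAR_gi = "base.incident", PAR_gr = "base.reflected")
  rows <- lapply(names(comp), function(cc) {
    lv <- strsplit(comp[[cc]], ".", fixed = TRUE)[[1]]
    data.frame(tree_id = par$tree_id, date = par$date,
               direction_deg = par$direction, level = lv[1],
               orientation = lv[2], par_value = par[[cc]])
  })
  long <- do.call(rbind, rows)
  long <- long[order(long$tree_id, long$date, long$direction_deg,
                     long$level, long$orientation), ]
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Read a long-format PAR CSV back into the wide component layout
#'
#' @param path CSV path written by [write_par_csv()].
#' @return Wide data frame as produced by [simulate_par()].
#' @export
read_par_csv <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("tree_id", "date", "direction_deg", "level", "orientation",
            "par_value")
  if (!all(need %in% names(long)))
    stop_voxfpar("PAR CSV missing required columns", "voxfpar_format_error")
  key <- paste0("PAR_", substr(long$level, 1, 1), substr(long$orientation, 1, 1))
  key <- sub("PAR_t", "PAR_c", key)  # top -> canopy naming
  key <- sub("PAR_b", "PAR_g", key)  # base -> ground naming
  wide <- stats::reshape(
    data.frame(tree_id = long$tree_id, date = long$date,
               direction = long$direction_deg, comp = key,
               par_value = long$par_value),
    idvar = c("tree_id", "date", "direction"), timevar = "comp",
    direction = "wide")
  names(wide) <- sub("^par_value\\.", "", names(wide))
  rownames(wide) <- NULL
  wide[order(wide$tree_id, wide$date, wide$direction), ]
}

#' Write a scene manifest recording all ground truth
#'
#' @param scene A [generate_stand()] scene.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_scene_manifest <- function(scene, path) {
  yaml::write_yaml(list(
    config = unclass(scene$config),
    ground = scene$ground,
    extent = as.list(scene$extent),
    sensor_heights = scene$sensor_heights,
    trees = lapply(seq_len(nrow(scene$trees)),
                   function(i) as.list(scene$trees[i, ])),
    true_stratum_fpar = lapply(seq_len(nrow(scene$true_stratum_fpar)),
                               function(i) as.list(scene$true_stratum_fpar[i, ]))),
    path, precision = 15)
  invisible(path)
}
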