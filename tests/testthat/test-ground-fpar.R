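par_row <- function(ci, cr, mi, mr, gi, gr, tree = 1, date = "2024-06-15",
                    dir = 0) {
  data.frame(tree_id = tree, date = date, direction = dir, PAR_ci = ci,
             PAR_cr = cr, PAR_mi = mi, PAR_mr = mr, PAR_gi = gi, PAR_gr = gr)
}

test_that("direction averaging is a component-wise mean", {
  recs <- do.call(rbind, lapply(c(0, 90, 180, 270), function(d)
    par_row(1000, 50, 300, 20, 100, 5, dir = d)))
  avg <- average_directions(recs)
  expect_equal(nrow(avg), 1)
  expect_equal(avg$PAR_ci, 1000)
  expect_equal(avg$n_directions, 4L)

  recs$PAR_ci <- c(1000, 1100, 900, 1000)
  expect_equal(average_directions(recs)$PAR_ci, 1000)

  one <- average_directions(par_row(800, 10, 200, 5, 50, 2))
  expect_equal(one$n_directions, 1L)
  expect_equal(one$PAR_gi, 50)
  expect_error(average_directions(par_row(1, 0, 0, 0, 0, 0)[0, ]),
               class = "voxfpar_data_error")
})

test_that("the whole-canopy balance reproduces worked values and flags invalid records", {
  m <- par_row(1000, 50, 300, 20, 100, 5)
  out <- compute_apar_fpar(m, mode = "three_layer")
  expect_equal(out$apar, 575, tolerance = 1e-12)
  expect_equal(out$fpar, 0.575, tolerance = 1e-12)
  expect_true(out$valid)

  total <- compute_apar_fpar(par_row(1000, 0, 0, 0, 0, 0), mode = "three_layer")
  expect_equal(total$fpar, 1)

  # the printed balance double-subtracts pass-through flux: fPAR = -1
  passthrough <- compute_apar_fpar(par_row(1000, 0, 1000, 0, 1000, 0),
                                   mode = "three_layer")
  expect_equal(passthrough$fpar, -1)
  expect_false(passthrough$valid)
  # the two-layer balance keeps the same record physical
  two <- compute_apar_fpar(par_row(1000, 0, 1000, 0, 1000, 0),
                           mode = "two_layer")
  expect_equal(two$fpar, 0)
  expect_true(two$valid)
  expect_error(compute_apar_fpar(par_row(0, 0, 0, 0, 0, 0)),
               class = "voxfpar_data_error")
})

test_that("layer fPAR differencing splits the balance across strata", {
  z <- compute_layer_fpar(par_row(1000, 0, 1000, 0, 1000, 0))
  expect_equal(z$fpar[z$stratum %in% c("upper", "middle")], c(0, 0))

  m <- par_row(1000, 0, 400, 0, 100, 0)
  out <- compute_layer_fpar(m)
  expect_equal(out$fpar[out$stratum == "upper"], 0.6, tolerance = 1e-12)
  expect_equal(out$fpar[out$stratum == "middle"], 0.3, tolerance = 1e-12)
  expect_equal(out$fpar[out$stratum == "lower"], 0.1, tolerance = 1e-12)
  expect_equal(sum(out$fpar), 1, tolerance = 1e-12)
  # floor transmission reduces only the lower layer
  out2 <- compute_layer_fpar(m, tau_floor = 0.2)
  expect_equal(out2$fpar[out2$stratum == "lower"], 0.08, tolerance = 1e-12)
})

test_that("simulated components invert to true layer absorption within 1e-9", {
  sc <- generate_stand(stand_config(n_rows = 2, n_cols = 3, seed = 33))
  par <- simulate_par(sc, albedo = 0, noise_sd = 0)
  avg <- average_directions(par)
  rec <- compute_layer_fpar(avg)
  truth <- attr(par, "true_fpar")
  key <- function(d) paste(d$tree_id, d$stratum)
  rec <- rec[order(key(rec)), ]
  truth <- truth[order(key(truth)), ]
  expect_equal(rec$fpar, truth$fpar, tolerance = 1e-9)
})

test_that("percentile thresholds use linear interpolation and reject degenerate stands", {
  thr <- derive_thresholds(c(10, 12, 14, 16, 18, 20, 22, 24))
  expect_equal(thr$t_upper, 20.5, tolerance = 1e-12)
  expect_equal(thr$t_lower, 15.6, tolerance = 1e-12)
  # permutation invariance
  thr2 <- derive_thresholds(rev(c(10, 12, 14, 16, 18, 20, 22, 24)))
  expect_identical(thr, thr2)
  # monotone in the percentile argument
  lo <- derive_thresholds(c(10, 12, 14, 16, 18, 20, 22, 24), 60, 30)
  expect_lt(lo$t_upper, thr$t_upper)
  expect_lt(lo$t_lower, thr$t_lower)
  expect_error(derive_thresholds(rep(18, 5)),
               class = "voxfpar_degenerate_error")
  expect_error(derive_thresholds(numeric()), class = "voxfpar_data_error")
})

test_that("stratum assignment partitions heights with the published boundaries", {
  tab <- data.frame(z = c(16, 15, 14.99, 7, 6.99, 0.5))
  out <- assign_strata(tab, list(t_upper = 15, t_lower = 7))
  expect_identical(out$stratum,
                   c("upper", "upper", "middle", "middle", "lower", "lower"))
  expect_false(anyNA(out$stratum))
})

test_that("voxel labelling assigns measured-tree fPAR by stratum and skips background", {
  lab <- matrix(0L, 10, 10)
  lab[1:5, 1:5] <- 1L       # one segmented tree in the south-west corner
  seg <- structure(list(labels = height_raster(lab, c(0, 0), 1),
                        trees = data.frame(tree_id = 1L, apex_x = 2.5,
                                           apex_y = 2.5, apex_height = 18)),
                   class = "tree_segmentation")
  vox <- expand.grid(x = c(2.5, 7.5), z = c(16, 10, 3))
  vox$y <- vox$x
  vox <- compute_indices(within(vox, {
    R450 <- 0.04; R560 <- 0.08; R650 <- 0.06; R730 <- 0.3; R840 <- 0.5
  }))
  vox <- assign_strata(vox, list(t_upper = 15, t_lower = 7))
  sf <- data.frame(tree_id = 1L, date = "d",
                   stratum = c("upper", "middle", "lower"),
                   fpar = c(0.9, 0.7, 0.5))
  out <- label_voxels(vox, sf, seg)
  inside <- out$voxels$x == 2.5
  expect_equal(out$voxels$fpar_label[inside & out$voxels$z == 16], 0.9)
  expect_equal(out$voxels$fpar_label[inside & out$voxels$z == 10], 0.7)
  expect_equal(out$voxels$fpar_label[inside & out$voxels$z == 3], 0.5)
  expect_true(all(is.na(out$voxels$fpar_label[!inside])))
  expect_equal(nrow(out$training), 3)
})

test_that("labelled voxel counts match a brute-force column census", {
  cfg <- get_demo_run()
  lab <- utils::read.csv(file.path(cfg$out_dir, "labelled.csv"))
  labels <- read_raster(file.path(cfg$out_dir, "seg_labels.tif"))
  scene <- voxfpar:::scene_from_manifest(file.path(cfg$out_dir, "scene.yaml"))
  seg_trees <- utils::read.csv(file.path(cfg$out_dir, "seg_trees.csv"))
  # independent census: nearest-stem mapping of segments, then a per-voxel
  # lookup of the label raster
  expected <- 0L
  for (r in seq_len(nrow(lab))) {
    jj <- floor((lab$x[r] - labels$origin[1]) / labels$gsd) + 1
    ii <- floor((lab$y[r] - labels$origin[2]) / labels$gsd) + 1
    if (ii < 1 || jj < 1 || ii > dim(labels$values)[1] ||
        jj > dim(labels$values)[2]) next
    sid <- labels$values[ii, jj, 1]
    if (is.na(sid) || sid == 0) next
    st <- seg_trees[seg_trees$tree_id == sid, ]
    d <- sqrt((scene$trees$x - st$apex_x)^2 + (scene$trees$y - st$apex_y)^2)
    if (min(d) <= 3) expected <- expected + 1L
  }
  expect_equal(sum(!is.na(lab$fpar_label)), expected)
  expect_gt(sum(!is.na(lab$fpar_label)), 0)
})
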