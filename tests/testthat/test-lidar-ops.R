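test_that("ground classification flags flat ground fully and recalls synthetic ground", {
  set.seed(21)
  flat <- point_cloud(runif(500, 0, 30), runif(500, 0, 30), rep(50, 500))
  cls <- classify_ground(flat, cell = 2, tolerance = 0.3)
  expect_true(all(cls$classification == 2L))

  sc <- generate_stand(stand_config(n_rows = 2, n_cols = 3, seed = 13))
  pc <- sample_point_cloud(sc, 20, noise_sd = 0.03, seed = 13)
  truth <- pc$classification == 2L
  pc$classification <- NULL
  cls <- classify_ground(pc, cell = 2, tolerance = 0.3)
  recall <- mean(cls$classification[truth] == 2L)
  expect_gte(recall, 0.95)

  col <- point_cloud(rep(1, 5), rep(1, 5), c(3, 10, 0.2, 7, 15))
  cls <- classify_ground(col, cell = 2, tolerance = 0.3)
  expect_identical(which(cls$classification == 2L), 3L)
})

test_that("height normalization subtracts the ground surface and applies the drop/clamp rule", {
  set.seed(22)
  g <- point_cloud(runif(400, 0, 20), runif(400, 0, 20), rep(100, 400))
  g <- classify_ground(g, cell = 2, tolerance = 0.1)
  # canopy return, a slightly sub-surface return and a far sub-surface return
  extra <- point_cloud(c(5, 7, 9), c(5, 7, 9), c(120, 99.95, 99.4),
                       classification = c(1L, 1L, 1L))
  pc <- rbind(g, extra)
  class(pc) <- c("point_cloud", "data.frame")
  out <- normalize_heights(pc)
  # canopy point at 120 over flat 100 m ground
  expect_equal(max(out$z), 20, tolerance = 1e-9)
  # point 0.6 m below the surface is dropped
  expect_equal(nrow(out), nrow(pc) - 1)
  # point 0.05 m below is clamped to zero
  expect_true(all(out$z >= 0))
  # idempotence: normalizing an already-normalized cloud is a no-op
  again <- normalize_heights(classify_ground(out, cell = 2, tolerance = 0.1))
  expect_equal(sort(again$z), sort(out$z), tolerance = 1e-9)
})

test_that("normalized apex heights recover true tree heights on a sloped scene", {
  noise <- 0.03
  sc <- generate_stand(stand_config(n_rows = 2, n_cols = 3, seed = 17))
  pc <- sample_point_cloud(sc, 25, noise_sd = noise, seed = 17)
  pc$classification <- NULL
  pc <- classify_ground(pc, cell = 2, tolerance = 0.3)
  out <- normalize_heights(pc)
  for (t in seq_len(nrow(sc$trees))) {
    tr <- sc$trees[t, ]
    near <- out$z[(out$x - tr$x)^2 + (out$y - tr$y)^2 < 1]
    expect_lt(abs(max(near) - tr$height), 2 * noise + 0.05)
  }
})

test_that("CHM equals the brute-force per-cell maximum exactly", {
  empty <- rasterize_chm(point_cloud(), gsd = 1)
  expect_true(all(is.na(empty$values)))

  one <- point_cloud(c(0.2, 0.3, 0.4), c(0.2, 0.3, 0.4), c(1.0, 3.5, 19.2))
  chm <- rasterize_chm(one, gsd = 1)
  expect_equal(as.numeric(chm$values[1, 1, 1]), 19.2)

  for (s in 1:5) {
    pc <- rand_cloud(10000, seed = 100 + s)
    gsd <- c(0.5, 1, 2)[s %% 3 + 1]
    chm <- rasterize_chm(pc, gsd = gsd)
    oracle <- bf_chm(pc, gsd)
    expect_identical(dim(chm$values)[1:2], dim(oracle$values))
    expect_identical(as.vector(chm$values[, , 1]), as.vector(oracle$values))
  }
})

test_that("half-open cell binning is lower-edge inclusive", {
  pc <- point_cloud(c(1, 2 - 1e-9, 2), c(0.5, 0.5, 0.5), c(5, 6, 7))
  chm <- rasterize_chm(pc, gsd = 1)
  expect_equal(as.numeric(chm$values[1, , 1]), c(6, 7))
})

test_that("watershed segmentation recovers isolated cones", {
  sc <- generate_stand(stand_config(n_rows = 1, n_cols = 1, seed = 23),
                       ground = list(intercept = 0, slope_x = 0, slope_y = 0))
  pc <- sample_point_cloud(sc, 30, noise_sd = 0.02, seed = 23)
  pc <- normalize_heights(classify_ground(pc))
  chm <- rasterize_chm(pc, gsd = 0.5)
  seg <- segment_trees(chm, min_height = 2, min_distance = 4)
  expect_equal(nrow(seg$trees), 1)
  expect_lt(abs(seg$trees$apex_x - sc$trees$x), 0.5 + 1e-9)
  expect_lt(abs(seg$trees$apex_y - sc$trees$y), 0.5 + 1e-9)

  flat <- height_raster(matrix(0, 10, 10), c(0, 0), 1)
  seg0 <- segment_trees(flat, min_height = 2)
  expect_equal(nrow(seg0$trees), 0)
})

test_that("segment labels partition the above-threshold CHM", {
  sc <- generate_stand(stand_config(n_rows = 2, n_cols = 2, seed = 29))
  pc <- sample_point_cloud(sc, 20, noise_sd = 0.02, seed = 29)
  pc <- normalize_heights(classify_ground(pc))
  chm <- rasterize_chm(pc, gsd = 0.5)
  seg <- segment_trees(chm, min_height = 2, min_distance = 4)
  v <- chm$values[, , 1]
  lab <- seg$labels$values[, , 1]
  above <- !is.na(v) & v >= 2
  expect_true(all(lab[above] > 0))
  expect_true(all(lab[!above] == 0))
  # apex height equals the max CHM value within each segment
  for (id in seg$trees$tree_id)
    expect_equal(seg$trees$apex_height[seg$trees$tree_id == id],
                 max(v[lab == id], na.rm = TRUE))
})

test_that("insufficient data raises informative errors", {
  expect_error(classify_ground(point_cloud(1, 1, 1)),
               class = "voxfpar_data_error")
  pc <- point_cloud(1:5, 1:5, 1:5)
  expect_error(normalize_heights(pc), class = "voxfpar_data_error")
})
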