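test_that("stand generation follows the lattice with bounded jitter", {
  cfg <- stand_config(n_rows = 4, n_cols = 5, seed = 9)
  sc <- generate_stand(cfg)
  expect_equal(nrow(sc$trees), 20)
  lattice_x <- (rep(1:5, 4) - 0.5) * 6
  lattice_y <- (rep(1:4, each = 5) - 0.5) * 8
  expect_true(all(abs(sc$trees$x - lattice_x) <= 0.1 * 6 + 1e-12))
  expect_true(all(abs(sc$trees$y - lattice_y) <= 0.1 * 8 + 1e-12))
  expect_true(all(sc$trees$height > 0))
  expect_true(all(sc$true_stratum_fpar$fpar >= 0 &
                    sc$true_stratum_fpar$fpar <= 1))
  # randomized blocks: the 20-position block holds each family exactly once
  expect_equal(sort(sc$trees$family_id), 1:20)
})

test_that("empty stand yields a ground-only scene", {
  sc <- generate_stand(stand_config(n_rows = 0, n_cols = 5))
  expect_equal(nrow(sc$trees), 0)
  pc <- sample_point_cloud(sc, point_density = 5, noise_sd = 0, seed = 1)
  expect_true(all(pc$classification == 2L))
  expect_error(stand_config(n_rows = -1), class = "voxfpar_config_error")
})

test_that("scene generation is deterministic under a fixed seed", {
  a <- generate_stand(stand_config(seed = 123))
  b <- generate_stand(stand_config(seed = 123))
  expect_identical(a$trees, b$trees)
  expect_identical(a$true_stratum_fpar, b$true_stratum_fpar)
  pa <- sample_point_cloud(a, 8, 0.02, seed = 5)
  pb <- sample_point_cloud(b, 8, 0.02, seed = 5)
  expect_identical(pa, pb)
})

test_that("point cloud respects crown apex height and sampling density", {
  cfg <- stand_config(n_rows = 1, n_cols = 1, height_mean = 20,
                      height_sd = 0, seed = 2)
  sc <- generate_stand(cfg, ground = list(intercept = 0, slope_x = 0,
                                          slope_y = 0))
  noise <- 0.05
  pc <- sample_point_cloud(sc, 30, noise_sd = noise, seed = 3)
  expect_lt(abs(max(pc$z) - 20), 3 * noise + 1e-9)
  ex <- sc$extent
  expect_true(all(pc$x >= ex[1] & pc$x <= ex[2] &
                    pc$y >= ex[3] & pc$y <= ex[4]))
  # doubling the density doubles the expected count (Poisson)
  n1 <- nrow(sample_point_cloud(sc, 20, 0, seed = 4))
  n2 <- nrow(sample_point_cloud(sc, 40, 0, seed = 4))
  expect_lt(abs(n2 / n1 - 2), 0.2)
})

test_that("orthomosaic spectra are bounded and track chlorophyll", {
  sc0 <- generate_stand(stand_config(n_rows = 0, n_cols = 0))
  r0 <- render_orthomosaic(sc0, gsd = 0.5)
  for (b in 1:5)
    expect_true(all(abs(r0$values[, , b] -
                          voxfpar:::SOIL_SPECTRUM[b]) < 1e-12))
  sc <- generate_stand(stand_config(n_rows = 1, n_cols = 2, seed = 4))
  sc$trees$chlorophyll_level <- c(0.2, 0.9)
  sc$trees$brightness <- c(1, 1)
  r <- render_orthomosaic(sc, gsd = 0.1)
  expect_true(all(r$values >= 0 & r$values <= 1))
  reci <- r$values[, , 5] / r$values[, , 4] - 1
  crown_mean <- function(t) {
    xc <- sc$extent[1] + (seq_len(dim(r$values)[2]) - 0.5) * r$gsd
    yc <- sc$extent[3] + (seq_len(dim(r$values)[1]) - 0.5) * r$gsd
    d2 <- outer(yc - sc$trees$y[t], xc - sc$trees$x[t],
                function(a, b) a^2 + b^2)
    mean(reci[d2 < (0.7 * sc$trees$crown_radius[t])^2])
  }
  expect_gt(crown_mean(2), crown_mean(1))
  # gsd arithmetic: extent/gsd cells per side
  expect_equal(dim(r$values)[1:2],
               unname(round(c(diff(sc$extent[3:4]),
                              diff(sc$extent[1:2])) / 0.1)))
})

test_that("PAR simulation matches the Beer-Lambert closed form", {
  # uniform leaf-area density: LAI above 10 m equals 3 when h = 18 and
  # total LAI = 6.75, so transmission is exp(-0.5 * 3) = 0.22313
  cfg <- stand_config(n_rows = 1, n_cols = 1, height_mean = 18,
                      height_sd = 0, lai_mean = 6.75, extinction_k = 0.5,
                      seed = 6)
  sc <- generate_stand(cfg)
  sc$trees$lai <- 6.75
  par <- simulate_par(sc, incident_par = 1000, albedo = 0, noise_sd = 0)
  expect_equal(par$PAR_mi[1] / par$PAR_ci[1], exp(-1.5), tolerance = 1e-12)
  tf <- attr(par, "true_fpar")
  expect_equal(tf$fpar[tf$stratum == "upper"], 1 - exp(-1.5),
               tolerance = 1e-12)
  expect_equal(1 - exp(-1.5), 0.77687, tolerance = 1e-5)
  # zero noise: the four cardinal readings are identical
  expect_true(all(vapply(split(par$PAR_ci, par$tree_id),
                         function(v) diff(range(v)) == 0, logical(1))))
})

test_that("true stratum fPAR decreases from upper to lower under defaults", {
  for (s in 1:100) {
    sc <- generate_stand(stand_config(n_rows = 1, n_cols = 3, seed = s))
    f <- sc$true_stratum_fpar
    wide <- matrix(f$fpar, ncol = 3,
                   dimnames = list(NULL, c("upper", "middle", "lower")))
    expect_true(all(wide[, "upper"] >= wide[, "middle"] - 1e-12))
    expect_true(all(wide[, "middle"] >= wide[, "lower"] - 1e-12))
  }
})

test_that("PAR tables round-trip through the long CSV layout", {
  sc <- generate_stand(stand_config(n_rows = 1, n_cols = 3, seed = 8))
  par <- simulate_par(sc, noise_sd = 0.05, seed = 2)
  f <- tempfile(fileext = ".csv")
  write_par_csv(par, f)
  back <- read_par_csv(f)
  expect_equal(back$PAR_ci, par$PAR_ci, tolerance = 1e-12)
  expect_equal(back$PAR_gr, par$PAR_gr, tolerance = 1e-12)
  expect_equal(back$tree_id, par$tree_id)
})

test_that("scene manifest preserves ground truth", {
  sc <- generate_stand(stand_config(n_rows = 2, n_cols = 2, seed = 11))
  f <- tempfile(fileext = ".yaml")
  write_scene_manifest(sc, f)
  back <- voxfpar:::scene_from_manifest(f)
  expect_equal(back$trees$height, sc$trees$height, tolerance = 1e-9)
  expect_equal(back$true_stratum_fpar$fpar, sc$true_stratum_fpar$fpar,
               tolerance = 1e-9)
})
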