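# synthetic tree-level training table: y linear in NDVI unless overridden
make_training <- function(n_trees = 40, noise = 0, seed = 1,
                          y_fun = function(d) 0.2 + 0.6 * d$NDVI) {
  set.seed(seed)
  rows <- n_trees * 3
  tab <- data.frame(tree_id = rep(seq_len(n_trees), each = 3),
                    stratum = rep(c("upper", "middle", "lower"), n_trees))
  for (nm in vi_names()) tab[[nm]] <- runif(rows)
  tab$NDVI <- runif(rows)
  tab$fpar <- y_fun(tab) + rnorm(rows, 0, noise)
  tab
}

test_that("tree-level splits are exact, deterministic and disjoint", {
  tab <- make_training(100)
  sp <- split_data(tab, 0.8, seed = 4)
  expect_equal(length(unique(sp$calibration$tree_id)), 80)
  expect_equal(length(unique(sp$validation$tree_id)), 20)
  expect_length(intersect(sp$calibration$tree_id, sp$validation$tree_id), 0)
  sp2 <- split_data(tab, 0.8, seed = 4)
  expect_identical(sp, sp2)
  expect_error(split_data(make_training(4), 0.8),
               class = "voxfpar_data_error")
})

test_that("R2 and RMSE match a brute-force evaluation to 1e-12", {
  expect_equal(evaluate_predictions(c(0.2, 0.8), c(0.2, 0.8)),
               list(r2 = 1, rmse = 0))
  ev <- evaluate_predictions(c(0, 2), c(1, 1))
  expect_equal(ev$rmse, 1, tolerance = 1e-12)
  expect_equal(ev$r2, 0, tolerance = 1e-12)
  y <- c(0.3, 0.5, 0.7, 0.4)
  expect_equal(evaluate_predictions(y, rep(mean(y), 4))$r2, 0,
               tolerance = 1e-12)
  expect_true(is.na(evaluate_predictions(rep(1, 3), c(1, 2, 3))$r2))
  set.seed(71)
  for (rep_ in 1:20) {
    y <- runif(50); yh <- runif(50)
    ev <- evaluate_predictions(y, yh)
    o <- bf_r2_rmse(y, yh)
    expect_equal(ev$r2, o$r2, tolerance = 1e-12)
    expect_equal(ev$rmse, o$rmse, tolerance = 1e-12)
  }
})

test_that("every learner recovers an exact linear signal", {
  tab <- make_training(40, noise = 0, seed = 2)
  sp <- split_data(tab, 0.8, seed = 2)
  # projection/boosting learners interpolate a noiseless linear response
  # essentially exactly; RF averaging and the RBF kernel smooth it, so they
  # get a looser (still demanding) band
  floor_of <- c(RF = 0.8, XGBoost = 0.99, SVM = 0.8, PLSR = 0.99)
  for (alg in c("RF", "XGBoost", "SVM", "PLSR")) {
    m <- fpar_train(sp$calibration, algorithm = alg, cv_repeats = 0, seed = 2)
    ev <- evaluate_predictions(sp$validation$fpar, predict(m, sp$validation))
    expect_gte(ev$r2, floor_of[[alg]])
  }
})

test_that("permuted labels yield no out-of-sample skill", {
  r2s <- vapply(1:10, function(s) {
    tab <- make_training(40, noise = 0, seed = s)
    set.seed(s + 500)
    tab$fpar <- sample(tab$fpar)
    sp <- split_data(tab, 0.8, seed = s)
    m <- fpar_train(sp$calibration, algorithm = "RF", cv_repeats = 0,
                    seed = s)
    evaluate_predictions(sp$validation$fpar, predict(m, sp$validation))$r2
  }, numeric(1))
  expect_true(all(r2s <= 0.2))
})

test_that("a single-cell grid search equals the no-search fit", {
  tab <- make_training(30, noise = 0.05, seed = 3)
  m1 <- fpar_train(tab, algorithm = "RF", grid_search = FALSE,
                   cv_repeats = 0, seed = 9)
  m2 <- fpar_train(tab, algorithm = "RF", grid_search = TRUE,
                   grid = data.frame(n_trees = 300, mtry = 6),
                   cv_repeats = 1, cv_folds = 5, seed = 9)
  expect_identical(m1$hyper[order(names(m1$hyper))],
                   m2$hyper[order(names(m2$hyper))])
  expect_equal(m1$fitted, m2$fitted, tolerance = 1e-12)
})

test_that("grouped CV folds never split a tree", {
  tab <- make_training(25)
  folds <- voxfpar:::make_group_folds(tab$tree_id, 10, seed = 5)
  per_tree <- tapply(folds, tab$tree_id, function(f) length(unique(f)))
  expect_true(all(per_tree == 1))
  expect_equal(sort(unique(folds)), 1:10)
  expect_error(voxfpar:::make_group_folds(rep(1:3, 2), 10, 1),
               class = "voxfpar_data_error")
})

test_that("permutation importance finds planted signal and ignores null predictors", {
  tab <- make_training(60, noise = 0.02, seed = 6,
                       y_fun = function(d) 0.1 + 0.5 * d$RECI)
  sp <- split_data(tab, 0.8, seed = 6)
  m <- fpar_train(sp$calibration, algorithm = "RF", cv_repeats = 0, seed = 6)
  imp <- permutation_importance(m, sp$validation, seed = 6)
  expect_identical(imp$predictor[1], "RECI")
  null_scores <- imp$importance[imp$predictor != "RECI"]
  expect_true(all(abs(null_scores) < 0.2 * imp$importance[1]))
})

test_that("duplicated predictors share importance mass", {
  tab <- make_training(60, noise = 0.02, seed = 8,
                       y_fun = function(d) 0.1 + 0.5 * d$RECI)
  tab$NDRE <- tab$RECI  # exact duplicate column
  sp <- split_data(tab, 0.8, seed = 8)
  m <- fpar_train(sp$calibration, algorithm = "RF", cv_repeats = 0, seed = 8)
  imp <- permutation_importance(m, sp$validation, seed = 8)
  top2 <- imp$predictor[1:2]
  expect_setequal(top2, c("RECI", "NDRE"))
})

test_that("voxel predictions are clipped, flagged and column-consistent", {
  overshoot <- structure(list(
    algorithm = "RF", predictors = c("NDVI", "RECI"), response = "fpar",
    scaling = NULL,
    learner = list(predict = function(M) rep(1.3, nrow(M)))),
    class = "fpar_model")
  tab <- data.frame(NDVI = c(0.5, NA), RECI = c(1, 1))
  out <- predict_voxels(overshoot, tab)
  expect_equal(out$fpar_pred[1], 1)
  expect_true(out$clipped[1])
  expect_true(is.na(out$fpar_pred[2]) && out$pred_missing[2])
})

test_that("model methods behave like a classic fitted object", {
  tab <- make_training(30, noise = 0.02, seed = 12)
  m <- fpar_train(tab, algorithm = "PLSR", cv_repeats = 0, seed = 12)
  expect_s3_class(m, "fpar_model")
  expect_output(print(m), "PLSR")
  expect_output(print(summary(m)), "calibration")
  expect_length(residuals(m), nrow(tab))
  expect_equal(m$y - residuals(m), m$fitted, tolerance = 1e-12)
  cf <- coef(m)
  expect_length(cf, length(vi_names()))
  # NDVI is the generating predictor: largest standardized slope
  expect_identical(names(which.max(abs(cf))), "NDVI")
  f <- tempfile(fileext = ".png")
  grDevices::png(f); plot(m); grDevices::dev.off()
  expect_true(file.exists(f))
})
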