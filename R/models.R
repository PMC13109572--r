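# Regression of stratum fPAR on the fourteen vegetation indices with four
# learners (random forest, gradient boosting, RBF support vector regression,
# partial least squares), tree-grouped repeated k-fold cross-validation and
# optional grid search. The model object follows the classic fitted-model
# idiom: fpar_train() returns an S3 "fpar_model" with print, summary,
# predict, residuals, coef and plot methods.

#' Split a table into calibration and validation sets at the tree level
#'
#' All rows sharing a grouping unit (default the tree) stay together, so no
#' tree contributes to both sides.
#'
#' @param table Data frame with the grouping column.
#' @param fraction Calibration fraction (default 0.8).
#' @param unit Grouping column name (default `"tree_id"`; use `"date"` for a
#'   temporal-independence split).
#' @param seed Integer seed.
#' @return List with `calibration` and `validation` data frames.
#' @export
split_data <- function(table, fraction = 0.8, unit = "tree_id", seed = 1) {
  units <- unique(table[[unit]])
  if (length(units) < 5)
    stop_voxfpar("need at least 5 grouping units to split", "voxfpar_data_error")
  with_seed(derive_seed(seed, "split"), {
    n_cal <- round(fraction * length(units))
    n_cal <- min(max(n_cal, 1), length(units) - 1)
    cal_units <- sample(units, n_cal)
    list(calibration = table[table[[unit]] %in% cal_units, , drop = FALSE],
         validation = table[!table[[unit]] %in% cal_units, , drop = FALSE])
  })
}

#' Coefficient of determination and root mean square error
#'
#' `R2 = 1 - sum((y - yhat)^2) / sum((y - ybar)^2)`;
#' `RMSE = sqrt(mean((y - yhat)^2))`. With zero total variance R2 is
#' undefined (`NA`); RMSE is always returned.
#'
#' @param observed,predicted Numeric vectors of equal length (n >= 2 for R2).
#' @return List with `r2` and `rmse`.
#' @export
evaluate_predictions <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  sse <- sum((observed - predicted)^2)
  rmse <- sqrt(sse / length(observed))
  sst <- sum((observed - mean(observed))^2)
  r2 <- if (length(observed) < 2 || sst == 0) NA_real_ else 1 - sse / sst
  list(r2 = r2, rmse = rmse)
}

default_hyper <- function(algorithm) {
  switch(algorithm,
         RF = list(n_trees = 300, mtry = 6),
         XGBoost = list(eta = 0.01, n_trees = 500, max_depth = 6),
         SVM = list(C = 10, gamma = 0.1, epsilon = 0.01),
         PLSR = list(n_components = 10))
}

default_grid <- function(algorithm) {
  switch(algorithm,
         RF = expand.grid(n_trees = 300, mtry = c(4, 6, 8)),
         XGBoost = expand.grid(eta = c(0.01, 0.05), n_trees = 500,
                               max_depth = c(4, 6)),
         SVM = expand.grid(C = c(1, 10, 100), gamma = c(0.01, 0.1, 1)),
         PLSR = data.frame(n_components = c(4, 6, 8, 10)))
}

# fit one learner on a standardized-or-raw matrix; returns a closure that
# predicts on new matrices of the same columns
fit_learner <- function(algorithm, X, y, hyper, seed) {
  switch(algorithm,
    RF = {
      with_seed(seed, {
        fit <- randomForest::randomForest(
          x = X, y = y, ntree = hyper$n_trees,
          mtry = min(hyper$mtry, ncol(X)))
        list(fit = fit, predict = function(newX)
          as.numeric(stats::predict(fit, newX)))
      })
    },
    XGBoost = {
      fit <- xgboost::xgb.train(
        params = list(eta = hyper$eta, max_depth = hyper$max_depth,
                      objective = "reg:squarederror", nthread = 1,
                      seed = seed),
        data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
        nrounds = hyper$n_trees)
      list(fit = fit, predict = function(newX)
        as.numeric(stats::predict(fit, xgboost::xgb.DMatrix(newX,
                                                            nthread = 1))))
    },
    SVM = {
      fit <- e1071::svm(x = X, y = y, type = "eps-regression",
                        kernel = "radial", cost = hyper$C,
                        gamma = hyper$gamma,
                        epsilon = hyper$epsilon %||% 0.01, scale = FALSE)
      list(fit = fit, predict = function(newX)
        as.numeric(stats::predict(fit, newX)))
    },
    PLSR = {
      nc <- min(hyper$n_components, ncol(X), nrow(X) - 1)
      fit <- mixOmics::pls(X, y, ncomp = nc, mode = "regression",
                           scale = FALSE)
      list(fit = fit, ncomp = nc, predict = function(newX)
        as.numeric(stats::predict(fit, newX)$predict[, 1, nc]))
    },
    stop_voxfpar(paste0("unknown algorithm: ", algorithm),
                 "voxfpar_config_error"))
}

# tree-grouped fold assignment: units are shuffled and dealt round-robin
make_group_folds <- function(groups, k, seed) {
  units <- unique(groups)
  if (length(units) < k)
    stop_voxfpar(sprintf("fewer grouping units (%d) than folds (%d)",
                         length(units), k), "voxfpar_data_error")
  with_seed(seed, {
    shuffled <- sample(units)
    fold_of_unit <- rep(seq_len(k), length.out = length(shuffled))
    unname(stats::setNames(fold_of_unit, as.character(shuffled))[as.character(groups)])
  })
}

#' Fit an fPAR regression model
#'
#' Fits one of four learners to tree-level (or voxel-level) rows of
#' vegetation-index predictors. Predictors are standardized (statistics from
#' the calibration rows only) for the distance/projection-based learners
#' (SVM, PLSR); the tree ensembles consume raw values. Cross-validation folds
#' are grouped by `group` so that no tree straddles a fold boundary; with
#' `grid_search = TRUE` the hyperparameter combination minimizing the mean CV
#' RMSE is selected before the final refit on all rows.
#'
#' @param data Data frame holding predictors, the response and the grouping
#'   column. Rows with missing predictors or response are dropped (count
#'   recorded in the result).
#' @param response Response column name (default `"fpar"`).
#' @param predictors Predictor column names (default the fourteen indices).
#' @param algorithm One of `"RF"`, `"XGBoost"`, `"SVM"`, `"PLSR"`.
#' @param hyper Named list of hyperparameters; `NULL` uses the defaults
#'   (RF: 300 trees, mtry 6; XGBoost: eta 0.01, 500 trees, depth 6;
#'   SVM: C 10, gamma 0.1, RBF; PLSR: 10 components).
#' @param grid_search Search the built-in grid by CV RMSE (default FALSE).
#' @param grid Optional data frame replacing the built-in grid.
#' @param cv_folds,cv_repeats Grouped k-fold CV setup (default 10 x 5); set
#'   `cv_repeats = 0` to skip CV entirely when no search is requested.
#' @param group Grouping column for folds (default `"tree_id"`).
#' @param seed Integer seed controlling folds and learner randomness.
#' @return An object of class `fpar_model`.
#' @export
fpar_train <- function(data, response = "fpar", predictors = vi_names(),
                       algorithm = c("RF", "XGBoost", "SVM", "PLSR"),
                       hyper = NULL, grid_search = FALSE, grid = NULL,
                       cv_folds = 10, cv_repeats = 5, group = "tree_id",
                       seed = 1) {
  algorithm <- match.arg(algorithm)
  stopifnot(all(predictors %in% names(data)), response %in% names(data),
            group %in% names(data))
  keep <- stats::complete.cases(data[, c(predictors, response)])
  n_dropped <- sum(!keep)
  data <- data[keep, , drop = FALSE]
  if (nrow(data) == 0)
    stop_voxfpar("all rows dropped: predictors or response entirely missing",
                 "voxfpar_data_error")
  if (nrow(data) < 20)
    stop_voxfpar(sprintf("need at least 20 complete training rows, got %d",
                         nrow(data)), "voxfpar_data_error")
  X <- as.matrix(data[, predictors, drop = FALSE])
  y <- data[[response]]
  groups <- data[[group]]
  standardize <- algorithm %in% c("SVM", "PLSR")
  scale_fun <- function(Xtr) {
    ctr <- colMeans(Xtr)
    scl <- apply(Xtr, 2, stats::sd)
    scl[scl == 0] <- 1
    list(center = ctr, scale = scl,
         apply = function(M) sweep(sweep(M, 2, ctr), 2, scl, "/"))
  }
  cand <- if (grid_search) {
    g <- grid %||% default_grid(algorithm)
    lapply(seq_len(nrow(g)), function(i) as.list(g[i, , drop = FALSE]))
  } else list(hyper %||% default_hyper(algorithm))
  cv_table <- NULL
  best <- cand[[1]]
  if (cv_repeats > 0) {
    k <- min(cv_folds, length(unique(groups)))
    cv_rmse <- matrix(NA_real_, length(cand), cv_repeats)
    for (rep_i in seq_len(cv_repeats)) {
      folds <- make_group_folds(groups, k, derive_seed(seed, paste0("cv", rep_i)))
      preds <- matrix(NA_real_, length(y), length(cand))
      for (f in seq_len(k)) {
        tr <- folds != f; te <- folds == f
        if (!any(te) || sum(tr) < 2) next
        Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
        if (standardize) {
          sc <- scale_fun(Xtr)
          Xtr <- sc$apply(Xtr); Xte <- sc$apply(Xte)
        }
        for (ci in seq_along(cand)) {
          m <- fit_learner(algorithm, Xtr, y[tr], cand[[ci]],
                           derive_seed(seed, paste0("fit", rep_i, f, ci)))
          preds[te, ci] <- m$predict(Xte)
        }
      }
      for (ci in seq_along(cand)) {
        ok <- !is.na(preds[, ci])
        cv_rmse[ci, rep_i] <- sqrt(mean((y[ok] - preds[ok, ci])^2))
      }
    }
    mean_rmse <- rowMeans(cv_rmse, na.rm = TRUE)
    cv_table <- do.call(rbind, lapply(seq_along(cand), function(ci)
      data.frame(cand[[ci]], cv_rmse = mean_rmse[ci],
                 cv_rmse_sd = stats::sd(cv_rmse[ci, ]))))
    best <- cand[[which.min(mean_rmse)]]
  }
  scaling <- NULL
  Xfit <- X
  if (standardize) {
    sc <- scale_fun(X)
    scaling <- sc[c("center", "scale")]
    Xfit <- sc$apply(X)
  }
  final <- fit_learner(algorithm, Xfit, y, best, derive_seed(seed, "final"))
  fitted_vals <- final$predict(Xfit)
  cal <- evaluate_predictions(y, fitted_vals)
  structure(list(algorithm = algorithm, learner = final, hyper = best,
                 predictors = predictors, response = response,
                 scaling = scaling, cv = cv_table,
                 calibration = list(r2 = cal$r2, rmse = cal$rmse,
                                    n = length(y)),
                 fitted = fitted_vals, y = y, groups = groups,
                 n_dropped = n_dropped, seed = seed),
            class = "fpar_model")
}

model_matrix <- function(object, newdata) {
  miss <- setdiff(object$predictors, names(newdata))
  if (length(miss))
    stop_voxfpar(paste0("newdata missing predictors: ",
                        paste(miss, collapse = ", ")), "voxfpar_format_error")
  M <- as.matrix(newdata[, object$predictors, drop = FALSE])
  if (!is.null(object$scaling))
    M <- sweep(sweep(M, 2, object$scaling$center), 2, object$scaling$scale, "/")
  M
}

#' @export
predict.fpar_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  M <- model_matrix(object, newdata)
  ok <- stats::complete.cases(M)
  out <- rep(NA_real_, nrow(M))
  if (any(ok)) out[ok] <- object$learner$predict(M[ok, , drop = FALSE])
  out
}

#' @export
residuals.fpar_model <- function(object, ...) object$y - object$fitted

#' @export
coef.fpar_model <- function(object, ...) {
  if (object$algorithm != "PLSR") {
    message("coefficients are only defined for the PLSR learner")
    return(invisible(NULL))
  }
  # PLSR with fixed ncomp is linear in X: recover slopes by probing
  p <- length(object$predictors)
  Z <- rbind(rep(0, p), diag(p))
  colnames(Z) <- object$predictors
  preds <- object$learner$predict(Z)
  stats::setNames(preds[-1] - preds[1], object$predictors)
}

#' @export
print.fpar_model <- function(x, ...) {
  cat(sprintf("fPAR regression model (%s)\n", x$algorithm))
  cat(sprintf("  predictors: %d vegetation indices; n = %d rows (%d dropped)\n",
              length(x$predictors), x$calibration$n, x$n_dropped))
  cat(sprintf("  hyperparameters: %s\n",
              paste(names(x$hyper), unlist(x$hyper), sep = "=", collapse = ", ")))
  cat(sprintf("  calibration R2 = %.3f, RMSE = %.4f\n",
              x$calibration$r2, x$calibration$rmse))
  if (!is.null(x$cv))
    cat(sprintf("  CV RMSE (grouped %s-fold): %.4f\n",
                "k", min(x$cv$cv_rmse)))
  invisible(x)
}

#' @export
summary.fpar_model <- function(object, ...) {
  out <- list(algorithm = object$algorithm, hyper = object$hyper,
              calibration = object$calibration, cv = object$cv,
              n_dropped = object$n_dropped)
  class(out) <- "summary.fpar_model"
  out
}

#' @export
print.summary.fpar_model <- function(x, ...) {
  cat(sprintf("fPAR model summary (%s)\n", x$algorithm))
  cat(sprintf("  calibration: n = %d, R2 = %.3f, RMSE = %.4f\n",
              x$calibration$n, x$calibration$r2, x$calibration$rmse))
  if (!is.null(x$cv)) {
    cat("  cross-validation grid:\n")
    print(x$cv, row.names = FALSE)
  }
  invisible(x)
}

#' @export
plot.fpar_model <- function(x, ...) {
  graphics::plot(x$y, x$fitted, xlab = "observed fPAR",
                 ylab = "fitted fPAR",
                 main = sprintf("%s calibration fit", x$algorithm), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Permutation importance of each predictor
#'
#' Mean increase in RMSE when one predictor column is permuted, averaged over
#' `n_repeats` permutations; larger = more important (the permutation analog
#' of mean decrease in accuracy).
#'
#' @param model An [fpar_train()] model.
#' @param data Evaluation rows (typically the validation set).
#' @param n_repeats Permutations per predictor.
#' @param seed Integer seed.
#' @return Data frame `predictor`, `importance`, sorted descending.
#' @export
permutation_importance <- function(model, data, n_repeats = 10, seed = 1) {
  keep <- stats::complete.cases(data[, c(model$predictors, model$response)])
  data <- data[keep, , drop = FALSE]
  y <- data[[model$response]]
  base_rmse <- evaluate_predictions(y, predict(model, data))$rmse
  imp <- with_seed(derive_seed(seed, "perm"), {
    vapply(model$predictors, function(p) {
      mean(vapply(seq_len(n_repeats), function(r) {
        d2 <- data
        d2[[p]] <- sample(d2[[p]])
        evaluate_predictions(y, predict(model, d2))$rmse - base_rmse
      }, numeric(1)))
    }, numeric(1))
  })
  out <- data.frame(predictor = model$predictors, importance = unname(imp))
  out[order(-out$importance), , drop = FALSE]
}

#' Predict fPAR for every voxel of a fused table
#'
#' Predictions are clipped to [0, 1] (`clipped` records where); rows with
#' missing predictors get missing predictions and `pred_missing = TRUE`.
#'
#' @param model An [fpar_train()] model.
#' @param table Fused voxel table carrying the predictor columns.
#' @return `table` with `fpar_pred`, `clipped` and `pred_missing` columns.
#' @export
predict_voxels <- function(model, table) {
  raw <- predict(model, table)
  table$pred_missing <- is.na(raw)
  table$clipped <- !is.na(raw) & (raw < 0 | raw > 1)
  table$fpar_pred <- pmin(1, pmax(0, raw))
  table
}
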