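#' Hyperparameter set for the tree-ensemble predictors
#'
#' Pins the settings the evaluation uses: random forest with 500 unpruned
#' trees, 1/3 of the markers tried at each split and terminal nodes of at
#' least five observations; gradient boosting with shrinkage 0.01,
#' subsampling rate 0.5, depth-5 trees and 1500 trees per model.
#'
#' @param rf_n_trees,rf_feature_fraction,rf_min_node random-forest settings.
#' @param gbm_shrinkage,gbm_subsample,gbm_depth,gbm_n_trees boosting
#'   settings.
#' @return A validated list of class `ensemble_config`.
#' @export
ensemble_config <- function(rf_n_trees = 500L, rf_feature_fraction = 1 / 3,
                            rf_min_node = 5L, gbm_shrinkage = 0.01,
                            gbm_subsample = 0.5, gbm_depth = 5L,
                            gbm_n_trees = 1500L) {
  cfg <- list(rf_n_trees = as.integer(rf_n_trees),
              rf_feature_fraction = rf_feature_fraction,
              rf_min_node = as.integer(rf_min_node),
              gbm_shrinkage = gbm_shrinkage,
              gbm_subsample = gbm_subsample,
              gbm_depth = as.integer(gbm_depth),
              gbm_n_trees = as.integer(gbm_n_trees))
  if (any(unlist(cfg[c("rf_n_trees", "rf_min_node", "gbm_depth",
                       "gbm_n_trees")]) < 1L))
    stop("tree counts, node sizes and depths must be positive")
  if (cfg$rf_feature_fraction <= 0 || cfg$rf_feature_fraction > 1 ||
      cfg$gbm_subsample <= 0 || cfg$gbm_subsample > 1)
    stop("fractions must lie in (0, 1]")
  if (cfg$gbm_shrinkage <= 0) stop("shrinkage must be > 0")
  structure(cfg, class = "ensemble_config")
}

#' Fit a tree-ensemble regressor and predict GEBVs
#'
#' Thin adapters over established implementations: `"rf"` calls
#' \pkg{randomForest} and `"gbm"` calls \pkg{xgboost} (squared-error
#' gradient boosting), both at the pinned [ensemble_config()]
#' hyperparameters with an explicit seed, so results are deterministic.
#'
#' @param g_train,g_test genotype matrices on the same markers.
#' @param y_train training values.
#' @param method `"rf"` or `"gbm"`.
#' @param config an [ensemble_config()].
#' @param seed integer seed set before fitting.
#' @return Numeric vector of test predictions.
#' @export
fit_predict_ensemble <- function(g_train, y_train, g_test,
                                 method = c("rf", "gbm"),
                                 config = ensemble_config(), seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(config, "ensemble_config"))
  A <- unclass(as.matrix(g_train)); B <- unclass(as.matrix(g_test))
  if (ncol(A) != ncol(B)) stop("training and test marker counts differ")
  y_train <- as.numeric(y_train)
  set.seed(seed)
  if (method == "rf") {
    fit <- randomForest::randomForest(
      x = A, y = y_train, ntree = config$rf_n_trees,
      mtry = max(1L, floor(ncol(A) * config$rf_feature_fraction)),
      nodesize = config$rf_min_node)
    as.numeric(stats::predict(fit, B))
  } else {
    dtrain <- xgboost::xgb.DMatrix(A, label = y_train)
    fit <- xgboost::xgb.train(
      params = list(objective = "reg:squarederror",
                    eta = config$gbm_shrinkage,
                    subsample = config$gbm_subsample,
                    max_depth = config$gbm_depth,
                    nthread = 1L),
      data = dtrain, nrounds = config$gbm_n_trees, verbose = 0L)
    as.numeric(stats::predict(fit, xgboost::xgb.DMatrix(B)))
  }
}
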