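# Individual regressor members behind a common fit/predict contract.
# The ensemble's neural member is a contract: any regressor consuming a
# molecular-graph or descriptor representation qualifies; the default is a
# feed-forward net on descriptor vectors, so the pipeline runs without
# deep-learning infrastructure. A message-passing implementation can be
# plugged in through the same `regressor_spec()` interface.

REGRESSOR_KINDS <- c("gradient_boosted_trees", "kernel_svr",
                     "k_nearest_neighbors", "neural_graph_or_descriptor_net",
                     "random_forest", "gaussian_process",
                     "multilayer_perceptron")

default_featurization <- function(kind) {
  switch(kind,
    gradient_boosted_trees = c("circular_fp", "path_fp_bits"),
    kernel_svr = c("descriptor_vector", "path_fp_bits"),
    k_nearest_neighbors = "circular_fp",
    neural_graph_or_descriptor_net = "descriptor_vector",
    random_forest = "path_fp_bits",
    gaussian_process = "descriptor_vector",
    multilayer_perceptron = "descriptor_vector",
    stop("unknown regressor kind: ", kind))
}

default_hyper_grid <- function(kind) {
  switch(kind,
    gradient_boosted_trees = list(nrounds = c(80L, 150L), max_depth = c(4L, 6L),
                                  learning_rate = 0.1),
    kernel_svr = list(cost = c(1, 10), epsilon = 0.1),
    k_nearest_neighbors = list(k = c(9L, 15L)),
    neural_graph_or_descriptor_net = list(size = 6L, decay = c(0.1, 0.01),
                                          maxit = 100L, n_restarts = 3L),
    random_forest = list(num_trees = 300L, mtry_frac = c(0.1, 0.3)),
    gaussian_process = list(sigma = c(0.01, 0.1)),
    multilayer_perceptron = list(size = c(4L, 8L), decay = 0.1, maxit = 120L),
    stop("unknown regressor kind: ", kind))
}

#' Specify a regressor member
#'
#' @param kind one of `"gradient_boosted_trees"`, `"kernel_svr"`,
#'   `"k_nearest_neighbors"`, `"neural_graph_or_descriptor_net"`,
#'   `"random_forest"`, `"gaussian_process"`, `"multilayer_perceptron"`.
#' @param featurization feature families consumed by this member (subset of
#'   `c("circular_fp", "path_fp_bits", "descriptor_vector")`).
#' @param hyper_grid named list of candidate hyperparameter values; the grid
#'   point with the best mean cross-validated RMSE is selected at training.
#' @return an object of class `regressor_spec`.
#' @export
regressor_spec <- function(kind,
                           featurization = default_featurization(kind),
                           hyper_grid = default_hyper_grid(kind)) {
  kind <- match.arg(kind, REGRESSOR_KINDS)
  featurization <- match.arg(featurization, FEATURIZATIONS, several.ok = TRUE)
  if (!is.list(hyper_grid) || length(hyper_grid) == 0L ||
      is.null(names(hyper_grid)) || any(!nzchar(names(hyper_grid)))) {
    stop("'hyper_grid' must be a non-empty named list")
  }
  structure(list(kind = kind, featurization = featurization,
                 hyper_grid = hyper_grid),
            class = "regressor_spec")
}

#' The default four-member ensemble specification
#'
#' Gradient-boosted trees, kernel SVR, k-nearest neighbors, and the
#' descriptor-net stand-in for the message-passing neural member.
#'
#' @return list of four `regressor_spec` objects.
#' @export
default_ensemble_specs <- function() {
  list(regressor_spec("gradient_boosted_trees"),
       regressor_spec("kernel_svr"),
       regressor_spec("k_nearest_neighbors"),
       regressor_spec("neural_graph_or_descriptor_net"))
}

# Expand a named list of candidate values into grid-point rows.
expand_hyper_grid <- function(hyper_grid) {
  grid <- expand.grid(hyper_grid, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(grid)), function(i) as.list(grid[i, , drop = FALSE]))
}

scale_columns <- function(X, center, scale) {
  scale[scale == 0 | !is.finite(scale)] <- 1
  sweep(sweep(X, 2L, center, "-"), 2L, scale, "/")
}

l2_normalize_rows <- function(X) {
  X / pmax(sqrt(rowSums(X^2)), 1e-9)
}

# Feature preprocessing per member kind: kernel and net members need
# column standardization (mixed physchem/bit scales); the nearest-neighbor
# member works on L2-row-normalized fingerprints, making its Euclidean
# neighbor search equivalent to a cosine-similarity search; tree members
# take raw features.
default_preprocess <- function(kind) {
  switch(kind,
    k_nearest_neighbors = "l2norm",
    kernel_svr = ,
    neural_graph_or_descriptor_net = ,
    gaussian_process = ,
    multilayer_perceptron = "scale",
    "none")
}

# Fit one member on a numeric feature matrix. Deterministic given `seed`
# (all backends run single-threaded).
fit_member <- function(kind, X, y, hyper, seed) {
  set.seed(seed)
  scaler <- NULL
  preprocess <- default_preprocess(kind)
  if (preprocess == "scale") {
    scaler <- list(type = "scale", center = colMeans(X),
                   scale = apply(X, 2L, stats::sd))
    X <- scale_columns(X, scaler$center, scaler$scale)
  } else if (preprocess == "l2norm") {
    scaler <- list(type = "l2norm")
    X <- l2_normalize_rows(X)
  }
  fit <- switch(kind,
    gradient_boosted_trees = {
      dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
      xgboost::xgb.train(
        params = list(max_depth = hyper$max_depth %||% 6L,
                      learning_rate = hyper$learning_rate %||% 0.1,
                      objective = "reg:squarederror",
                      nthread = 1, seed = seed),
        data = dtrain, nrounds = hyper$nrounds %||% 100L, verbose = 0)
    },
    kernel_svr = e1071::svm(X, y, kernel = "radial",
                            cost = hyper$cost %||% 1,
                            epsilon = hyper$epsilon %||% 0.1,
                            gamma = hyper$gamma %||% (1 / ncol(X)),
                            scale = FALSE, cachesize = 256,
                            tolerance = 0.01),
    k_nearest_neighbors = caret::knnreg(X, y, k = hyper$k %||% 5L),
    neural_graph_or_descriptor_net = ,
    multilayer_perceptron = lapply(seq_len(hyper$n_restarts %||% 1L),
      function(r) {
        # average over random restarts: small nets are sensitive to their
        # weight initialization, and the restart mean is the stable predictor
        set.seed(seed + 7919L * r)
        nnet::nnet(X, y, size = hyper$size %||% 6L,
                   decay = hyper$decay %||% 0.1,
                   maxit = hyper$maxit %||% 120L, linout = TRUE,
                   trace = FALSE, MaxNWts = 100000L)
      }),
    random_forest = ranger::ranger(
      x = X, y = y, num.trees = hyper$num_trees %||% 300L,
      mtry = max(1L, floor((hyper$mtry_frac %||% 0.3) * ncol(X))),
      num.threads = 1L, seed = seed),
    gaussian_process = kernlab::gausspr(
      X, y, kernel = "rbfdot",
      kpar = list(sigma = hyper$sigma %||% 0.1), var = 0.01),
    stop("unknown regressor kind: ", kind))
  structure(list(kind = kind, fit = fit, hyper = hyper, scaler = scaler),
            class = "qsar_member")
}

predict_member <- function(member, X) {
  if (!is.null(member$scaler)) {
    X <- if (member$scaler$type == "l2norm") {
      l2_normalize_rows(X)
    } else {
      scale_columns(X, member$scaler$center, member$scaler$scale)
    }
  }
  out <- switch(member$kind,
    gradient_boosted_trees = predict(member$fit,
                                     xgboost::xgb.DMatrix(X, nthread = 1)),
    kernel_svr = predict(member$fit, X),
    k_nearest_neighbors = predict(member$fit, X),
    neural_graph_or_descriptor_net = ,
    multilayer_perceptron = {
      preds <- vapply(member$fit, function(f) as.numeric(predict(f, X)),
                      numeric(nrow(X)))
      if (is.null(dim(preds))) preds <- matrix(preds, nrow = nrow(X))
      rowMeans(preds)
    },
    random_forest = predict(member$fit, data = X,
                            num.threads = 1L)$predictions,
    gaussian_process = as.numeric(kernlab::predict(member$fit, X)))
  as.numeric(out)
}

# Grid search: pick the grid point minimizing mean CV RMSE. Grid points whose
# fit fails are skipped with a warning; all points failing is an error.
tune_member <- function(spec, X, y, folds, seed) {
  grid <- expand_hyper_grid(spec$hyper_grid)
  if (length(grid) == 1L) return(grid[[1L]])
  scores <- vapply(seq_along(grid), function(g) {
    errs <- vapply(seq_along(folds), function(f) {
      test <- folds[[f]]
      fit <- tryCatch(
        fit_member(spec$kind, X[-test, , drop = FALSE], y[-test],
                   grid[[g]], seed + f),
        error = function(e) NULL)
      if (is.null(fit)) return(NA_real_)
      pred <- predict_member(fit, X[test, , drop = FALSE])
      sqrt(mean((y[test] - pred)^2))
    }, numeric(1))
    if (all(is.na(errs))) NA_real_ else mean(errs, na.rm = TRUE)
  }, numeric(1))
  if (all(is.na(scores))) {
    stop(sprintf("all hyperparameter grid points failed for %s", spec$kind))
  }
  if (anyNA(scores)) {
    warning(sprintf("%d grid point(s) failed for %s and were skipped",
                    sum(is.na(scores)), spec$kind))
  }
  grid[[which.min(scores)]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
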