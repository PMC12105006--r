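# Cross-validated model evaluation: the four-metric suite (RMSE, MAE,
# explained-variance score, R^2), fold construction stratified by measurement
# type, and the mean-rank model comparison.

#' Regression metric suite
#'
#' @param y observed values.
#' @param yhat predicted values.
#' @return named numeric vector `rmse`, `mae`, `evs`, `r2`. When `y` has zero
#'   variance, `evs` and `r2` are undefined and reported as `NA`.
#' @export
regression_metrics <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("'y' and 'yhat' lengths differ")
  res <- y - yhat
  rmse <- sqrt(mean(res^2))
  mae <- mean(abs(res))
  if (length(y) < 2L || stats::var(y) == 0) {
    evs <- NA_real_
    r2 <- NA_real_
  } else {
    evs <- 1 - stats::var(res) / stats::var(y)
    r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  }
  c(rmse = rmse, mae = mae, evs = evs, r2 = r2)
}

# k folds stratified by a grouping factor: within each stratum indices are
# shuffled and dealt round-robin, so every fold mirrors the stratum mix.
stratified_folds <- function(strata, k, seed) {
  if (k < 2L) stop("'k' must be at least 2")
  set.seed(seed)
  assignment <- integer(length(strata))
  for (s in unique(strata)) {
    idx <- sample(which(strata == s))
    assignment[idx] <- rep_len(seq_len(k), length(idx))
  }
  lapply(seq_len(k), function(f) which(assignment == f))
}

#' Cross-validated evaluation of QSAR model families
#'
#' Computes out-of-fold predictions for each listed model family, plus the
#' uniform-weight ensemble of the canonical four members when present, and
#' reports the four-metric suite per model and fold. Folds are stratified by
#' measurement type; the affinity normalization is refit on each training
#' fold so no test information leaks into the target scale.
#'
#' @param records affinity record data.frame (`smiles`, `measurement`,
#'   `pchembl`).
#' @param specs list of `regressor_spec` objects (up to the full set of
#'   model families).
#' @param k number of folds (default 10); every fold must receive at least 5
#'   records.
#' @param seed integer seed.
#' @param include_ensemble add an `ensemble` pseudo-model averaging the
#'   canonical four member kinds (or all members if fewer are present).
#' @param tune if `TRUE`, run the grid search inside every training fold;
#'   if `FALSE` (default) each member uses the first value of each
#'   hyperparameter list, keeping evaluation cost linear in the fold count.
#' @param circular_bits modeling fingerprint length.
#' @param features precomputed [featurize_set()] output for these records
#'   (an optimization for repeated evaluation of the same records; computed
#'   here when `NULL`).
#' @return object of class `qsar_cv`: data.frame with columns `model`,
#'   `fold`, `rmse`, `mae`, `evs`, `r2`.
#' @export
qsar_cv <- function(records, specs = default_ensemble_specs(), k = 10L,
                    seed = 1L, include_ensemble = TRUE, tune = FALSE,
                    circular_bits = 256L, features = NULL) {
  records <- validate_affinity_records(records)
  if (k < 2L) stop("'k' must be at least 2")
  folds <- stratified_folds(records$measurement, k, seed)
  if (any(lengths(folds) < 5L)) {
    stop("every fold must receive at least 5 records; reduce 'k'")
  }
  labels <- member_labels(specs)
  families <- unique(unlist(lapply(specs, `[[`, "featurization")))
  feats <- features %||%
    featurize_set(records$smiles, families, circular_bits)
  ens_idx <- which(vapply(specs, `[[`, "", "kind") %in%
                     vapply(default_ensemble_specs(), `[[`, "", "kind"))
  if (length(ens_idx) < 2L) ens_idx <- seq_along(specs)

  rows <- list()
  for (f in seq_along(folds)) {
    test <- folds[[f]]
    train_rec <- records[-test, , drop = FALSE]
    norm <- affinity_normalization(train_rec$pchembl, train_rec$measurement)
    y_train <- transform_affinity(norm, train_rec$pchembl, train_rec$measurement)
    y_test <- transform_affinity(norm, records$pchembl[test],
                                 records$measurement[test])
    preds <- matrix(NA_real_, nrow = length(test), ncol = length(specs))
    for (i in seq_along(specs)) {
      X <- member_features(feats, specs[[i]]$featurization)
      hyper <- if (tune) {
        inner <- stratified_folds(train_rec$measurement, k = 3L,
                                  seed = seed + 7L * f)
        tune_member(specs[[i]], X[-test, , drop = FALSE], y_train, inner,
                    seed + 1000L * i + f)
      } else {
        lapply(specs[[i]]$hyper_grid, `[[`, 1L)
      }
      fit <- fit_member(specs[[i]]$kind, X[-test, , drop = FALSE], y_train,
                        hyper, seed + 17L * i + 101L * f)
      preds[, i] <- predict_member(fit, X[test, , drop = FALSE])
      rows[[length(rows) + 1L]] <- data.frame(
        model = labels[i], fold = f,
        t(regression_metrics(y_test, preds[, i])))
    }
    if (include_ensemble) {
      ens_pred <- rowMeans(preds[, ens_idx, drop = FALSE])
      rows[[length(rows) + 1L]] <- data.frame(
        model = "ensemble", fold = f,
        t(regression_metrics(y_test, ens_pred)))
    }
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  class(report) <- c("qsar_cv", "data.frame")
  report
}

#' @export
print.qsar_cv <- function(x, ...) {
  cat(sprintf("Cross-validated metrics (%d models, %d folds)\n",
              length(unique(x$model)), max(x$fold)))
  agg <- stats::aggregate(x[, c("rmse", "mae", "evs", "r2")],
                          by = list(model = x$model), FUN = mean)
  print(agg, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @method plot qsar_cv
#' @export
plot.qsar_cv <- function(x, ...) {
  old <- graphics::par(mfrow = c(2, 2), mar = c(6, 4, 2, 1))
  on.exit(graphics::par(old))
  arrows <- c(rmse = "(lower better)", mae = "(lower better)",
              evs = "(higher better)", r2 = "(higher better)")
  for (metric in c("rmse", "mae", "evs", "r2")) {
    graphics::boxplot(x[[metric]] ~ x$model, las = 2, xlab = "",
                      ylab = metric, main = paste(metric, arrows[[metric]]))
  }
  invisible(x)
}

#' Mean-rank model comparison
#'
#' For each of the four metrics, models are sorted best-first (ascending
#' RMSE/MAE, descending EVS/R^2) on their fold-mean value and assigned ranks
#' 1..M, ties receiving the average rank; `mean_rank` and `rank_sd` aggregate
#' each model's four ranks.
#'
#' @param report a `qsar_cv` report (or data.frame with the same columns).
#' @return data.frame with columns `model`, `mean_rank`, `rank_sd`, sorted by
#'   `mean_rank`.
#' @export
rank_models <- function(report) {
  needed <- c("model", "rmse", "mae", "evs", "r2")
  if (!all(needed %in% names(report))) {
    stop("'report' must contain columns ", paste(needed, collapse = ", "))
  }
  agg <- stats::aggregate(report[, c("rmse", "mae", "evs", "r2")],
                          by = list(model = report$model), FUN = mean)
  if (anyNA(agg[, c("rmse", "mae", "evs", "r2")])) {
    bad <- agg$model[apply(is.na(agg[, -1L]), 1L, any)]
    stop("missing metric value(s) for model(s): ", paste(bad, collapse = ", "))
  }
  ranks <- cbind(rmse = rank(agg$rmse), mae = rank(agg$mae),
                 evs = rank(-agg$evs), r2 = rank(-agg$r2))
  out <- data.frame(model = agg$model,
                    mean_rank = rowMeans(ranks),
                    rank_sd = apply(ranks, 1L, stats::sd))
  out[order(out$mean_rank), , drop = FALSE]
}
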