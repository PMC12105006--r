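# The four-member uniform-weight affinity ensemble. Members are trained on
# the Box-Cox + z-score normalized affinity scale; the ensemble prediction
# f_pch(G) is the unweighted arithmetic mean of the member outputs and the
# spread sigma_ens(G) is their population standard deviation, used by the
# internal-consistency filter.

#' Fit the affinity ensemble QSAR model
#'
#' Trains the member regressors on measurement-type-normalized pChEMBL
#' values. Each member's hyperparameters are chosen by grid search over its
#' `hyper_grid`, scored by mean cross-validated RMSE with folds stratified by
#' measurement type. Training is deterministic given `seed`.
#'
#' @param records data.frame with columns `smiles`, `measurement`
#'   (`Ki`/`Kd`/`IC50`/`EC50`) and `pchembl`; at least 50 rows.
#' @param specs list of `regressor_spec` objects; the default is the
#'   four-member ensemble (gradient-boosted trees, kernel SVR, k-nearest
#'   neighbors, descriptor-net neural member).
#' @param seed integer seed controlling every stochastic step.
#' @param tune_folds folds for the hyperparameter grid search (default 5).
#' @param normalization an `affinity_norm` object fitted on the same records,
#'   or `NULL` to fit one here.
#' @param weights member averaging weights; default uniform. Exposed for
#'   generality, but the screening pipeline assumes homogeneous weights.
#' @param circular_bits modeling fingerprint length (default 256).
#' @return an object of class `qsar_ensemble`.
#' @export
qsar_ensemble <- function(records, specs = default_ensemble_specs(),
                          seed = 1L, tune_folds = 5L, normalization = NULL,
                          weights = NULL, circular_bits = 256L) {
  records <- validate_affinity_records(records)
  if (nrow(records) < 50L) {
    stop("at least 50 affinity records are required to train the ensemble")
  }
  stopifnot(is.list(specs), length(specs) >= 1L,
            all(vapply(specs, inherits, logical(1), "regressor_spec")))
  if (is.null(weights)) {
    weights <- rep(1 / length(specs), length(specs))
  }
  if (length(weights) != length(specs) || abs(sum(weights) - 1) > 1e-8) {
    stop("'weights' must have one entry per member and sum to 1")
  }
  if (is.null(normalization)) {
    normalization <- affinity_normalization(records$pchembl, records$measurement)
  }
  y <- transform_affinity(normalization, records$pchembl, records$measurement)
  families <- unique(unlist(lapply(specs, `[[`, "featurization")))
  feats <- featurize_set(records$smiles, families, circular_bits)
  folds <- stratified_folds(records$measurement, k = tune_folds, seed = seed)
  members <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    X <- member_features(feats, specs[[i]]$featurization)
    hyper <- tune_member(specs[[i]], X, y, folds, seed + 1000L * i)
    members[[i]] <- fit_member(specs[[i]]$kind, X, y, hyper, seed + 17L * i)
  }
  names(members) <- member_labels(specs)
  structure(list(members = members, specs = specs, weights = weights,
                 normalization = normalization,
                 circular_bits = circular_bits, seed = seed,
                 n_train = nrow(records),
                 train_smiles = records$smiles),
            class = "qsar_ensemble")
}

member_labels <- function(specs) {
  kinds <- vapply(specs, `[[`, "", "kind")
  make.unique(kinds, sep = "_")
}

# Canonicalize and validate an affinity record table.
validate_affinity_records <- function(records) {
  if (!is.data.frame(records) ||
      !all(c("smiles", "measurement", "pchembl") %in% names(records))) {
    stop("'records' must be a data.frame with columns smiles, measurement, pchembl")
  }
  records$measurement <- match_measurement(as.character(records$measurement))
  if (!is.numeric(records$pchembl) || !all(is.finite(records$pchembl))) {
    stop("'pchembl' must be finite numeric")
  }
  records$smiles <- canonical_smiles(as.character(records$smiles))
  records
}

#' Predict affinities with the ensemble
#'
#' Returns per-member predictions on the normalized scale, the uniform-weight
#' ensemble mean `f_pch`, and the member spread `sigma_ens` (population
#' standard deviation). With `units = "pchembl"` the ensemble mean is also
#' mapped back to pChEMBL through the inverse transform of the modal
#' measurement type of the training data (the conventional reporting scale
#' for unlabeled candidates; a message notes the type used).
#'
#' @param object a fitted `qsar_ensemble`.
#' @param newdata character vector of SMILES, or a data.frame with a
#'   `smiles` column.
#' @param units `"normalized"` (default) or `"pchembl"`.
#' @param ... unused.
#' @return data.frame with one row per molecule: `smiles`, one column per
#'   member, `f_pch`, `sigma_ens` (and `pchembl` when requested).
#' @method predict qsar_ensemble
#' @export
predict.qsar_ensemble <- function(object, newdata,
                                  units = c("normalized", "pchembl"), ...) {
  units <- match.arg(units)
  smiles <- if (is.data.frame(newdata)) as.character(newdata$smiles)
            else as.character(newdata)
  if (length(smiles) == 0L) {
    stop("'newdata' contains no molecules")
  }
  can <- tryCatch(canonical_smiles(smiles),
                  error = function(e) {
                    stop("cannot featurize input: ", conditionMessage(e),
                         call. = FALSE)
                  })
  families <- unique(unlist(lapply(object$specs, `[[`, "featurization")))
  feats <- featurize_set(can, families, object$circular_bits)
  per_member <- vapply(seq_along(object$members), function(i) {
    X <- member_features(feats, object$specs[[i]]$featurization)
    predict_member(object$members[[i]], X)
  }, numeric(length(can)))
  if (is.null(dim(per_member))) per_member <- matrix(per_member, nrow = 1L)
  colnames(per_member) <- names(object$members)
  comb <- ensemble_combine(per_member, object$weights)
  out <- data.frame(smiles = can, per_member, f_pch = comb$mean,
                    sigma_ens = comb$spread, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (units == "pchembl") {
    m <- modal_measurement(object$normalization)
    message("reporting pChEMBL through the inverse transform of the modal ",
            "measurement type: ", m)
    out$pchembl <- inverse_affinity(object$normalization, out$f_pch, m)
  }
  rownames(out) <- NULL
  out
}

#' Combine member predictions into the ensemble statistics
#'
#' The ensemble prediction is the weighted (by default uniform) mean of the
#' member outputs; the spread is the population (n-divisor) standard
#' deviation around that mean, the internal-consistency statistic
#' `sigma_ens`. The spread is zero exactly when all members agree.
#'
#' @param per_member numeric matrix, one row per molecule and one column per
#'   member (a vector is treated as a single molecule).
#' @param weights member weights summing to 1; default uniform.
#' @return list with numeric vectors `mean` and `spread`.
#' @export
ensemble_combine <- function(per_member, weights = NULL) {
  if (is.null(dim(per_member))) per_member <- matrix(per_member, nrow = 1L)
  if (is.null(weights)) {
    weights <- rep(1 / ncol(per_member), ncol(per_member))
  }
  if (length(weights) != ncol(per_member) || abs(sum(weights) - 1) > 1e-8) {
    stop("'weights' must have one entry per member and sum to 1")
  }
  m <- as.numeric(per_member %*% weights)
  spread <- sqrt(as.numeric(((per_member - m)^2) %*% weights))
  list(mean = m, spread = spread)
}

#' @export
print.qsar_ensemble <- function(x, ...) {
  cat("Ensemble QSAR affinity model\n")
  cat(sprintf("  members (%d, weights %s):\n", length(x$members),
              paste(signif(x$weights, 3), collapse = "/")))
  for (i in seq_along(x$members)) {
    m <- x$members[[i]]
    cat(sprintf("   - %s [%s] %s\n", names(x$members)[i],
                paste(x$specs[[i]]$featurization, collapse = "+"),
                paste(names(m$hyper), unlist(m$hyper),
                      sep = "=", collapse = ", ")))
  }
  cat(sprintf("  trained on %d records, seed %d\n", x$n_train, x$seed))
  invisible(x)
}

#' @export
summary.qsar_ensemble <- function(object, ...) {
  print(object)
  cat("\nNormalization:\n")
  print(object$normalization)
  invisible(object)
}
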