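# 12-task toxicity-probability model and the all-tasks nontoxic decision
# rule. The model is a contract: any multi-label probabilistic classifier on
# molecular features qualifies. The default implementation fits one
# gradient-boosted classifier per task on circular fingerprint bits, with
# missing labels excluded from that task's training set; a multitask
# message-passing network can be plugged in behind the same interface.

#' Default 12-endpoint task list
#'
#' Nuclear-receptor and stress-response panel names in the conventional
#' 12-assay toxicology layout.
#'
#' @return character vector of 12 task names.
#' @export
tox_tasks <- function() {
  c("NR.AR", "NR.AR.LBD", "NR.AhR", "NR.Aromatase", "NR.ER", "NR.ER.LBD",
    "NR.PPAR.gamma", "SR.ARE", "SR.ATAD5", "SR.HSE", "SR.MMP", "SR.p53")
}

#' Fit the 12-task toxicity model
#'
#' @param labels data.frame with a `smiles` column and 12 binary label
#'   columns (0/1, `NA` = missing). Column names fix the task order echoed in
#'   predictions.
#' @param seed integer seed; training is deterministic given it.
#' @param n_bits fingerprint length for the per-task classifiers.
#' @param nrounds boosting rounds per task.
#' @param min_per_class minimum positives and negatives a task needs to be
#'   trainable (default 10); a task with a single observed class is flagged
#'   untrainable with a warning and predicted at its class prior.
#' @return object of class `tox_model`.
#' @export
toxicity_model <- function(labels, seed = 1L, n_bits = 256L, nrounds = 60L,
                           min_per_class = 10L) {
  if (!is.data.frame(labels) || !"smiles" %in% names(labels)) {
    stop("'labels' must be a data.frame with a 'smiles' column")
  }
  task_names <- setdiff(names(labels), "smiles")
  if (length(task_names) != 12L) {
    stop(sprintf("expected 12 task columns, found %d", length(task_names)))
  }
  smiles <- canonical_smiles(as.character(labels$smiles))
  Y <- as.matrix(labels[, task_names])
  if (!all(Y %in% c(0, 1) | is.na(Y))) {
    stop("task labels must be 0, 1 or NA")
  }
  X <- morgan_fp(smiles, radius = 2L, n_bits = n_bits)
  fits <- vector("list", length(task_names))
  names(fits) <- task_names
  for (j in seq_along(task_names)) {
    obs <- which(!is.na(Y[, j]))
    yj <- Y[obs, j]
    n_pos <- sum(yj == 1)
    n_neg <- sum(yj == 0)
    if (n_pos == 0L || n_neg == 0L) {
      warning(sprintf("task %s has a single observed class; predicting the class prior",
                      task_names[j]), call. = FALSE)
      fits[[j]] <- list(type = "prior", prior = mean(yj))
      next
    }
    if (n_pos < min_per_class || n_neg < min_per_class) {
      stop(sprintf("task %s has %d positive / %d negative labels; at least %d of each required",
                   task_names[j], n_pos, n_neg, min_per_class))
    }
    set.seed(seed + j)
    dtrain <- xgboost::xgb.DMatrix(X[obs, , drop = FALSE], label = yj,
                                   nthread = 1)
    fit <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = 4L,
                    learning_rate = 0.2, nthread = 1, seed = seed + j),
      data = dtrain, nrounds = nrounds, verbose = 0)
    fits[[j]] <- list(type = "xgb", fit = fit)
  }
  structure(list(fits = fits, tasks = task_names, n_bits = n_bits,
                 seed = seed, n_train = nrow(labels)),
            class = "tox_model")
}

#' Predict the 12-task toxicity profile
#'
#' @param object a fitted `tox_model`.
#' @param newdata character vector of SMILES or data.frame with a `smiles`
#'   column.
#' @param ... unused.
#' @return numeric matrix, one row per molecule and one column per task, of
#'   probabilities in `[0, 1]`.
#' @method predict tox_model
#' @export
predict.tox_model <- function(object, newdata, ...) {
  smiles <- if (is.data.frame(newdata)) as.character(newdata$smiles)
            else as.character(newdata)
  can <- tryCatch(canonical_smiles(smiles),
                  error = function(e) {
                    stop("cannot featurize input: ", conditionMessage(e),
                         call. = FALSE)
                  })
  X <- morgan_fp(can, radius = 2L, n_bits = object$n_bits)
  P <- vapply(object$fits, function(f) {
    if (f$type == "prior") {
      rep(f$prior, length(can))
    } else {
      as.numeric(predict(f$fit, xgboost::xgb.DMatrix(X, nthread = 1)))
    }
  }, numeric(length(can)))
  if (is.null(dim(P))) P <- matrix(P, nrow = 1L)
  colnames(P) <- object$tasks
  rownames(P) <- can
  P
}

#' @export
print.tox_model <- function(x, ...) {
  n_prior <- sum(vapply(x$fits, function(f) f$type == "prior", logical(1)))
  cat(sprintf("12-task toxicity model (%d boosted tasks, %d prior fallback)\n",
              12L - n_prior, n_prior))
  cat("  tasks:", paste(x$tasks, collapse = ", "), "\n")
  cat(sprintf("  trained on %d molecules, seed %d\n", x$n_train, x$seed))
  invisible(x)
}

#' All-tasks nontoxic decision rule
#'
#' A compound is nontoxic only if every task probability is below the
#' threshold; a probability exactly at the threshold counts as toxic (the
#' indicator is 1 when `p >= threshold`).
#'
#' @param profile numeric vector of 12 probabilities, or a matrix with 12
#'   columns (one row per molecule).
#' @param threshold decision threshold in `(0, 1]`; scalar, or one per task
#'   when stricter per-task cutoffs are wanted.
#' @return for a vector profile, a list with `nontoxic` (logical) and
#'   `flags` (12 integer toxicity indicators); for a matrix, a data.frame of
#'   flags with a `nontoxic` column.
#' @export
is_nontoxic <- function(profile, threshold = 0.5) {
  if (any(threshold <= 0 | threshold > 1)) {
    stop("'threshold' must lie in (0, 1]")
  }
  if (is.matrix(profile)) {
    if (ncol(profile) != 12L) stop("'profile' must have 12 columns")
    check_probs(profile)
    flags <- t(apply(profile, 1L, function(p) as.integer(p >= threshold)))
    colnames(flags) <- colnames(profile)
    out <- as.data.frame(flags)
    out$nontoxic <- rowSums(flags) == 0L
    return(out)
  }
  if (length(profile) != 12L) stop("'profile' must contain 12 probabilities")
  check_probs(profile)
  flags <- as.integer(profile >= threshold)
  list(nontoxic = sum(flags) == 0L, flags = flags)
}

check_probs <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("toxicity probabilities must lie in [0, 1]")
  }
  invisible(p)
}
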