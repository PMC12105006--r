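# The iterative generate -> filter -> append -> retrain refinement loop.
# Each iteration generates a candidate batch, screens it through the four
# filters, appends the survivors to the generator's training set and rebuilds
# the generator. Only the generator retrains inside the loop: survivors carry
# no measured affinity or toxicity labels, so the QSAR and toxicity models
# cannot honestly be refit on them. The similarity reference grows with the
# accepted molecules (primary set plus earlier acceptances) so near-
# duplicates of earlier acceptances are suppressed.

#' Design-loop configuration
#'
#' @param n_iterations number of refinement cycles, between 1 and 5. The
#'   cycle count is deliberately capped: prolonged recursion concentrates the
#'   generator on its own output and defeats the novelty filter.
#' @param batch_size candidates generated per iteration.
#' @param filter_config a [filter_config()].
#' @param seed integer seed governing generation.
#' @param retrain_generator rebuild the generator from the enlarged training
#'   set after each iteration (default `TRUE`).
#' @return object of class `loop_config`.
#' @export
loop_config <- function(n_iterations = 5L, batch_size = 10000L,
                        filter_config, seed = 1L,
                        retrain_generator = TRUE) {
  if (n_iterations < 1L || n_iterations > 5L) {
    stop("'n_iterations' must be between 1 and 5")
  }
  if (batch_size < 1L) stop("'batch_size' must be at least 1")
  stopifnot(inherits(filter_config, "filter_config"))
  structure(list(n_iterations = as.integer(n_iterations),
                 batch_size = as.integer(batch_size),
                 filter_config = filter_config,
                 seed = as.integer(seed),
                 retrain_generator = isTRUE(retrain_generator)),
            class = "loop_config")
}

#' Run the generate-filter-retrain design loop
#'
#' @param records primary affinity records (data.frame with `smiles`,
#'   `measurement`, `pchembl`); their molecules seed the generator and the
#'   similarity reference.
#' @param qsar a fitted `qsar_ensemble`.
#' @param tox a fitted `tox_model`.
#' @param config a [loop_config()].
#' @return object of class `design_run`: per-iteration funnel counts,
#'   accepted molecules per iteration (pairwise disjoint), the training-set
#'   size trajectory, and `final_candidates` -- the top
#'   `retain_fraction` of all accepted molecules by predicted affinity.
#' @export
run_design_loop <- function(records, qsar, tox, config) {
  stopifnot(inherits(qsar, "qsar_ensemble"), inherits(tox, "tox_model"),
            inherits(config, "loop_config"))
  records <- validate_affinity_records(records)
  primary <- unique(records$smiles)
  gen <- fragment_generator(primary, seed = config$seed)
  ref_fp <- morgan_fp(primary, radius = 2L, n_bits = 2048L)
  accepted <- list()
  accepted_pred <- list()
  funnel <- list()
  trajectory <- length(primary)
  training <- primary
  for (it in seq_len(config$n_iterations)) {
    batch <- generate_batch(gen, config$batch_size,
                            seed = config$seed + 100003L * it)
    n_generated <- config$batch_size
    n_valid <- length(batch)
    if (n_valid == 0L) {
      funnel[[it]] <- data.frame(
        iteration = it, n_generated = n_generated, n_valid = 0L,
        affinity_pass = 0L, toxicity_pass = 0L, similarity_pass = 0L,
        consistency_pass = 0L, n_accepted = 0L)
      trajectory <- c(trajectory, length(training))
      next
    }
    pred <- predict(qsar, batch)
    profile <- predict(tox, batch)
    cand_fp <- morgan_fp(batch, radius = 2L, n_bits = 2048L)
    s_d <- as.numeric(apply(tanimoto_matrix(cand_fp, ref_fp), 1L, max))
    verdict <- evaluate_filters(pred$f_pch, pred$sigma_ens, profile, s_d,
                                config$filter_config)
    surv <- which(verdict$overall)
    funnel[[it]] <- data.frame(
      iteration = it, n_generated = n_generated, n_valid = n_valid,
      affinity_pass = sum(verdict$affinity_pass),
      toxicity_pass = sum(verdict$toxicity_pass),
      similarity_pass = sum(verdict$similarity_pass),
      consistency_pass = sum(verdict$consistency_pass),
      n_accepted = length(surv))
    if (length(surv) > 0L) {
      acc <- batch[surv]
      accepted[[length(accepted) + 1L]] <- acc
      accepted_pred[[length(accepted_pred) + 1L]] <-
        pred$f_pch[surv]
      names(accepted)[length(accepted)] <- as.character(it)
      training <- c(training, acc)
      ref_fp <- rbind(ref_fp, cand_fp[surv, , drop = FALSE])
      if (config$retrain_generator) {
        gen <- fragment_generator(training, seed = config$seed)
      }
    }
    trajectory <- c(trajectory, length(training))
  }
  all_accepted <- unlist(accepted, use.names = FALSE)
  all_scores <- unlist(accepted_pred, use.names = FALSE)
  final <- if (length(all_accepted) > 0L) {
    retain_top(all_accepted, all_scores,
               config$filter_config$retain_fraction)
  } else {
    character(0)
  }
  structure(list(funnel = do.call(rbind, funnel),
                 accepted = accepted,
                 final_candidates = final,
                 trajectory = trajectory,
                 config = config),
            class = "design_run")
}

#' @export
print.design_run <- function(x, ...) {
  cat("Design-loop run\n")
  if (!is.null(x$funnel)) print(x$funnel, row.names = FALSE)
  cat(sprintf("training-set trajectory: %s\n",
              paste(x$trajectory, collapse = " -> ")))
  cat(sprintf("final candidates retained: %d\n", length(x$final_candidates)))
  invisible(x)
}
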