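# The four screening filters as a verdict-producing cascade:
#   affinity      f_pch(G)  >  Q3        (third quartile of training scores)
#   toxicity      nontoxic in all 12 classes (every p_i < 0.5)
#   similarity    s_D(G)    <  0.5       (max Tanimoto vs the reference set)
#   consistency   sigma_ens(G) < sigma_thr (= 1)
# All comparisons are strict, so boundary cases fail. All four predicates are
# always evaluated (no short-circuit) so the diagnostics are complete.

#' Screening filter configuration
#'
#' @param affinity_threshold minimum predicted normalized affinity,
#'   conventionally the third quartile Q3 of the training scores
#'   (see [affinity_q3()]).
#' @param tox_threshold per-task toxicity probability cutoff (default 0.5;
#'   may be a vector of 12 stricter per-task values).
#' @param sim_threshold maximum Tanimoto similarity to the reference set
#'   (default 0.5).
#' @param sigma_thr maximum ensemble spread (default 1).
#' @param retain_fraction fraction of survivors kept by [retain_top()]
#'   (default 0.05).
#' @return object of class `filter_config`.
#' @export
filter_config <- function(affinity_threshold, tox_threshold = 0.5,
                          sim_threshold = 0.5, sigma_thr = 1,
                          retain_fraction = 0.05) {
  # +/-Inf is a meaningful affinity threshold (an always-failing or
  # always-passing filter); NA/NaN are not
  stopifnot(length(affinity_threshold) == 1L, !is.na(affinity_threshold),
            is.finite(sim_threshold), is.finite(sigma_thr),
            all(is.finite(tox_threshold)))
  if (retain_fraction <= 0 || retain_fraction > 1) {
    stop("'retain_fraction' must lie in (0, 1]")
  }
  if (any(tox_threshold <= 0 | tox_threshold > 1)) {
    stop("'tox_threshold' must lie in (0, 1]")
  }
  structure(list(affinity_threshold = affinity_threshold,
                 tox_threshold = tox_threshold,
                 sim_threshold = sim_threshold,
                 sigma_thr = sigma_thr,
                 retain_fraction = retain_fraction),
            class = "filter_config")
}

#' @export
print.filter_config <- function(x, ...) {
  cat("Screening filter configuration\n")
  cat(sprintf("  affinity:    f_pch > %.4g (normalized scale)\n",
              x$affinity_threshold))
  cat(sprintf("  toxicity:    all 12 p_i < %s\n",
              paste(signif(x$tox_threshold, 3), collapse = "/")))
  cat(sprintf("  similarity:  s_D < %.4g\n", x$sim_threshold))
  cat(sprintf("  consistency: sigma_ens < %.4g\n", x$sigma_thr))
  cat(sprintf("  retention:   top %.4g%% of survivors\n",
              100 * x$retain_fraction))
  invisible(x)
}

#' Affinity filter threshold: third quartile of training scores
#'
#' The third quartile (linear-interpolation quantile convention) of the
#' normalized affinity scores of the training records.
#'
#' @param records affinity record data.frame.
#' @param normalization an `affinity_norm` fit for those records.
#' @return scalar threshold on the normalized scale.
#' @export
affinity_q3 <- function(records, normalization) {
  records <- validate_affinity_records(records)
  if (nrow(records) < 1L) stop("'records' must be non-empty")
  z <- transform_affinity(normalization, records$pchembl, records$measurement)
  unname(stats::quantile(z, 0.75, type = 7))
}

#' Evaluate the four screening filters
#'
#' Vectorized, pure predicate evaluation over precomputed statistics; model
#' wiring lives in [screen_candidates()]. All four flags are computed for
#' every candidate.
#'
#' @param f_pch ensemble mean prediction(s), normalized scale.
#' @param sigma_ens ensemble spread(s).
#' @param profile toxicity probability matrix (n x 12) or a single 12-vector.
#' @param s_d maximum Tanimoto similarity to the reference set.
#' @param config a `filter_config`.
#' @return data.frame with the diagnostics (`f_pch`, `sigma_ens`, `s_d`,
#'   `max_p`), the four pass flags, and `overall` (their conjunction).
#' @export
evaluate_filters <- function(f_pch, sigma_ens, profile, s_d, config) {
  stopifnot(inherits(config, "filter_config"))
  if (!is.matrix(profile)) profile <- matrix(profile, nrow = 1L)
  n <- length(f_pch)
  if (length(sigma_ens) != n || nrow(profile) != n || length(s_d) != n) {
    stop("'f_pch', 'sigma_ens', 'profile' rows and 's_d' must align")
  }
  check_probs(profile)
  if (n == 0L) {
    return(data.frame(f_pch = numeric(0), sigma_ens = numeric(0),
                      s_d = numeric(0), max_p = numeric(0),
                      affinity_pass = logical(0), toxicity_pass = logical(0),
                      similarity_pass = logical(0),
                      consistency_pass = logical(0), overall = logical(0)))
  }
  flags <- matrix(as.integer(t(t(profile) >= config$tox_threshold)),
                  nrow = n)
  toxicity_pass <- rowSums(flags) == 0L
  out <- data.frame(
    f_pch = f_pch,
    sigma_ens = sigma_ens,
    s_d = s_d,
    max_p = apply(profile, 1L, max),
    affinity_pass = f_pch > config$affinity_threshold,
    toxicity_pass = toxicity_pass,
    similarity_pass = s_d < config$sim_threshold,
    consistency_pass = sigma_ens < config$sigma_thr)
  out$overall <- out$affinity_pass & out$toxicity_pass &
    out$similarity_pass & out$consistency_pass
  out
}

#' Screen candidate molecules through the four-filter cascade
#'
#' Runs the ensemble QSAR model, the toxicity model and the similarity
#' statistic on each candidate and applies [evaluate_filters()].
#'
#' @param smiles character vector of candidate SMILES.
#' @param qsar a fitted `qsar_ensemble`.
#' @param tox a fitted `tox_model`.
#' @param reference reference molecules for the novelty statistic: character
#'   vector of SMILES or a precomputed 2048-bit fingerprint matrix.
#' @param config a `filter_config`.
#' @return data.frame: `smiles`, the 12 task probabilities, diagnostics,
#'   four flags and `overall`.
#' @export
screen_candidates <- function(smiles, qsar, tox, reference, config) {
  stopifnot(inherits(qsar, "qsar_ensemble"), inherits(tox, "tox_model"),
            inherits(config, "filter_config"))
  can <- canonical_smiles(smiles)
  pred <- predict(qsar, can)
  profile <- predict(tox, can)
  s_d <- max_similarity(can, reference)
  verdict <- evaluate_filters(pred$f_pch, pred$sigma_ens, profile, s_d, config)
  cbind(data.frame(smiles = can, stringsAsFactors = FALSE),
        as.data.frame(profile, row.names = FALSE), verdict)
}

#' Retain the top fraction of surviving candidates
#'
#' Sorts survivors by predicted affinity (descending) and keeps
#' `ceiling(fraction * N)`; ties at the cut are broken by canonical-SMILES
#' lexicographic order so retention is deterministic.
#'
#' @param smiles survivor SMILES.
#' @param score predicted affinity per survivor (ensemble mean).
#' @param fraction fraction to keep, in `(0, 1]`.
#' @return character vector of retained SMILES.
#' @export
retain_top <- function(smiles, score, fraction = 0.05) {
  if (fraction <= 0 || fraction > 1) stop("'fraction' must lie in (0, 1]")
  if (length(smiles) != length(score)) {
    stop("'smiles' and 'score' must have the same length")
  }
  n <- length(smiles)
  if (n == 0L) return(character(0))
  keep <- ceiling(fraction * n)
  ord <- order(-score, smiles, method = "radix")
  smiles[ord[seq_len(min(keep, n))]]
}
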