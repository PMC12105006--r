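# Measurement-type-stratified Box-Cox + z-score normalization of pChEMBL
# affinities, with an exact inverse. Heterogeneous assay readouts (Ki, Kd,
# IC50, EC50) systematically differ; fitting the transform separately per
# measurement type puts them on one comparable target scale.

MEASUREMENT_TYPES <- c("Ki", "Kd", "IC50", "EC50")

# Case-insensitive measurement-type normalization; errors on unknown labels.
match_measurement <- function(measurement) {
  m <- MEASUREMENT_TYPES[match(toupper(measurement), toupper(MEASUREMENT_TYPES))]
  if (anyNA(m)) {
    bad <- unique(measurement[is.na(m)])
    stop("unknown measurement type(s): ", paste(bad, collapse = ", "),
         " (expected one of ", paste(MEASUREMENT_TYPES, collapse = ", "), ")")
  }
  m
}

# Box-Cox transform and its inverse; lambda = 0 is the log branch.
boxcox_transform <- function(x, lambda) {
  if (any(x <= 0)) stop("Box-Cox requires strictly positive values")
  if (abs(lambda) < 1e-12) log(x) else (x^lambda - 1) / lambda
}

boxcox_inverse <- function(y, lambda) {
  if (abs(lambda) < 1e-12) return(exp(y))
  arg <- lambda * y + 1
  if (any(arg <= 0)) {
    stop(sprintf(
      "inverse Box-Cox undefined: lambda*y + 1 must be > 0 (lambda = %.4g, min arg = %.4g)",
      lambda, min(arg)))
  }
  arg^(1 / lambda)
}

# Profile log-likelihood MLE of the Box-Cox exponent over a bounded interval.
boxcox_lambda_mle <- function(x, interval = c(-3, 3)) {
  n <- length(x)
  slx <- sum(log(x))
  negll <- function(lambda) {
    y <- boxcox_transform(x, lambda)
    s2 <- stats::var(y) * (n - 1) / n
    if (!is.finite(s2) || s2 <= 0) return(Inf)
    n / 2 * log(s2) - (lambda - 1) * slx
  }
  stats::optimize(negll, interval = interval)$minimum
}

#' Fit per-measurement-type affinity normalization
#'
#' For each measurement type present, estimates a Box-Cox exponent by maximum
#' likelihood (bounded search over `lambda_range`) and the mean and standard
#' deviation of the transformed values, so that `transform_affinity()` maps
#' each type's affinities to a zero-mean, unit-variance scale, and
#' `inverse_affinity()` maps model outputs back to pChEMBL units.
#'
#' @param pchembl numeric vector of pChEMBL values (negative log10 molar
#'   activity; must be positive after `shift`).
#' @param measurement character vector of measurement types (`Ki`, `Kd`,
#'   `IC50`, `EC50`; case-insensitive), same length as `pchembl`.
#' @param shift non-negative constant added before the power transform
#'   (defensive; pChEMBL values are already positive). Default 0.
#' @param lambda_range search interval for the Box-Cox exponent.
#' @param min_per_type minimum records required per type present (default 8).
#' @return an object of class `affinity_norm`: a per-type list of
#'   `lambda`, `shift`, `mean_t`, `sd_t`, `n`.
#' @export
affinity_normalization <- function(pchembl, measurement, shift = 0,
                                   lambda_range = c(-3, 3),
                                   min_per_type = 8L) {
  if (length(pchembl) != length(measurement)) {
    stop("'pchembl' and 'measurement' must have the same length")
  }
  if (!all(is.finite(pchembl))) stop("'pchembl' must be finite")
  if (shift < 0) stop("'shift' must be non-negative")
  measurement <- match_measurement(measurement)
  if (any(pchembl + shift <= 0)) {
    stop("all pchembl + shift values must be strictly positive")
  }
  params <- list()
  for (m in unique(measurement)) {
    x <- pchembl[measurement == m] + shift
    if (length(x) < min_per_type) {
      stop(sprintf("measurement type %s has %d records; at least %d required",
                   m, length(x), min_per_type))
    }
    if (stats::var(x) == 0) {
      stop(sprintf("measurement type %s has zero variance; cannot normalize", m))
    }
    lambda <- boxcox_lambda_mle(x, lambda_range)
    y <- boxcox_transform(x, lambda)
    sd_t <- stats::sd(y)
    if (!is.finite(sd_t) || sd_t <= 0) {
      stop(sprintf("degenerate transformed values for type %s", m))
    }
    params[[m]] <- list(lambda = lambda, shift = shift,
                        mean_t = mean(y), sd_t = sd_t, n = length(x))
  }
  structure(list(params = params, lambda_range = lambda_range),
            class = "affinity_norm")
}

#' @export
print.affinity_norm <- function(x, ...) {
  cat("Per-measurement-type Box-Cox + z-score normalization\n")
  tab <- do.call(rbind, lapply(names(x$params), function(m) {
    p <- x$params[[m]]
    data.frame(type = m, n = p$n, lambda = p$lambda, shift = p$shift,
               mean_t = p$mean_t, sd_t = p$sd_t)
  }))
  print(tab, row.names = FALSE, digits = 4)
  invisible(x)
}

norm_params_for <- function(object, measurement) {
  p <- object$params[[measurement]]
  if (is.null(p)) {
    stop(sprintf("no normalization parameters for measurement type %s", measurement))
  }
  p
}

#' Transform pChEMBL values to the normalized scale
#'
#' Applies the fitted per-type Box-Cox transform followed by a z-score:
#' `z = (boxcox(x + shift, lambda) - mean_t) / sd_t`.
#'
#' @param object an `affinity_norm` fit.
#' @param pchembl numeric vector.
#' @param measurement measurement type per value (recycled if length one).
#' @return numeric vector of normalized scores.
#' @export
transform_affinity <- function(object, pchembl, measurement) {
  stopifnot(inherits(object, "affinity_norm"))
  measurement <- match_measurement(measurement)
  if (length(measurement) == 1L) measurement <- rep(measurement, length(pchembl))
  if (length(measurement) != length(pchembl)) {
    stop("'measurement' must have length 1 or length(pchembl)")
  }
  out <- numeric(length(pchembl))
  for (m in unique(measurement)) {
    p <- norm_params_for(object, m)
    i <- measurement == m
    y <- boxcox_transform(pchembl[i] + p$shift, p$lambda)
    out[i] <- (y - p$mean_t) / p$sd_t
  }
  out
}

#' Map normalized scores back to pChEMBL units
#'
#' Exact inverse of `transform_affinity()` for the given measurement type.
#'
#' @param object an `affinity_norm` fit.
#' @param z numeric vector of normalized scores.
#' @param measurement a single measurement type (or one per score).
#' @return numeric vector of pChEMBL values.
#' @export
inverse_affinity <- function(object, z, measurement) {
  stopifnot(inherits(object, "affinity_norm"))
  measurement <- match_measurement(measurement)
  if (length(measurement) == 1L) measurement <- rep(measurement, length(z))
  if (length(measurement) != length(z)) {
    stop("'measurement' must have length 1 or length(z)")
  }
  out <- numeric(length(z))
  for (m in unique(measurement)) {
    p <- norm_params_for(object, m)
    i <- measurement == m
    y <- z[i] * p$sd_t + p$mean_t
    out[i] <- boxcox_inverse(y, p$lambda) - p$shift
  }
  out
}

# Most frequent measurement type in the fit -- the type whose inverse is used
# when a single human-readable pChEMBL is requested for an unlabeled
# candidate (logged by callers).
modal_measurement <- function(object) {
  ns <- vapply(object$params, `[[`, numeric(1), "n")
  names(ns)[which.max(ns)]
}
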