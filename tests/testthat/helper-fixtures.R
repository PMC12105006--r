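# Shared fixtures, generated in code. The small measurement mix keeps every
# type above the per-type minimum at modest library sizes.

small_mix <- c(IC50 = 0.6, Ki = 0.4, Kd = 0, EC50 = 0)

small_spec <- function(n = 200L, seed = 42L,
                       type_offsets = c(IC50 = 0, Ki = 0.25,
                                        Kd = 0, EC50 = 0), ...) {
  synthetic_spec(n_molecules = n, seed = seed, assay_mix = small_mix,
                 type_offsets = type_offsets, ...)
}

# A modest library reused across chem-level tests.
fix_spec <- small_spec(n = 500L)
fix_library <- simulate_library(fix_spec)

# Fresh Gaussian latent values pushed through the inverse Box-Cox warp:
# the direct construction used by the lambda-recovery checks.
inverse_boxcox_sample <- function(n, lambda, mean, sd, seed) {
  set.seed(seed)
  y <- stats::rnorm(n, mean, sd)
  if (abs(lambda) < 1e-12) exp(y) else (lambda * y + 1)^(1 / lambda)
}

# Identity-like normalization object (lambda = 1, recentered so the
# transformed value equals the raw value), for filter-threshold tests.
identity_norm <- function(types = "IC50") {
  params <- lapply(types, function(t) {
    list(lambda = 1, shift = 0, mean_t = -1, sd_t = 1, n = 10L)
  })
  names(params) <- types
  structure(list(params = params, lambda_range = c(-3, 3)),
            class = "affinity_norm")
}

random_profile_matrix <- function(n, seed) {
  set.seed(seed)
  matrix(stats::runif(n * 12), ncol = 12,
         dimnames = list(NULL, tox_tasks()))
}

# Lazily trained small ensemble shared across test files (training is the
# expensive step; the fixture is deterministic, so sharing is safe).
.fixture_cache <- new.env(parent = emptyenv())

shared_small_model <- function() {
  if (is.null(.fixture_cache$model)) {
    spec <- small_spec(n = 150L, seed = 23L)
    lib <- simulate_library(spec)
    aff <- simulate_affinity(lib, spec)
    .fixture_cache$model <- list(
      spec = spec, lib = lib, aff = aff,
      qsar = qsar_ensemble(aff, seed = 5, tune_folds = 3))
  }
  .fixture_cache$model
}
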