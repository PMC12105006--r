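# Synthetic benchmark generator: library grammar, planted affinity
# structure, rule-based toxicity labels.

test_that("library generation is seeded, valid and scaffold-diverse", {
  spec <- small_spec(n = 100L, seed = 77)
  l1 <- simulate_library(spec)
  l2 <- simulate_library(spec)
  expect_identical(l1, l2)
  expect_identical(l1, unique(l1))
  expect_identical(l1, canonical_smiles(l1))
  # multiple distinct ring systems present
  has_n <- grepl("n", l1)
  has_o <- grepl("o", l1)
  expect_gt(sum(has_n), 0)
  expect_gt(sum(has_o), 0)
  expect_warning(simulate_library(small_spec(n = 100000L)), "distinct")
})

test_that("affinity is a deterministic structure function in the zero-noise limit", {
  spec <- small_spec(n = 80L, seed = 78, noise_sd = 1e-9,
                     bc_lambda = c(IC50 = 1, Ki = 1, Kd = 1, EC50 = 1),
                     type_offsets = c(IC50 = 0, Ki = 0, Kd = 0, EC50 = 0))
  lib <- simulate_library(spec)
  aff <- simulate_affinity(lib, spec)
  signal <- denovoscreen:::latent_signal(lib, spec)
  # lambda = 1 warp is x = latent + 1
  expect_equal(aff$pchembl, spec$base + signal + 1, tolerance = 1e-6)
})

test_that("type offsets shift per-type means by the planted amount", {
  spec <- synthetic_spec(
    n_molecules = 2000L, seed = 79,
    assay_mix = c(IC50 = 0.5, Ki = 0.5, Kd = 0, EC50 = 0),
    type_offsets = c(IC50 = 0, Ki = 1, Kd = 0, EC50 = 0),
    bc_lambda = c(IC50 = 1, Ki = 1, Kd = 1, EC50 = 1),
    noise_sd = 0.4)
  lib <- simulate_library(spec)
  aff <- simulate_affinity(lib, spec)
  diff_mean <- mean(aff$pchembl[aff$measurement == "Ki"]) -
    mean(aff$pchembl[aff$measurement == "IC50"])
  n1 <- sum(aff$measurement == "Ki")
  n2 <- sum(aff$measurement == "IC50")
  total_sd <- sd(aff$pchembl)
  se <- total_sd * sqrt(1 / n1 + 1 / n2)
  expect_lt(abs(diff_mean - 1), 3 * se)
})

test_that("measurement types follow the configured mix within binomial error", {
  spec <- synthetic_spec(n_molecules = 2000L, seed = 80)
  lib <- simulate_library(spec)
  aff <- simulate_affinity(lib, spec)
  for (m in names(spec$assay_mix)) {
    p <- spec$assay_mix[[m]]
    obs <- mean(aff$measurement == m)
    expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / 2000) + 1e-9)
  }
})

test_that("toxicity labels follow the rules exactly without flip noise", {
  spec <- small_spec(n = 150L, seed = 81, flip_noise = 0, missing_rate = 0)
  lib <- simulate_library(spec)
  labels <- simulate_toxicity(lib, spec)
  smarts <- vapply(spec$tox_rules, `[[`, "", "smarts")
  counts <- denovoscreen:::substructure_counts(lib, smarts)
  for (j in 1:12) {
    expect_identical(labels[[j + 1L]], as.integer(counts[, j] > 0))
  }
})

test_that("missingness mask hits the configured rate", {
  spec <- small_spec(n = 500L, seed = 82, missing_rate = 0.2)
  lib <- simulate_library(spec)
  labels <- simulate_toxicity(lib, spec)
  frac <- mean(is.na(as.matrix(labels[, -1L])))
  expect_lt(abs(frac - 0.2), 3 * sqrt(0.2 * 0.8 / (500 * 12)))
})

test_that("spec validation rejects inconsistent settings", {
  expect_error(synthetic_spec(assay_mix = c(IC50 = 0.5, Ki = 0.2,
                                            Kd = 0.1, EC50 = 0.1)),
               "sum to 1")
  expect_error(synthetic_spec(noise_sd = 0), "positive")
  expect_error(synthetic_spec(n_molecules = 0), "at least 1")
  expect_error(synthetic_spec(flip_noise = 1.2), "flip_noise")
})
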