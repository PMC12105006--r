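# Generate -> filter -> append -> retrain loop invariants at reduced scale.

make_loop_inputs <- function(n = 300L, seed = 63L) {
  spec <- small_spec(n = n, seed = seed)
  lib <- simulate_library(spec)
  aff <- simulate_affinity(lib, spec)
  tox_df <- simulate_toxicity(lib, spec)
  qsar <- qsar_ensemble(aff, seed = 5, tune_folds = 3)
  toxm <- toxicity_model(tox_df, seed = 5)
  list(aff = aff, qsar = qsar, toxm = toxm,
       q3 = affinity_q3(aff, qsar$normalization))
}

loop_inputs <- make_loop_inputs()

test_that("an unsatisfiable affinity threshold yields empty iterations", {
  fc <- filter_config(affinity_threshold = Inf)
  lc <- loop_config(n_iterations = 2, batch_size = 40, filter_config = fc,
                    seed = 4)
  run <- run_design_loop(loop_inputs$aff, loop_inputs$qsar, loop_inputs$toxm,
                         lc)
  expect_equal(run$funnel$n_accepted, c(0L, 0L))
  expect_equal(length(unique(run$trajectory)), 1L)
  expect_length(run$final_candidates, 0)
})

test_that("loop structure invariants hold and the run is replayable", {
  # a permissive configuration so acceptances actually occur
  fc <- filter_config(affinity_threshold = quantile(
    transform_affinity(loop_inputs$qsar$normalization,
                       loop_inputs$aff$pchembl, loop_inputs$aff$measurement),
    0.25), sim_threshold = 0.9, sigma_thr = 2)
  lc <- loop_config(n_iterations = 3, batch_size = 60, filter_config = fc,
                    seed = 4)
  run <- run_design_loop(loop_inputs$aff, loop_inputs$qsar, loop_inputs$toxm,
                         lc)
  expect_lte(nrow(run$funnel), 3)
  expect_true(all(diff(run$trajectory) >= 0))
  acc <- unlist(run$accepted, use.names = FALSE)
  expect_gt(length(acc), 0) # the permissive config must accept something
  expect_identical(acc, unique(acc))
  expect_length(intersect(acc, unique(loop_inputs$aff$smiles)), 0)
  # every retained candidate re-passes the four filters on independent recheck
  if (length(run$final_candidates) > 0) {
    recheck <- screen_candidates(run$final_candidates, loop_inputs$qsar,
                                 loop_inputs$toxm,
                                 unique(loop_inputs$aff$smiles), fc)
    # the loop's similarity reference is a superset of the primary set, so
    # all four predicates must re-pass against the primary molecules
    expect_true(all(recheck$overall))
  }
  run2 <- run_design_loop(loop_inputs$aff, loop_inputs$qsar, loop_inputs$toxm,
                          lc)
  expect_identical(serialize(run, NULL), serialize(run2, NULL))
})

test_that("loop configuration is validated", {
  fc <- filter_config(affinity_threshold = 0)
  expect_error(loop_config(n_iterations = 6, batch_size = 10,
                           filter_config = fc), "between 1 and 5")
  expect_error(loop_config(n_iterations = 0, batch_size = 10,
                           filter_config = fc), "between 1 and 5")
  expect_error(loop_config(n_iterations = 2, batch_size = 0,
                           filter_config = fc), "at least 1")
})
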