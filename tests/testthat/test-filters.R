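# The four-filter screening cascade and top-fraction retention.

test_that("affinity threshold is the linear-interpolation third quartile", {
  recs <- data.frame(smiles = fix_library[1:8], measurement = "IC50",
                     pchembl = 1:8)
  expect_equal(affinity_q3(recs, identity_norm()), 6.25)
  one <- data.frame(smiles = fix_library[1], measurement = "IC50",
                    pchembl = 7)
  expect_equal(affinity_q3(one, identity_norm()), 7)
  same <- data.frame(smiles = fix_library[1:4], measurement = "IC50",
                     pchembl = rep(5.5, 4))
  expect_equal(affinity_q3(same, identity_norm()), 5.5)
})

test_that("filter boundary semantics are strict", {
  cfg <- filter_config(affinity_threshold = 0)
  nontox <- matrix(rep(0.1, 12), nrow = 1)
  # spread exactly at the threshold fails the consistency filter
  v <- evaluate_filters(1, 1.0, nontox, 0.1, cfg)
  expect_false(v$consistency_pass)
  # a candidate identical to a reference molecule fails similarity
  v <- evaluate_filters(1, 0.1, nontox, 1.0, cfg)
  expect_false(v$similarity_pass)
  # prediction exactly at Q3 fails affinity (strict >)
  v <- evaluate_filters(0, 0.1, nontox, 0.1, cfg)
  expect_false(v$affinity_pass)
  # probability exactly 0.5 fails toxicity
  tox <- nontox
  tox[1, 4] <- 0.5
  v <- evaluate_filters(1, 0.1, tox, 0.1, cfg)
  expect_false(v$toxicity_pass)
  # all satisfied strictly -> overall pass
  v <- evaluate_filters(1, 0.5, nontox, 0.3, cfg)
  expect_true(v$overall)
})

test_that("verdicts agree with direct evaluation of the printed predicates", {
  set.seed(31)
  n <- 1000
  f_pch <- rnorm(n)
  sigma <- abs(rnorm(n, 1, 0.5))
  s_d <- runif(n)
  profile <- random_profile_matrix(n, seed = 32)
  q3 <- 0.2
  cfg <- filter_config(affinity_threshold = q3)
  v <- evaluate_filters(f_pch, sigma, profile, s_d, cfg)
  for (i in seq_len(n)) {
    expect_identical(v$affinity_pass[i], f_pch[i] > q3)
    expect_identical(v$toxicity_pass[i],
                     sum(ifelse(profile[i, ] >= 0.5, 1, 0)) == 0)
    expect_identical(v$similarity_pass[i], s_d[i] < 0.5)
    expect_identical(v$consistency_pass[i], sigma[i] < 1)
    expect_identical(v$overall[i],
                     v$affinity_pass[i] && v$toxicity_pass[i] &&
                       v$similarity_pass[i] && v$consistency_pass[i])
  }
})

test_that("relaxing thresholds never shrinks the survivor set; filtering is idempotent", {
  set.seed(33)
  n <- 400
  f_pch <- rnorm(n)
  sigma <- abs(rnorm(n, 1, 0.5))
  s_d <- runif(n)
  profile <- random_profile_matrix(n, seed = 34)
  base <- filter_config(affinity_threshold = 0.3, sim_threshold = 0.4,
                        sigma_thr = 0.8)
  v0 <- evaluate_filters(f_pch, sigma, profile, s_d, base)
  relaxed <- filter_config(affinity_threshold = 0.1, sim_threshold = 0.6,
                           sigma_thr = 1.2)
  v1 <- evaluate_filters(f_pch, sigma, profile, s_d, relaxed)
  expect_true(all(v1$overall[v0$overall]))
  surv <- which(v0$overall)
  v2 <- evaluate_filters(f_pch[surv], sigma[surv],
                         profile[surv, , drop = FALSE], s_d[surv], base)
  expect_true(all(v2$overall))
})

test_that("retention keeps the ceiling of the fraction, ties broken lexicographically", {
  smiles <- sprintf("mol%03d", 1:100)
  score <- seq(1, 100) / 100
  kept <- retain_top(smiles, score, 0.05)
  expect_length(kept, 5)
  expect_true(all(score[match(kept, smiles)] >= 0.96))
  expect_length(retain_top(smiles[1:3], score[1:3], 0.05), 1) # ceil(0.15)
  expect_identical(retain_top(smiles[1:3], score[1:3], 0.9), smiles[3:1])
  tied <- retain_top(c("b", "a", "c"), c(1, 1, 1), 1 / 3)
  expect_identical(tied, "a")
  expect_error(retain_top(smiles, score, 0), "\\(0, 1\\]")
  expect_identical(retain_top(character(0), numeric(0), 0.5), character(0))
})
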