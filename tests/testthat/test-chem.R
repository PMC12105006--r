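# Molecule identity, fingerprints and Tanimoto similarity.

test_that("canonicalization maps equivalent SMILES together and is idempotent", {
  expect_equal(canonical_smiles("C1=CC=CC=C1"), canonical_smiles("c1ccccc1"))
  once <- canonical_smiles(fix_library)
  expect_identical(canonical_smiles(once), once)
})

test_that("unparsable SMILES raise a structured error naming the input", {
  expect_error(canonical_smiles("not_a_smiles"), "not_a_smiles")
  expect_error(canonical_smiles(c("CCO", "xx$$yy")), "position 2")
  expect_warning(out <- canonical_smiles(c("CCO", "xx$$yy"),
                                         skip_invalid = TRUE),
                 "position 2")
  expect_false(is.na(out[1]))
  expect_true(is.na(out[2]))
  expect_error(canonical_smiles(character(0)))
  expect_error(canonical_smiles(c("CCO", "")))
})

test_that("circular fingerprints are deterministic and structure-sensitive", {
  fp1 <- morgan_fp(c("c1ccccc1", "c1ccccc1"))
  expect_identical(fp1[1, ], fp1[2, ])
  expect_equal(ncol(fp1), 2048L)
  expect_gte(sum(morgan_fp("C")[1, ]), 1L)
  fp2 <- morgan_fp(c("c1ccccc1", "C1CCCCC1"))
  expect_true(any(fp2[1, ] != fp2[2, ]))
})

test_that("fingerprint argument errors are raised", {
  expect_error(morgan_fp("C", n_bits = 0), "positive")
  expect_error(morgan_fp("C", radius = -1), "non-negative")
  expect_error(morgan_fp("C", n_bits = 1000), "power of two")
  expect_error(morgan_fp("invalid$smiles"), "fingerprint generation failed")
})

test_that("tanimoto matches its set definition and conventions", {
  a <- c(1, 1, 1, 0)
  b <- c(0, 1, 1, 1)
  expect_equal(tanimoto(a, b), 0.5) # on-bits {1,2,3} vs {2,3,4}
  expect_equal(tanimoto(a, a), 1.0)
  expect_equal(tanimoto(c(1, 1, 0, 0), c(0, 0, 1, 1)), 0.0)
  expect_equal(tanimoto(c(0, 0, 0), c(0, 0, 0)), 1.0) # degenerate convention
  expect_error(tanimoto(c(1, 0), c(1, 0, 1)), "lengths differ")
})

test_that("tanimoto is symmetric on random fingerprint pairs", {
  set.seed(11)
  for (i in 1:50) {
    a <- rbinom(64, 1, 0.3)
    b <- rbinom(64, 1, 0.3)
    expect_identical(tanimoto(a, b), tanimoto(b, a))
  }
})

test_that("max_similarity equals a brute-force loop over the reference set", {
  mols <- fix_library[1:120]
  fps <- morgan_fp(mols)
  ref <- fps[21:120, , drop = FALSE]
  got <- max_similarity(fps[1:20, , drop = FALSE], ref)
  brute <- vapply(1:20, function(i) {
    max(vapply(seq_len(nrow(ref)),
               function(j) tanimoto(fps[i, ], ref[j, ]), numeric(1)))
  }, numeric(1))
  expect_equal(got, brute, tolerance = 1e-12)
  # each maximum dominates every pairwise similarity
  expect_true(all(got >= denovoscreen:::tanimoto_matrix(fps[1:20, , drop = FALSE], ref) - 1e-12))
})

test_that("max_similarity boundary behavior", {
  mols <- fix_library[1:5]
  expect_equal(max_similarity(mols[1], mols)[1], 1.0)
  single <- max_similarity(mols[2], mols[1])
  expect_equal(single, tanimoto(morgan_fp(mols[2])[1, ],
                                morgan_fp(mols[1])[1, ]))
  expect_error(max_similarity(mols[1], character(0)), "non-empty")
})

test_that("smiles files round-trip and invalid rows are reported", {
  path <- withr::local_tempfile(fileext = ".smi")
  write_smiles(fix_library[1:10], path)
  expect_identical(read_smiles(path), fix_library[1:10])
  csv <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(smiles = c(fix_library[1], "bad$row")), csv,
            row.names = FALSE)
  expect_error(read_smiles(csv), "position 2")
  expect_warning(out <- read_smiles(csv, skip_invalid = TRUE), "position 2")
  expect_identical(out, fix_library[1])
})
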