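# Measurement-stratified Box-Cox + z-score normalization.

test_that("closed-form branches of the power transform hold", {
  bc <- denovoscreen:::boxcox_transform
  inv <- denovoscreen:::boxcox_inverse
  x <- c(0.5, 1, 2, 7.3)
  expect_equal(bc(x, 1), x - 1)
  expect_equal(bc(x, 0), log(x))
  expect_equal(inv(log(x), 0), x)
  expect_equal(inv(bc(x, 0.37), 0.37), x, tolerance = 1e-12)
  expect_error(bc(c(-1, 2), 0.5), "positive")
  expect_error(inv(-10, 0.5), "lambda\\*y")
})

test_that("fitted normalization standardizes each type to mean 0, sd 1", {
  x <- inverse_boxcox_sample(300, 0.5, 3.4, 0.8, seed = 1)
  m <- rep(c("IC50", "Ki"), length.out = 300)
  fit <- affinity_normalization(x, m)
  z <- transform_affinity(fit, x, m)
  for (t in c("IC50", "Ki")) {
    expect_lt(abs(mean(z[m == t])), 1e-9)
    expect_lt(abs(sd(z[m == t]) - 1), 1e-9)
  }
})

test_that("types are fitted independently of each other's records", {
  x1 <- inverse_boxcox_sample(150, 0.5, 3.4, 0.6, seed = 2)
  x2 <- inverse_boxcox_sample(150, 1.2, 3.0, 0.5, seed = 3)
  joint <- affinity_normalization(c(x1, x2),
                                  rep(c("IC50", "Ki"), each = 150))
  alone <- affinity_normalization(x1, rep("IC50", 150))
  expect_equal(joint$params$IC50, alone$params$IC50)
})

test_that("degenerate inputs are rejected", {
  expect_error(affinity_normalization(rep(5, 20), rep("IC50", 20)),
               "zero variance")
  expect_error(affinity_normalization(runif(5) + 5, rep("IC50", 5)),
               "at least 8")
  expect_error(affinity_normalization(c(-1, runif(19) + 5), rep("Ki", 20)),
               "strictly positive")
  expect_error(affinity_normalization(runif(20) + 5, rep("XX50", 20)),
               "unknown measurement")
  fit <- affinity_normalization(runif(20) + 5, rep("IC50", 20))
  expect_error(transform_affinity(fit, 5, "Ki"), "no normalization parameters")
})

test_that("transform/inverse round-trip is exact over random exponents", {
  set.seed(7)
  for (trial in 1:20) {
    # arbitrary exponent applied to fixed positive data: the round trip and
    # monotonicity must hold for any lambda in the search range
    lambda <- runif(1, -2, 2)
    params <- structure(
      list(params = list(IC50 = list(lambda = lambda, shift = 0,
                                     mean_t = 0.5, sd_t = 0.7, n = 10L)),
           lambda_range = c(-3, 3)),
      class = "affinity_norm")
    x <- exp(rnorm(200, 0.5, 0.3))
    z <- transform_affinity(params, x, "IC50")
    back <- inverse_affinity(params, z, "IC50")
    expect_lt(max(abs(back - x)), 1e-9)
    # monotone: order preserved
    expect_identical(order(z), order(x))
  }
  # z = 0 maps to the back-transformed per-type transformed mean
  x <- inverse_boxcox_sample(100, 0.5, 3.4, 0.5, seed = 9)
  fit <- affinity_normalization(x, rep("Kd", 100))
  p <- fit$params$Kd
  expect_equal(inverse_affinity(fit, 0, "Kd"),
               denovoscreen:::boxcox_inverse(p$mean_t, p$lambda))
})

test_that("lambda MLE agrees with the profile-likelihood grid oracle", {
  x <- inverse_boxcox_sample(400, 0.5, 3.4, 0.8, seed = 13)
  got <- denovoscreen:::boxcox_lambda_mle(x)
  prof <- MASS::boxcox(x ~ 1, lambda = seq(-1, 2, 0.005), plotit = FALSE)
  oracle <- prof$x[which.max(prof$y)]
  expect_lt(abs(got - oracle), 0.01)
})

test_that("a planted exponent is recovered from warped Gaussian samples", {
  errs <- vapply(1:5, function(s) {
    x <- inverse_boxcox_sample(500, 0.5, 3.4, 1.0, seed = 200 + s)
    fit <- affinity_normalization(x, rep("IC50", 500))
    abs(fit$params$IC50$lambda - 0.5)
  }, numeric(1))
  expect_true(all(errs < 0.2))
})
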