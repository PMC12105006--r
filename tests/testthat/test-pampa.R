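# PAMPA transmittance, permeability and CNS classification.

test_that("transmittance matches the printed expression", {
  g <- pampa_geometry()
  expect_equal(transmittance(1.0, 0, g), 0)
  expect_equal(transmittance(0.8, 0.8, g), 100)
  expect_equal(transmittance(1.0, 0.25, g), 25)
  set.seed(51)
  g2 <- pampa_geometry(v_donor = 0.3, v_receptor = 0.18)
  for (trial in 1:100) {
    ad <- runif(1, 0.1, 2)
    ar <- runif(1, 0, 1.5)
    expect_equal(transmittance(ad, ar, g2),
                 100 * g2$v_receptor * ar / (g2$v_donor * ad))
  }
  expect_error(transmittance(0, 0.5, g), "strictly positive")
  expect_error(transmittance(1, -0.1, g), "non-negative")
  expect_error(pampa_geometry(v_donor = 0), "strictly positive")
})

test_that("permeability matches the hand oracle and is monotone", {
  g <- pampa_geometry()
  expect_equal(pampa_permeability(0, g), 0)
  # hand computation at the default geometry:
  # prefactor = 0.2*0.2 / ((0.2+0.2)*0.2642*10800) = 3.504635e-5 cm/s,
  # f_eq = 0.5, %T = 25 -> -ln(1 - 0.5) = ln 2 -> Pe = 24.292307 e-6 cm/s
  expect_equal(pampa_permeability(25, g), 24.292307, tolerance = 1e-6)
  tt <- seq(0.5, 49.5, by = 0.5)
  pe <- pampa_permeability(tt, g)
  expect_true(all(diff(pe) > 0))
  expect_error(pampa_permeability(50, g), "saturation")
  expect_error(pampa_permeability(60, g), "saturation")
})

test_that("the verbatim printed expression is audit-only at equal volumes", {
  expect_error(pampa_permeability(25, pampa_geometry(), formula = "printed"),
               "Vd - Vr")
  g <- pampa_geometry(v_donor = 0.3, v_receptor = 0.15)
  got <- pampa_permeability(10, g, formula = "printed")
  direct <- 0.3 * 0.15 / ((0.3 - 0.15) * g$area * g$time) *
    (100 * 0.3) / (100 * 0.3 - 10 * (0.3 - 0.15)) * 1e6
  expect_equal(got, direct)
})

test_that("CNS classification reproduces the bibliographic thresholds", {
  cal <- cns_calibration(experimental = 1:6, literature = 1:6)
  expect_equal(cal$slope, 1)
  expect_equal(cal$t_hi, 4)
  expect_equal(cal$t_lo, 2)
  expect_identical(as.character(classify_cns(cal, c(5, 3, 1))),
                   c("CNS+", "CNS+/-", "CNS-"))
  # boundary values are ambiguous, not CNS+/-
  expect_identical(as.character(classify_cns(cal, c(4, 2))),
                   c("CNS+/-", "CNS+/-"))
  expect_error(cns_calibration(1:2, 1:2), "at least 3")
  expect_error(cns_calibration(c(3, 2, 1), c(1, 2, 3)), "not positive")
  expect_error(cns_calibration(1:3, rep(2, 3)), "degenerate")
})

test_that("classification is invariant under joint rescaling of the assay", {
  set.seed(55)
  lit <- runif(8, 0.5, 8)
  exp_pe <- 1.7 * lit + 0.3 + rnorm(8, sd = 0.1)
  cal <- cns_calibration(exp_pe, lit)
  compounds <- runif(20, 0, 12)
  cls <- classify_cns(cal, compounds)
  scale <- 3.2
  cal2 <- cns_calibration(exp_pe * scale, lit)
  cls2 <- classify_cns(cal2, compounds * scale)
  expect_identical(cls, cls2)
})

test_that("plate analysis averages replicates and wavelengths", {
  plate <- data.frame(
    compound = rep(c("a", "b"), each = 4),
    replicate = rep(1:2, times = 4),
    a_donor_pre = 1,
    a_receptor_post = c(0.10, 0.12, 0.14, 0.16, 0.30, 0.30, 0.32, 0.32))
  res <- pampa_analyze(plate)
  expect_equal(res$percent_t[res$compound == "a"], mean(c(10, 12, 14, 16)))
  expect_equal(res$n_wells, c(4L, 4L))
  expect_equal(res$pe[res$compound == "a"],
               pampa_permeability(13, pampa_geometry()))
  expect_error(pampa_analyze(data.frame(compound = "a")), "must contain")
})

test_that("the bundled synthetic plate file runs the full PAMPA workflow", {
  plate <- read_pampa_plate(system.file("extdata", "synthetic_pampa_plate.csv",
                                        package = "denovoscreen"))
  res <- pampa_analyze(plate)
  expect_equal(nrow(res), 8)
  expect_true(all(res$pe > 0))
  refs <- read.csv(system.file("extdata", "synthetic_reference_drugs.csv",
                               package = "denovoscreen"))
  cal <- cns_calibration(res$pe[match(refs$drug, res$compound)],
                         refs$literature_pe)
  cls <- classify_cns(cal, res$pe)
  # permeability ordering must be reflected in the classes
  expect_identical(as.character(cls[res$compound == "ref_drug_01"]), "CNS+")
  expect_identical(as.character(cls[res$compound == "ref_drug_05"]), "CNS-")
  expect_error(read_pampa_plate(system.file("extdata",
                                            "synthetic_reference_drugs.csv",
                                            package = "denovoscreen")),
               "missing column")
})
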