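# Seeded synthetic benchmark generator. Produces a molecule library from a
# scaffold-plus-substituent grammar (bicyclic heteroaryl cores with varied
# ring substituents), then plants a structure-dependent affinity signal with
# measurement-type imbalance, per-type offsets, a per-type Box-Cox warp and
# Gaussian noise, and 12 substructure-rule toxicity labels with flip noise
# and missingness. Everything is deterministic given the spec's seed, so the
# whole pipeline is testable without any external dataset. The grammar is
# deliberately generic: no test depends on a specific real chemotype.

scaffold_templates <- function() {
  c(benzimidazole   = "c1cc({A})cc2c1nc({B})[nH]2",
    indole          = "c1cc({A})cc2c1cc({B})[nH]2",
    quinazoline     = "c1cc({A})cc2c1ncc({B})n2",
    benzofuran      = "c1cc({A})cc2c1cc({B})o2",
    benzothiophene  = "c1cc({A})cc2c1cc({B})s2",
    azaindole       = "c1cc({A})c2cc({B})[nH]c2n1",
    benzoxazole     = "c1cc({A})cc2c1nc({B})o2",
    indazole        = "c1cc({A})cc2c1c({B})n[nH]2",
    quinoline       = "c1cc({A})cc2c1ncc({B})c2",
    imidazopyridine = "c1cc({A})cn2c1nc({B})c2")
}

substituent_set <- function() {
  c("", "C", "CC", "CCC", "C(C)C", "OC", "OCC", "N", "NC", "N(C)C",
    "F", "Cl", "Br", "C#N", "C(F)(F)F", "CO", "CCO", "C(=O)N", "C(=O)NC",
    "S(=O)(=O)N", "C(=O)OC", "c3ccccc3", "c3ccncc3", "C3CC3", "OC(F)F",
    "NC(C)=O")
}

default_signal_substructures <- function() {
  list(list(smarts = "C(=O)N",        weight =  1.10),
       list(smarts = "[OX2H]",        weight =  0.90),
       list(smarts = "a[F,Cl,Br]",    weight =  0.80),
       list(smarts = "S(=O)(=O)N",    weight = -1.30),
       list(smarts = "C(F)(F)F",      weight = -0.90),
       list(smarts = "[nX2]",         weight =  0.50),
       list(smarts = "O[CH3]",        weight = -0.60))
}

default_tox_rules <- function() {
  rules <- list(
    list(smarts = "a[Cl,Br]",        positive = TRUE),
    list(smarts = "S(=O)(=O)N",      positive = TRUE),
    list(smarts = "C(F)(F)F",        positive = TRUE),
    list(smarts = "C#N",             positive = TRUE),
    list(smarts = "[OX2H]",          positive = TRUE),
    list(smarts = "O[CH3]",          positive = TRUE),
    list(smarts = "C(=O)N",          positive = TRUE),
    list(smarts = "c3ccncc3",        positive = TRUE),
    list(smarts = "N(C)C",           positive = TRUE),
    list(smarts = "[s,o]1cccc1",     positive = TRUE),
    list(smarts = "C(=O)OC",         positive = TRUE),
    list(smarts = "aF",              positive = TRUE))
  stats::setNames(rules, tox_tasks())
}

#' Specification for the synthetic benchmark
#'
#' Defaults emulate the study conditions of a heterogeneous kinase-inhibitor
#' affinity table: an IC50-dominated measurement mix, per-type offsets on the
#' transformed scale, a per-type Box-Cox warp (exponent 0.5), and Gaussian
#' assay noise of 0.4.
#'
#' @param n_molecules library size (default 1782).
#' @param seed integer seed.
#' @param assay_mix named measurement-type frequencies (must sum to 1).
#' @param type_offsets named per-type shifts on the latent (transformed)
#'   scale.
#' @param noise_sd Gaussian noise SD on the latent scale (> 0).
#' @param bc_lambda named per-type Box-Cox exponents used to warp the latent
#'   scale into pChEMBL units (1 = no warp).
#' @param base latent-scale intercept; with the default warp this puts the
#'   typical pChEMBL near 7.
#' @param signal_substructures list of `list(smarts =, weight =)` terms
#'   defining the structural affinity signal.
#' @param tox_rules named list (one per task) of `list(smarts =, positive =)`
#'   label rules.
#' @param flip_noise per-task label flip probability.
#' @param missing_rate per-task missing-label probability.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_molecules = 1782L, seed = 1L,
                           assay_mix = c(IC50 = 0.72, Ki = 0.20,
                                         Kd = 0.05, EC50 = 0.03),
                           type_offsets = c(IC50 = 0, Ki = 0.25,
                                            Kd = -0.2, EC50 = -0.35),
                           noise_sd = 0.4,
                           bc_lambda = c(IC50 = 0.5, Ki = 0.5,
                                         Kd = 0.5, EC50 = 0.5),
                           base = 3.4,
                           signal_substructures = default_signal_substructures(),
                           tox_rules = default_tox_rules(),
                           flip_noise = 0.1,
                           missing_rate = 0.1) {
  if (n_molecules < 1L) stop("'n_molecules' must be at least 1")
  if (abs(sum(assay_mix) - 1) > 1e-8) stop("'assay_mix' must sum to 1")
  if (noise_sd <= 0) stop("'noise_sd' must be positive")
  if (flip_noise < 0 || flip_noise > 1) stop("'flip_noise' must lie in [0, 1]")
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("'missing_rate' must lie in [0, 1)")
  }
  names(assay_mix) <- match_measurement(names(assay_mix))
  names(type_offsets) <- match_measurement(names(type_offsets))
  names(bc_lambda) <- match_measurement(names(bc_lambda))
  structure(list(n_molecules = as.integer(n_molecules), seed = as.integer(seed),
                 assay_mix = assay_mix, type_offsets = type_offsets,
                 noise_sd = noise_sd, bc_lambda = bc_lambda, base = base,
                 signal_substructures = signal_substructures,
                 tox_rules = tox_rules, flip_noise = flip_noise,
                 missing_rate = missing_rate),
            class = "synthetic_spec")
}

#' Generate the synthetic molecule library
#'
#' Enumerates the scaffold-substituent grammar, canonicalizes and
#' deduplicates it, and draws `n_molecules` distinct molecules. If the
#' grammar holds fewer distinct molecules than requested, all of them are
#' returned with a warning.
#'
#' @param spec a [synthetic_spec()].
#' @return character vector of canonical SMILES.
#' @export
simulate_library <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  templates <- scaffold_templates()
  subs <- substituent_set()
  grid <- expand.grid(template = templates, a = subs, b = subs,
                      stringsAsFactors = FALSE)
  raw <- mapply(function(t, a, b) {
    t <- sub("({A})", if (nzchar(a)) paste0("(", a, ")") else "", t,
             fixed = TRUE)
    sub("({B})", if (nzchar(b)) paste0("(", b, ")") else "", t, fixed = TRUE)
  }, grid$template, grid$a, grid$b, USE.NAMES = FALSE)
  can <- ob_smiles_convert(raw)
  can <- unique(can[!is.na(can)])
  set.seed(spec$seed)
  if (length(can) < spec$n_molecules) {
    warning(sprintf("grammar yields %d distinct molecules; %d requested",
                    length(can), spec$n_molecules), call. = FALSE)
    return(sample(can))
  }
  sample(can, spec$n_molecules)
}

# Count SMARTS matches for each molecule (batch, in-process).
substructure_counts <- function(smiles, smarts) {
  obs <- ChemmineOB::forEachMol("SMILES",
                                paste(paste(smiles, seq_along(smiles)),
                                      collapse = "\n"),
                                identity)
  if (length(obs) != length(smiles)) {
    stop("substructure counting failed: could not parse all molecules")
  }
  vapply(smarts, function(pat) {
    as.numeric(ChemmineOB::smartsSearch_OB(obs, pat, uniqueMatches = TRUE))
  }, numeric(length(smiles)))
}

# Deterministic structural affinity signal of a molecule set.
latent_signal <- function(smiles, spec) {
  smarts <- vapply(spec$signal_substructures, `[[`, "", "smarts")
  w <- vapply(spec$signal_substructures, `[[`, numeric(1), "weight")
  counts <- substructure_counts(smiles, smarts)
  as.numeric(counts %*% w)
}

#' Simulate heterogeneous affinity records
#'
#' Each molecule gets a measurement type drawn from `assay_mix`; its latent
#' value is `base + type_offset + structural signal + Gaussian noise`, and
#' the recorded pChEMBL is the inverse Box-Cox warp (exponent
#' `bc_lambda[type]`) of the latent value, so that the per-type distributions
#' are skewed the way the fitted normalization expects to undo.
#'
#' @param smiles molecule library (from [simulate_library()]).
#' @param spec a [synthetic_spec()].
#' @return data.frame with columns `smiles`, `measurement`, `pchembl`.
#' @export
simulate_affinity <- function(smiles, spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (length(smiles) == 0L) stop("'smiles' must be non-empty")
  signal <- latent_signal(smiles, spec)
  set.seed(spec$seed + 1L)
  measurement <- sample(names(spec$assay_mix), length(smiles), replace = TRUE,
                        prob = spec$assay_mix)
  latent <- spec$base + spec$type_offsets[measurement] + signal +
    stats::rnorm(length(smiles), 0, spec$noise_sd)
  pchembl <- numeric(length(smiles))
  for (m in unique(measurement)) {
    i <- measurement == m
    pchembl[i] <- boxcox_inverse(latent[i], spec$bc_lambda[[m]])
  }
  data.frame(smiles = smiles, measurement = unname(measurement),
             pchembl = pchembl, stringsAsFactors = FALSE)
}

#' Simulate 12-task toxicity labels
#'
#' Task labels follow their substructure rule (presence of the rule's
#' pattern), each independently flipped with probability `flip_noise` and
#' masked as missing with probability `missing_rate`.
#'
#' @param smiles molecule library.
#' @param spec a [synthetic_spec()].
#' @return data.frame: `smiles` plus 12 label columns in [tox_tasks()] order
#'   (0/1 with `NA` for missing).
#' @export
simulate_toxicity <- function(smiles, spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (length(smiles) == 0L) stop("'smiles' must be non-empty")
  smarts <- vapply(spec$tox_rules, `[[`, "", "smarts")
  counts <- substructure_counts(smiles, smarts)
  rule <- counts > 0
  positive <- vapply(spec$tox_rules, `[[`, logical(1), "positive")
  rule[, !positive] <- !rule[, !positive]
  set.seed(spec$seed + 2L)
  n <- length(smiles)
  labels <- matrix(NA_integer_, nrow = n, ncol = length(spec$tox_rules),
                   dimnames = list(NULL, names(spec$tox_rules)))
  for (j in seq_along(spec$tox_rules)) {
    flip <- stats::runif(n) < spec$flip_noise
    lab <- as.integer(xor(rule[, j], flip))
    lab[stats::runif(n) < spec$missing_rate] <- NA_integer_
    labels[, j] <- lab
  }
  cbind(data.frame(smiles = smiles, stringsAsFactors = FALSE),
        as.data.frame(labels))
}
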