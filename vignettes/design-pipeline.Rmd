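---
title: "An ensemble-QSAR design pipeline for nontoxic kinase-inhibitor candidates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An ensemble-QSAR design pipeline for nontoxic kinase-inhibitor candidates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Hit discovery for a kinase target typically starts from a modest set of
known inhibitors whose activities were measured under heterogeneous assay
protocols (Ki, Kd, IC50, EC50, summarized as pChEMBL = -log10 of the molar
activity). `denovoscreen` implements a complete desk pipeline around such a
table: it normalizes the heterogeneous affinities onto one target scale,
fits an ensemble QSAR regressor with an internal-consistency estimate, fits
a 12-task toxicity gate, and then runs an iterative generate-filter-retrain
loop around a pluggable molecule generator, retaining only candidates that
pass four screening filters. A separate module computes PAMPA
blood-brain-barrier permeabilities from plate absorbances and classifies
compounds against calibrated CNS thresholds.

## Affinity normalization

Different measurement types produce systematically shifted and differently
skewed pChEMBL distributions, so records are normalized separately per
type. For type $m$ with raw value $x$:

$$ y = \frac{(x+s)^{\lambda_m} - 1}{\lambda_m} \quad (\lambda_m \neq 0),
\qquad y = \ln(x+s) \quad (\lambda_m = 0), \qquad
z = \frac{y - \mu_m}{\sigma_m} $$

$\lambda_m$ is the Box-Cox exponent estimated by profile maximum likelihood
over a bounded interval ($[-3, 3]$; the profile is unimodal in practice and
`optimize()` finds the maximizer to machine precision — a grid-based
profile-likelihood oracle agrees to $<0.01$). The shift $s$ defaults to 0
because pChEMBL values are positive; it is configurable defensively. The
transform is monotone and exactly invertible, and the package refuses
degenerate fits (fewer than 8 records per type, zero within-type variance).

Two reporting decisions were genuinely open:

* **Threshold scale.** The affinity filter's Q3 threshold is computed on the
  *normalized* scale (the scale all model predictions live on), with the
  linear-interpolation quantile convention.
* **Inverse for unlabeled candidates.** A generated molecule has no
  measurement type, so a single human-readable pChEMBL is reported through
  the inverse transform of the *modal* measurement type of the training
  data (IC50-dominated tables in practice); the choice is logged in the
  prediction message.

## The ensemble QSAR model

Four member regressors are trained on the normalized scale and combined
with homogeneous (uniform) weights:

* gradient-boosted trees on circular + path fingerprint bits,
* a radial-kernel support-vector regressor on the descriptor vector
  (physicochemical properties + MACCS substructure keys, standardized)
  plus path fingerprint bits,
* a k-nearest-neighbor regressor on L2-row-normalized circular
  fingerprints, which turns its Euclidean neighbor search into a
  cosine-similarity search — the natural metric for fingerprint vectors,
* a feed-forward neural network on the standardized descriptor vector.

The neural member is a *contract*: any regressor consuming a molecular
graph or descriptor vector can be plugged in through `regressor_spec()`; a
message-passing network qualifies. The default feed-forward implementation
averages three random restarts, because small nets are sensitive to weight
initialization and the restart mean is the stable predictor.

For molecule $G$, the ensemble reports

$$ f_{\mathrm{pch}}(G) = \frac{1}{4}\sum_{i=1}^{4} \hat y_i(G), \qquad
\hat\sigma_{\mathrm{ens}}(G) = \sqrt{\tfrac{1}{4}\sum_i (\hat y_i(G) -
f_{\mathrm{pch}}(G))^2}. $$

The spread uses the population (n-divisor) standard deviation: the filter
threshold $\sigma_{\mathrm{thr}} = 1$ is stated on the $\sigma$ scale, and
the four member outputs are the complete population of predictions for that
molecule, not a sample. Weighted averaging is exposed as an option but
defaults to uniform.

Hyperparameters are chosen by grid search scored on mean cross-validated
RMSE with folds stratified by measurement type (stratification keeps every
fold's assay mix representative and every training fold normalizable;
evaluation at `k = 10`). `qsar_cv()` reports RMSE, MAE, explained-variance
score and $R^2$ per model and fold, refitting the normalization inside each
training fold so no test information leaks into the target scale; folds
with zero target variance report the variance-based metrics as `NA` rather
than propagating NaN. `rank_models()` aggregates the four metrics into mean
ranks with the average-tie convention.

## The toxicity gate

The 12-endpoint model is likewise a contract. The default implementation
fits one gradient-boosted classifier per endpoint on circular fingerprint
bits, excluding missing labels from that endpoint's training set; an
endpoint observed with a single class falls back to its class prior with a
warning. A compound is nontoxic only if all 12 predicted probabilities are
strictly below the threshold; a probability of exactly 0.5 counts as toxic
(the indicator is $1$ when $p \ge 0.5$). Stricter per-endpoint thresholds
can be supplied as a 12-vector.

## The four screening filters

Candidates are screened by the conjunction of four strict predicates:

| filter | predicate | default threshold |
|---|---|---|
| affinity | $f_{\mathrm{pch}}(G) > Q_3$ | third quartile of training scores |
| toxicity | $\sum_i \mathbf{1}[p_i \ge t] = 0$ | $t = 0.5$ |
| similarity | $s_D(G) = \max_{G' \in D} T(G, G') < t_s$ | $t_s = 0.5$ |
| consistency | $\hat\sigma_{\mathrm{ens}}(G) < \sigma_{\mathrm{thr}}$ | $\sigma_{\mathrm{thr}} = 1$ |

All comparisons are strict, so boundary cases fail. All four predicates are
always evaluated (no short-circuiting) so that the per-candidate
diagnostics are complete. The similarity statistic uses 2048-bit, radius-2
circular fingerprints — the community default; the filter's fingerprint
parameters are a package decision, not a literature constant. The Tanimoto
coefficient of two all-zero fingerprints is defined as 1 (two featureless
objects are indistinguishable), a degenerate case that matters only for
pathological inputs.

Survivor retention keeps the top `retain_fraction` (default 5%) of the
*survivor* set by predicted affinity, rounding the quota up so a non-empty
survivor list never retains zero, with ties at the cut broken by
canonical-SMILES order for determinism.

## The generate-filter-retrain loop

The generator is pluggable; the default recombines retrosynthetic-style
fragments. Every training molecule is cleaved at each acyclic single bond
(graph bridges of bond order 1 — ring systems stay intact), and fragments
carry their attachment atom. Joining two fragments with a single bond
restores exactly the valence each attachment atom lost at cleavage, so
every recombination is valence-consistent by construction; products are
still reparsed, canonicalized, and deduplicated, and must be absent from
the training set. Generation is seeded and has an attempt budget of
$50 \times n$ assemblies, after which it returns fewer molecules with a
warning rather than looping.

Each loop iteration generates a batch, screens it, appends survivors to the
generator's training set, and rebuilds the generator. Two design points:

* **Only the generator retrains in-loop.** Survivors have no measured
  labels, so refitting the affinity or toxicity models on them would train
  on their own predictions.
* **The similarity reference grows** (primary set plus earlier
  acceptances), suppressing near-duplicates of earlier acceptances. The
  similarity statistic is defined against the primary set; extending the
  reference is a strictly more conservative interpretation.

The iteration count is capped at 5: prolonged recursion concentrates the
generator on its own output and defeats the novelty filter. Retention is
applied once over the pooled survivors of all iterations. Funnel counts per
iteration are diagnostics, not reproducible quantities.

## PAMPA-BBB module

Percent transmittance and effective permeability follow the standard
two-compartment solution

$$ \%T = 100\,\frac{V_r A_r}{V_d A_d}, \qquad
P_e = \frac{V_d V_r}{(V_d + V_r)\,S\,t}\,
\left(-\ln\!\left(1 - \frac{f}{f_{eq}}\right)\right), $$

with $f = \%T/100$ and $f_{eq} = V_r/(V_d+V_r)$, at the standard plate
geometry ($V_d = V_r = 0.2\ \mathrm{cm^3}$, $S = 0.2642\ \mathrm{cm^2}$,
$t = 10{,}800$ s), reported in $10^{-6}$ cm/s. An alternative closed form
sometimes quoted for this assay carries $(V_d - V_r)$ in denominators and
no logarithm; it is undefined for equal-volume plates and is therefore kept
behind `formula = "printed"` for audit only, with a diagnostic when
$V_d = V_r$. A compound whose transferred fraction reaches $f_{eq}$ is at
equilibrium and has no finite permeability; this is a saturation error, not
a number.

Reference drugs with literature permeabilities calibrate the classification:
a least-squares fit of experimental on literature $P_e$ maps the
bibliographic bounds ($4$ and $2 \times 10^{-6}$ cm/s) onto the
experimental scale; compounds above/below/between the mapped bounds are
CNS+, CNS-, CNS+/-. A non-positive calibration slope invalidates the run.
Replicates and wavelengths are averaged per compound with the standard
deviation reported.

## The synthetic benchmark

`synthetic_spec()` defines seeded study conditions emulating a curated
kinase-affinity table, with no external download:

* a **library** drawn from a scaffold grammar of 10 bicyclic heteroaryl
  cores with two substitution sites over 26 substituents, enumerated,
  canonicalized and deduplicated (several thousand distinct molecules; the
  default library size is 1782);
* an **affinity table** whose latent value is `base + type offset +
  structural signal + N(0, noise_sd)` with `noise_sd = 0.4` and a planted
  per-type Box-Cox warp (exponent 0.5) mapping the latent scale into
  skewed pChEMBL-like units (median near 8). The structural signal is a
  weighted count of seven substructure patterns (amide, hydroxyl, aryl
  halide, sulfonamide, trifluoromethyl, aromatic nitrogen, methoxy) with
  weights fixed so the signal standard deviation is near 0.9 — roughly the
  2:1 structure-to-assay-noise ratio typical of curated public affinity
  data. The measurement mix is IC50-dominated
  (IC50/Ki/Kd/EC50 = 0.72/0.20/0.05/0.03) with per-type offsets of
  0/0.25/-0.2/-0.35 on the latent scale;
* a **toxicity table** of 12 substructure-rule labels with 10% label flips
  and 10% missingness.

What passing tests on this benchmark do show: the pipeline recovers planted
structure-activity signal, undoes planted measurement heterogeneity, and
enforces its filter contracts exactly. What they do not show: performance
on real SAR landscapes — the grammar has no activity cliffs, no
matched-pair structure, and deliberately avoids reproducing any real
chemotype, so no test depends on a specific real molecule.

## Problem sizes and numerical choices

The shipped checks run at desk scale on one CPU: 10-fold cross-validation
at a library size of 1500 over 10 seeds for the signal-recovery and
model-ranking properties, a 5-iteration x 500-candidate design loop, 10^4
round-trip values for the normalization inverse, 1000 randomized tuples for
the filter oracle, and exponent recovery at n = 500 over 20 seeds. The
production-scale loop (batches of 10^4) uses the same code paths with a
larger `batch_size`.

Modeling fingerprints are folded to 256 bits (circular and path) — folding
trades a little bit-collision noise for kernel and tree tractability at
these problem sizes — while the similarity filter keeps its own 2048-bit
fingerprint. The SVR solver runs at a convergence tolerance of 0.01 with an
enlarged kernel cache; round-trip identity is verified at 1e-9; ensemble
arithmetic against brute force at 1e-12. Every stochastic step (fold assignment, member training,
generation, synthetic data) derives from an explicit integer seed, and
single-threaded backends make reruns bit-identical.

## Known limitations

* The default generator recombines exactly two fragments per candidate, so
  its products stay close to the training chemotypes by construction;
  learned generators plug in through the same contract.
* Fragment pool deduplication keys on the fragment's canonical SMILES plus
  the attachment atom's element and degree; attachment *positions* that are
  symmetry-distinct but share that key are merged, which only affects pool
  multiplicities.
* Censored activity records (">"/"<" qualifiers) and assay covariates are
  out of scope; records enter as point values.
* The toxicity default is a per-task classifier: it ignores label
  correlations across the 12 endpoints.
* Docking, ADMET profiling and any claim about real-compound toxicity or
  potency are outside the package.
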