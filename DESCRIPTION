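Package: denovoscreen
Title: De Novo Design and Screening of Nontoxic Kinase-Inhibitor Candidates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An iterative generate-filter-retrain pipeline for de novo design
    of nontoxic kinase-inhibitor candidates. Provides measurement-type
    stratified Box-Cox normalization of heterogeneous pChEMBL affinities, a
    four-member uniform-weight ensemble QSAR regressor with a prediction
    spread (internal consistency) estimate, a 12-task toxicity probability
    gate, a four-filter screening cascade (affinity, toxicity, Tanimoto
    novelty, ensemble consistency), a pluggable molecule generator with a
    fragment-recombination default, a seeded synthetic benchmark generator,
    and PAMPA blood-brain-barrier transmittance, permeability and CNS
    classification calculations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    xgboost,
    e1071,
    caret,
    nnet,
    ranger,
    kernlab,
    igraph,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
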