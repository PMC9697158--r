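Package: EnsembleFuse
Title: Optimised Multimodal Late-Fusion Ensemble Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects multimodal classifier ensembles for binary clinical
    prognosis by late fusion. Given binary predictions from unimodal models
    (patient-level clinical learners and slice-level imaging networks) across
    repeated patient-grouped train/validation/test splits, the package
    enumerates all odd-sized candidate ensembles containing at least one model
    per modality, scores each by fold-averaged majority-vote recall and
    pairwise kappa diversity, and returns the ensemble minimising the combined
    two-term objective, together with its Pareto front and the single-objective,
    averaged, a-posteriori and relaxed-constraint baseline ensembles. Also
    provides the accompanying clinical-table preprocessing (train-split
    imputation, one-hot encoding, min-max normalisation), slice-to-patient
    majority-vote aggregation, a repeated-split evaluation protocol with
    mean and standard-deviation reporting, and synthetic cohort and
    correlated-classifier generators for testing selection behaviour.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'registry.R'
    'predictions.R'
    'clinical.R'
    'metrics.R'
    'voting.R'
    'selector.R'
    'bootstrap.R'
    'synthetic.R'
    'cli.R'
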