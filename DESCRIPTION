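Package: enzEval
Title: Hierarchical Evaluation of Enzyme Commission Number Predictions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Model-agnostic evaluation toolkit for Enzyme Commission (EC)
    number prediction. Implements hierarchical multi-label accuracy metrics
    at EC levels 1-4 with batched variance and per-group reporting,
    per-class F1-optimal decision thresholds, majority-voting and stacking
    ensembles, scoring of EC-number completion by inter-model agreement,
    reaction-similarity scoring of partial and additional EC recommendations
    with a sibling-sampling fallback, leakage-aware dataset curation by
    sequence-identity clustering, and a deterministic synthetic fixture
    generator emulating hierarchical multi-label annotations, scored model
    predictions, protein sequences and toy reaction tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    glmnet,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'ec-label.R'
    'AllClasses.R'
    'AllGenerics.R'
    'annotation-table.R'
    'prediction-table.R'
    'fingerprints.R'
    'reaction-table.R'
    'io.R'
    'sunburst.R'
    'exact-eval.R'
    'thresholds.R'
    'ensemble.R'
    'completion.R'
    'recommend.R'
    'curation.R'
    'synth.R'
    'run-tasks.R'
    'utils.R'
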