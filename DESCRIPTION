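Package: paslink
Title: Pathway Activation Scoring and Drug-Sensitivity Correlation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes signed Pathway Activation Strength (PAS) scores from
    linear-scale expression matrices normalized jointly against multiple
    normal-tissue control datasets, estimates IC50 values from plate-level
    dose-response viability data by four-parameter-logistic fitting,
    screens pathways for Pearson correlation between PAS and IC50 across
    cell-line panels, and intersects significant pathways across
    independent datasets and normalization control sets. A synthetic-data
    generator with planted pathway perturbations and a planted PAS-IC50
    relationship provides ground truth for every stage of the pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    limma,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
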