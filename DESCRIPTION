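Package: transloc
Title: Protein Translocation Evidence Scoring from Ontology and Interactome Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts protein subcellular translocation from Gene Ontology
    annotations and protein-protein interaction network topology. Provides an
    OBO ontology reader with ancestor-closure annotation propagation, degree
    and bridgeness centrality on the interactome giant component, a packaged
    19-feature weighted-indicator model producing a Translocation Evidence
    Score (TES) with calibrated high/low/non-translocating classification,
    a decision-stump gradient-boosting trainer with importance-based feature
    selection and repeated stratified cross-validation, a Data Complexity
    Score for manually curated entries, seeded synthetic data generators for
    every input format, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    xgboost
Config/testthat/edition: 3
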