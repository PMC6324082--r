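# transloc

Protein translocation — the regulated movement of a protein between
subcellular compartments, with the change of interaction partners and
function that comes with it — is a central mechanism in signalling and
disease, but translocating proteins are scattered across the literature and
hard to find by keyword search. `transloc` implements a prediction pipeline
that scores human proteins for translocation likelihood from two kinds of
evidence:

* **functional annotation** — the protein's Gene Ontology terms, propagated
  to all `is_a`/`part_of` ancestors, and
* **interactome topology** — the protein's degree and *bridgeness* (a
  centrality that is high for proteins connecting large network modules) in
  a protein–protein interaction network.

It is aimed at systems biologists who want to score their own protein sets,
re-train the model on new curation, or stress-test the approach on synthetic
data.

## The model

Every protein is reduced to a vector of binary indicators
`x = (x_1, …, x_n)` against a packaged table of `n = 19` features — 15 GO
terms, two degree cutoffs (`degree < 14.5`, `degree < 62.5`) and two
bridgeness cutoffs (`bridgeness < 2.5e-06`, `< 0.000292`) — each carrying a
signed importance weight `w_i` obtained as the summed leaf scores of a
boosted one-depth-tree (decision stump) classifier. The **Translocation
Evidence Score** is

```
TES_raw = Σ_i w_i x_i,          TES = (TES_raw − min) / (max − min)
```

min–max normalized over the scored cohort to [0, 1]. Calibrated boundaries
partition proteins into three classes: `TES > 0.6167` high-confidence
translocating (no negative-set protein scores above this), `0.4487 ≤ TES ≤
0.6167` low-confidence, and `TES < 0.4487` non-translocating (the lower
boundary maximizes F1 on the training cohort).

The package also reimplements the full model-construction protocol —
gradient-boosted stumps with logistic loss (numerically identical to
xgboost at depth 1), normalized-gain feature selection at the 0.02 cutoff,
repeated stratified 5-fold cross-validation with AUC/PR/MCC reporting, and
both threshold-calibration rules — plus a curation layer (schema validation,
positive/negative training-set assembly, Data Complexity Score) and seeded
synthetic generators for every input format.

## Worked example

A protein with 20 interactome neighbours, no bridgeness record, and GO
annotations *animal organ morphogenesis* (GO:0009887) and *cytoplasm*
(GO:0005737) activates three model indicators — the two GO terms and
`degree < 62.5`:

```r
library(transloc)
w <- tes_weights()            # the packaged 19-feature model
p <- protein_features("proteinA",
                      go_terms = c("GO:0009887", "GO:0005737"),
                      degree = 20)
x <- binarize_features(p, w)
names(x)[x == 1]
#> [1] "GO:0009887"        "GO:0005737"        "degree_below_62.5"
raw_tes(x, w)
#> [1] 3.531                # = 2.675 + 1.353 - 0.497
```

A cohort runs through `score_cohort()`; the highest raw score maps to TES 1,
the lowest to 0, and each protein gets a class label:

```r
feats <- list(
  protein_features("low", degree = 5),
  protein_features("mid", go_terms = c("GO:0005829", "GO:0005737",
                                       "GO:0048523"), degree = 20),
  protein_features("top", go_terms = c("GO:0009887", "GO:0006109",
                                       "GO:0005737"), degree = 100))
score_cohort(feats, w)
#>   protein_id raw_tes       tes             class
#> 1        low  -1.037 0.0000000 non_translocating
#> 2        mid   2.546 0.5432904    low_confidence
#> 3        top   5.558 1.0000000   high_confidence
```

Real inputs enter the same way: `read_obo()` + `read_annotations()` +
`annotate_proteins()` build the ancestor-closed GO sets, `read_edge_list()`
+ `topology_table()` the degree/bridgeness columns, and `feature_frame()`
merges the two for `score_cohort()`.

The same pipeline is scriptable from a shell via the bundled CLI
(`inst/exec/transloc`): `simulate`, `featurize`, `score`, `classify`,
`train`, `cv`, `thresholds`, `dcs`, `validate`.

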