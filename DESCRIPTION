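Package: epireact
Title: Peptide Reactivity Prediction and De Novo Epitope Peptide Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Knowledge-based prediction of linear B-cell epitope reactivity
    to pooled human antibodies (IVIg). Computes sequence-derived peptide
    features (length, isoelectric point, residue occurrences, sliding-window
    propensity-scale profiles) and dataset-derived features from all-vs-all
    Needleman-Wunsch and Smith-Waterman alignment scores; fits logistic
    regression classifiers with collinearity/M5 or LASSO feature selection;
    evaluates them with leakage-aware leave-one-out cross-validation; and
    generates de novo peptides by complete-linkage clustering of local
    alignment distances, cluster multiple alignment, information-ordered
    motif extraction under k-mer novelty constraints, and model-based
    ranking into high/low/medium reactivity candidate lists. A synthetic
    peptide-set generator with planted motif families supports end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    glmnet,
    stats,
    utils
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
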