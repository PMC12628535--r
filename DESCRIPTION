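Package: methclr
Title: Multi-View Contrastive Learning for RNA Methylation Site Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts RNA methylation sites (m6A, m7G, Nm and related marks)
    from fixed-length 41-nt sequence windows using a dual-view deep network:
    a k-mer token embedding view processed by a CNN-BiLSTM-attention branch
    and a chaos-game-representation (CGR) scalar-state view processed by a
    BiLSTM branch. The fused representation is trained jointly with a
    supervised cross-entropy head and a SimCLR-style NT-Xent contrastive
    objective under adaptive multi-task weighting, designed for
    sample-limited datasets. Includes synthetic planted-motif dataset
    generation, full evaluation metrics (MCC, AUROC, AUPRC), cross-type
    transfer matrices, and gradient/perturbation interpretability profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    pROC
Config/testthat/edition: 3
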