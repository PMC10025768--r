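Package: scOpenAnno
Title: Source-Free Open-Set Cell-Type Annotation for Single-Cell Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Annotates cells in an unlabeled single-cell RNA-seq (or binarized
    scATAC-seq gene-activity) dataset using only a classifier model pre-trained
    on labeled reference data, never the reference data itself. The model is a
    zero-inflated negative binomial (ZINB) denoising autoencoder with a softmax
    classifier and two frozen auxiliary classifiers. Novel (reference-absent)
    cell types are detected automatically by testing the per-cell ensemble
    certainty score (E-score) distribution for bimodality (bimodality
    coefficient and Hartigan's dip test) and, when present, separated by an
    adaptive manifold-mixup threshold. The encoder is then fine-tuned on the
    target data alone with a multi-order neighborhood affinity loss over
    memory banks of embeddings and soft labels. Includes a clustered-ZINB
    simulator for closed/partial/open/open-partial label-space settings, an
    evaluation module (total accuracy, H-score), and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    e1071,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
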