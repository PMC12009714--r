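Package: stweave
Title: Pairwise Graph Autoencoder for Spatial Transcriptomics Embedding and
    Spatial Imputation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns paired latent encodings of spatially resolved
    transcriptomics (SRT) data: an attribute encoding of expression profiles,
    a topology encoding of the spatial neighborhood graph, and their
    concatenation. The two autoencoders are coupled by cross-reconstruction
    and by adversarial matching of both latent distributions to a standard
    Gaussian prior. Missing or masked locations are completed by feature
    propagation (harmonic graph diffusion) before topology encoding, and the
    trained model supports consistency-aware spatial imputation: padding
    spots are generated between measured lattice spots, then domain labels
    are propagated and gene expression predicted at unobserved locations via
    gradient-boosted regression on the latent encodings. Includes a seeded
    synthetic SRT data generator with planted spatial domains, clustering and
    evaluation metrics, and a masking-robustness benchmark.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    mclust,
    igraph,
    xgboost,
    jsonlite,
    yaml,
    cluster
Suggests:
    testthat (>= 3.0.0),
    withr,
    SingleCellExperiment,
    SummarizedExperiment,
    S4Vectors
Config/testthat/edition: 3
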