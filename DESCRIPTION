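Package: baoannotator
Title: Machine-Learning-Assisted Semantic Annotation of Bioassay Protocol Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hybrid machine-learning and user-confirmation engine for
    annotating free-text bioassay protocol descriptions with BioAssay
    Ontology (BAO) property:value terms. Assay text is converted into
    part-of-speech chunk blocks, which feed per-annotation
    Laplacian-modified naive Bayes scorers. Per-model linear calibrations
    are optimized for cross-model ranking separation, and second-order
    annotation-correlation models rescore candidates as a curator approves
    annotations. Includes an approve/reject/filter/search session engine,
    a simulated-operator evaluation protocol with a frequency-ranking
    null baseline, leave-one-out ROC evaluation, a synthetic corpus
    generator with planted annotation co-occurrence, RDF Turtle export
    and conjunctive triple-pattern queries, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite
Config/testthat/edition: 3
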