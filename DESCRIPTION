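Package: xtalcurate
Title: Curation and Local Adaptation of Crystallisation Outcome Image Datasets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for curating four-class protein-crystallisation outcome
    image datasets and adapting classifiers to a local laboratory. Measures
    and removes semantic redundancy by agglomerative clustering in an
    embedding space, merges multi-annotator labels into consensus labels,
    selects local images for training-set augmentation by class distribution
    or prediction hardness, and diagnoses domain shift through
    decision-boundary distance distributions. Includes a deterministic
    synthetic droplet-image generator so every stage runs without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    jsonlite,
    graphics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jpeg,
    uwot,
    mclust,
    EBImage
Config/testthat/edition: 3
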