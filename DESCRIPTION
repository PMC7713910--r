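Package: pitfallID
Title: Machine-Learning Identification of Pitfall-Trap Specimens from
    Batch Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A pipeline for identifying batch-imaged pitfall-trap
    specimens (developed for ground beetles, Carabidae) from
    morphometric feature vectors rather than raw pixels. Extracts
    ImageJ-style size, shape, and colour descriptors (68 variables per
    specimen across dorsal and ventral views) from photographs of
    multiple specimens on a light background; trains and tunes five
    classifier families (k-nearest neighbours, linear discriminant
    analysis, naive Bayes, random forests, single-hidden-layer neural
    networks); and evaluates them with a hierarchical classifier that
    lifts species-level predictions through the taxonomy, single-level
    classifiers trained per rank, local species-pool reranking, and a
    novel-species protocol for taxa absent from training. A synthetic
    data generator produces taxonomies, hierarchically structured
    feature tables, site pools, and rendered batch images with analytic
    ground truth so the full pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    MASS,
    e1071,
    randomForest,
    nnet,
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    tiff
Config/testthat/edition: 3
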