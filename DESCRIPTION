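Package: intaxa
Title: Integrative Taxonomy Inference from Morphometric, Karyological,
    Seed and Niche Evidence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for integrative species and subspecies delimitation
    from multiple independent evidence streams. Implements mixed-variable
    morphometric ordination (Gower dissimilarity with Podani's ordinal
    correction, Cailliez correction, principal coordinate analysis,
    sampling-adequacy diagnostics), grouping-hypothesis competition
    (ANOSIM, jackknifed and stepwise linear discriminant analysis,
    Cohen's kappa), an adaptive per-character univariate test cascade
    with Holm correction, karyotype asymmetry indices (THL, MCA, CVCL,
    CVCI), elliptic Fourier descriptors of seed outlines with
    morpho-colorimetric features, and PCA-based environmental niche
    overlap with Schoener's D and background similarity tests. Synthetic
    data generators emulate each evidence stream so the whole pipeline is
    testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    car,
    EBImage,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    vegan,
    ape,
    jsonlite,
    withr
Config/testthat/edition: 3
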