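Package: fdsweep
Title: Sensitivity of Functional Diversity Metrics to Trait Number and Correlation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how the number of traits and the correlation
    among traits affect functional diversity metrics in plant communities.
    Implements eight metrics from first principles (convex-hull functional
    richness, minimum-spanning-tree functional evenness, functional dispersion,
    functional divergence, Rao's quadratic entropy, and Gaussian kernel-density
    hypervolume richness, evenness and dispersion), Gower and Euclidean species
    dissimilarities with principal coordinates analysis, an exhaustive
    trait-subset sweep engine, mixed-model inference with polynomial AIC
    selection and Benjamini-Hochberg adjustment, and a synthetic-data generator
    emulating grassland community and trait tables.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    MASS,
    lme4,
    lmerTest,
    data.table,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster,
    vegan,
    Matrix,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
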