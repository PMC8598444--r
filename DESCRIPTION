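Package: hta
Title: Spatial Heterogeneity of Trait Combinations via the HTA Index
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies spatial heterogeneity of multivariate trait
    combinations (for example sets of genes called present at each spot of
    a spatial transcriptomics assay) with the HeTerogeneity Average index
    (HTA), a grid-based statistic built from base-C Shannon entropy of
    trait-combination proportions within axis-aligned regions.  Provides
    median-threshold trait calling, combination encoding, nearest-neighbour
    map resizing, a permutation null model over trait combinations with
    Lyapunov central-limit-theorem p-values, exact null moments by
    exhaustive enumeration for small regions, synthetic map generators,
    region reports, rendering of heterogeneity maps, and a command-line
    interface.  Supports 2D and 3D position lattices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
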