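Package: spinestereo
Title: Comparing 2D Stereological and 3D Volumetric Measurements of Dendritic Spines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative machinery for comparing dendritic-spine measurements
    made on single 2D transmission electron microscopy (TEM) sections with
    measurements made on 3D reconstructed volumes. Implements the
    size-frequency stereological density estimator with unbiased
    counting-frame exclusion, direct 3D counting with excluding planes, the
    sphere/disc algebra that converts spine-head areas, volumes, PSD lengths
    and synaptic apposition lengths between 2D and 3D representations, and
    the comparison protocol (summary tables, fixed-bin frequency curves,
    Spearman rank correlations, rank-sum and ANOVA tests). A synthetic
    neuropil generator and a virtual sectioning engine provide populations
    with known ground truth so that every estimator can be validated without
    microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
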