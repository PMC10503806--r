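Package: dielmetrics
Title: Diurnal Rhythm Detection and Host-Microbe Metabolic Time-Series Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing diurnal (24-hour light/dark) structure in
    host transcriptome, gut microbiome and indirect-calorimetry data from
    factorial mouse studies. Implements an empirical JTK-style nonparametric
    rhythm scan with a gamma-fitted permutation null, cosinor (harmonic
    regression) rhythm tests, factorial oscillator-driver partitioning,
    compositional log-ratio differentials for 16S feature tables,
    replicate-resampled permutation-averaged Spearman coexpression networks,
    and indirect-calorimetry summaries (Weir energy expenditure, robust Sn
    outlier masking, PRCF-logistic EC50, basal metabolic rate, ANCOVA).
    A synthetic-data module generates all input types with planted ground
    truth so every stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    vegan,
    igraph,
    minpack.lm,
    mvtnorm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    biomformat,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
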