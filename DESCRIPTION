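Package: chipnorm
Title: Data-Adaptive Normalization of ChIP-seq Samples Against Controls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates the ChIP/control normalization factor and the
    background read proportion of a ChIP-seq sample by a data-adaptive
    search over genome bin widths and total-count thresholds, alongside
    four classical comparator estimators (low-count background bins,
    Poisson-tail bin exclusion, iterative strand-split background fitting,
    and bin-count regression). Includes a synthetic paired-sample
    generator with known ground truth (point-source and diffuse
    enrichment, shared non-uniform background, control-side artifacts),
    a two-stage binomial peak caller, and sample-swap empirical FDR
    evaluation utilities for benchmarking normalization methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
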