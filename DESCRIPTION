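Package: BidirCore
Title: Bidirectionally Interacting Network Cores from Directed
    Functional Connectivity
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates weighted directed functional networks from
    multi-trial region-of-interest time series using normalized directed
    transfer entropy (NDTE) under a bivariate vector-autoregressive model,
    with block-permutation surrogate significance testing and density
    thresholding. From any weighted directed network it exactly extracts
    hierarchically nested "complexes" -- subnetworks that cannot be split
    by a weak bidirectional cut -- together with per-node coreness, and
    provides comparison metrics (bidirectionality-ignored complexes,
    weighted degree, s-core decomposition, functional rich-club scores)
    and the accompanying statistics (Pearson correlation with BCa
    bootstrap intervals, regression confidence bands, one-way ANOVA with
    effect size). A synthetic-data module generates toy networks and VAR
    time series with planted bidirectional cores.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    boot
Config/testthat/edition: 3
RoxygenNote: 7.3.3
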