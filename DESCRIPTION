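Package: CoexNets
Title: Gene Association Measures and Transcription-Factor Coordination
    Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes eight measures of pairwise gene association
    (Pearson, Spearman, Kendall tau-b, weighted rank correlation,
    Hoeffding's D, distance covariance, Theil-Sen and rank Theil-Sen
    slopes) with independence tests, ranks genome-wide coexpression
    partners, builds transcription-factor coordination networks from
    top-list overlaps, decomposes them into clusters with the greedy
    Triple-Link algorithm, and evaluates results against pathway
    membership, positive-gene sets and marginal normality.  A synthetic
    expression-data generator with planted pathway blocks and
    coordinated TF groups makes every stage testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
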