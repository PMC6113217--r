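Package: netprio
Title: Network-Based Disease-Gene Prioritization with Negative Resampling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Prioritizes candidate disease genes on a protein-protein
    interaction network. Computes topology features (degree, K-core,
    betweenness, first- and second-neighborhood seed-gene ratios) and a
    summed GO biological-process log-odds enrichment score per gene,
    screens features with two-sample Kolmogorov-Smirnov tests, trains a
    linear-kernel support vector machine under a balanced
    negative-resampling protocol with Platt-calibrated posterior
    probabilities, and ranks unlabeled genes by posterior probability.
    Includes a seedable synthetic-data generator emulating the statistical
    structure the analysis assumes, so the whole pipeline runs without
    external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
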