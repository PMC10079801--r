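Package: oamkit
Title: Outlying Aspect Mining for Anomaly Detection and Explanation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects anomalies in numeric tabular data (for example clinical
    records) with four detectors -- the local outlier factor, isolation
    forest, the Sp nearest-neighbour sub-sample score and the iNNE
    hypersphere-ensemble score -- and then explains each detected anomaly by
    searching feature subspaces with a staged beam search under four
    outlying-aspect scoring measures (kernel-density rank, density Z-score,
    smoothed-grid density Z-score and SiNNE). Discovered subspaces are
    ranked by a chi-square-kernel quality value computed on min-max
    normalised data. Includes a synthetic-data generator with planted
    outlying subspaces, ranking metrics (AUC, precision at n), CSV/ARFF
    input and a small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    foreign,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
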