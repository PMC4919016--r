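Package: pcqm
Title: Point-Centred Quarter Method Density Estimation and Monte Carlo
    Evaluation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Plotless plant-density estimation with the point-centred
    quarter method (PCQM) of orders 1-3, in both the widely published
    estimator form and the Pollard-consistent corrected form. Includes
    simulators for random, aggregated and regular spatial point patterns,
    the Clark-Evans aggregation index, a virtual quadrant sampler with
    edge buffering, and a Monte Carlo evaluation framework computing
    relative root mean square error and relative bias with rank-based
    estimator comparisons (Wilcoxon, Kruskal-Wallis with Dunn post-hoc).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
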