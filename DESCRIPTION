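Package: cpmpaths
Title: Predicting Paths of Tumor Progression with Cancer Progression Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation pipeline for assessing whether cancer progression
    models (CPMs) can predict the distribution of paths of tumor progression
    and evolutionary unpredictability. Generates random fitness landscapes
    (DAG-representable, multi-peaked, and Rough Mount Fuji), simulates clonal
    tumor evolution to fixation recording lines of descent (LODs), samples
    cross-sectional data under tumor-size detection regimes, fits conjunctive
    Bayesian network (CBN) and oncogenetic tree (OT) models, converts fits
    into probability-weighted path distributions, and scores predictions with
    Jensen-Shannon divergence on path distributions (including an
    unequal-path-length matching procedure), recall/precision on path mass,
    path diversities, and bootstrap reliability.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
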