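Package: dialectscope
Title: Cryptic Song Dialects, Proximity Networks and Assortative Mating
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for studying whether
    machine-detectable population signatures ("cryptic dialects") in learned
    birdsong predict assortative mating. Generates synthetic zebra finch
    colonies with cultural transmission of song, renders songs as waveforms,
    classifies dialects with a windowed spectral-feature classifier, scores
    motif similarity by dynamic time warping, infers proximity networks from
    automated tracking fixes, computes categorical assortativity with
    permutation inference, calls pair bonds against a zero-truncated Poisson
    background, and compares observed mating matrices against competing
    imprinting hypotheses, including a crossed-random-effects model of dyadic
    distances.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    glmnet,
    igraph,
    jsonlite,
    lme4,
    Rcpp,
    stats,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
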