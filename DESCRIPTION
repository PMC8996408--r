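Package: walnutmedia
Title: Machine-Learning Models and Swarm Optimization for Walnut In Vitro
    Proliferation Media
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reusable pipeline for predicting and optimizing Persian walnut
    (Juglans regia) in vitro proliferation media. Packages a 9-factor,
    3-level Taguchi screening design with per-treatment response summaries
    (proliferation rate, callus weight, shoot tip necrosis, vitrification)
    for the cultivars Chandler and Rayen; expands the summaries into
    moment-matched replicate-level datasets; fits and cross-validates
    multiple linear regression, k-nearest-neighbour, single-hidden-layer
    perceptron and gene expression programming (GEP) response-surface
    models; and searches the factor space with multi-objective particle
    swarm optimization to propose an optimal medium per genotype, including
    a registry of transcribed GEP equations usable as exact prediction
    surfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
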