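Package: vascufab
Title: Simulation of Self-Organizing Vascular Cell Factories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Agent-based simulation of a bioengineered cell factory supported
    by a self-organizing vascular network. Phase I self-organizes chemotactic,
    adhesive vascular cells seeded among producer cells into a vessel network
    connecting two circulatory columns; Phase II extracts a pipe network from
    the cell morphology (rasterization, local width, medial-axis
    skeletonization, graph extraction) and solves Poiseuille/Kirchhoff flow;
    Phase III runs the operating factory (vessel-wall nutrient delivery,
    Michaelis-Menten product synthesis with product inhibition, vessel-wall
    product removal) to steady state and reports throughput. Includes the
    evaluation experiments: vascular-fraction sweep, robustness over seeds,
    and domain-width scaling.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
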