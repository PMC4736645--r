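Package: goodwave
Title: Spatial Evolution of Public-Good Production on a Lattice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-based Monte-Carlo simulator of a population evolving a
    continuous public-good production trait on a square lattice with Moore
    (k = 8) connectivity. Individuals replicate into empty neighbouring nodes
    with a fitness-weighted lottery, pay a per-unit cost for the good they
    produce, and share its benefit with their neighbourhood. The package
    provides the core asynchronous update engine (accelerated in C++),
    well-mixed and mixing controls, weak and strong altruism variants,
    evolutionary cost sweeps, strip-geometry invasion-rate assays and pairwise
    front/back competition assays, together with trajectory summaries,
    bimodality detection, snapshot persistence, lattice rendering and a small
    command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
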