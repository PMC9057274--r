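Package: netswitch
Title: Bond-Switching Monte Carlo Generation of Two-Dimensional Biological Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates two-dimensional planar networks with a variable node-degree
    distribution (conserved mean degree) by an extended Wooten-Winer-Weaire
    bond-switching Monte Carlo method driven by a simplified Keating-type
    harmonic potential. Provides explicit ring (face) bookkeeping on periodic or
    finite embedded planar graphs, thermalisation, logarithmic simulated
    annealing and fixed-temperature protocols, a structural metric suite
    (degree moments, ring statistics, ring-adjacency assortativity), a
    raster render/skeleton-extraction round trip emulating micrograph analysis,
    and a parameter-sweep driver mapping generated networks into the
    {mu2(k), r} network landscape.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    igraph,
    yaml,
    png,
    tiff,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
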