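Package: irregnet
Title: Degree-Based Irregularity Indices for Chemical Graphs and
    Polyhedral Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes twelve degree-based irregularity indices (Albertson,
    IRDIF, IRL, IRLU, IRLF, IRF, IRLA, IRD1, IRA, IRGA, IRB and the
    per-edge total irregularity) for arbitrary undirected simple graphs,
    either from a concrete graph or from a degree-pair edge partition.
    Provides generators for the octahedron and icosahedron graphs and for
    corner-sharing chains of them, parametric edge-partition families for
    the two-dimensional octahedral and icosahedral sheet networks, symbolic
    quadratic closed forms of every index on those families, reproduction
    of the published index tables with a machine-readable discrepancy
    report, and family-vs-family dominance comparisons.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    utils,
    stats,
    graphics,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
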