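Package: polyskel
Title: Exact Skeleton Graphs of Polytopes from Degenerate Half-Space Descriptions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Converts a system of linear inequalities A x <= b (an
    H-representation, read from cdd-style .ine files or built
    programmatically) into the skeleton graph of its feasible polytope:
    the set of extreme points and the edges (1-faces) joining them.
    Degeneracy at a vertex, where more than n constraints meet, is
    resolved by incremental double-description slicing of the vertex
    cone, with a 2-face record and a rejection pre-test that cut down
    the number of colaminarity tests; neighbouring vertices are then
    reached by a min-ratio pivot along each extreme ray, and a
    breadth-first traversal assembles the complete graph.  All geometry
    is carried out in exact rational arithmetic (GNU GMP), so active
    sets, ranks and degeneracies are decided without tolerances.
    Includes generators for benchmark families (a no-signaling
    correlation polytope, Birkhoff polytopes, random regular polytopes,
    hypercubes, simplices and cross-polytopes), size and connectivity
    metrics of the conversion, graph export, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
SystemRequirements: GNU GMP library with C++ bindings (libgmp, libgmpxx)
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
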