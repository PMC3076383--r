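Package: skeinpath
Title: Knot Detection and HOMFLY Polynomials for Polygonal Paths and Protein Backbones
Version: 0.1.0
Authors@R:
    person("skeinpath", "developers", email = "skeinpath@example.org",
           role = c("aut", "cre"))
Description: Topological analysis of open and closed polygonal curves in
    three dimensions. Reduces polygonal links with generalized Reidemeister
    moves (minimal structure reduction), computes the two-variable HOMFLY
    polynomial by explicit geometric construction of Conway skein triples,
    specializes to the Jones and Alexander polynomials, and identifies knot
    type and handedness. Includes a protein backbone front end (C-alpha
    trace extraction, gap splitting, chain closure, knotted-core trimming),
    a deterministic fixture generator for parametric knots and links, and
    an independent diagrammatic skein oracle for cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
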