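Package: petrinv
Title: Minimal Petri Net Invariants, Siphons and Traps by Finite-Domain
    Constraint Solving
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Structural analysis of biochemical reaction networks viewed as
    Petri nets. Reads plain-text reaction systems and SBML documents, and
    computes minimal semi-positive P- and T-invariants (conservation laws
    and flux cycles), their inequality relaxations (species pools that can
    only grow or only shrink), and minimal siphons and traps. The
    computation is a finite-domain constraint satisfaction problem solved
    by bounds-consistency propagation and low-to-high depth-first
    labelling, with syntactic detection and merging of interchangeable
    ("parallel") places so that exponentially many symmetric solutions can
    be counted without being enumerated.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
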