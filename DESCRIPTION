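Package: tailmoves
Title: Rearrangement Moves and Tier Connectivity for Binary Phylogenetic Networks
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for exploring the tiers of rooted and unrooted binary
    phylogenetic network space with rearrangement moves. Implements tail and
    head moves (and the derived rSPR and rNNI classes) on rooted binary
    networks, SPR moves on unrooted networks, validity checking, move
    enumeration and distance classification, simulation of distance-1 head
    moves by short tail-move sequences, constructive bounded-length move
    sequences connecting any two networks with the same reticulation number,
    decomposition of tail moves into distance-1 tail moves, rootability
    testing and bipolar orientation of unrooted networks, exhaustive tier
    enumeration and exact move-distance oracles at toy scale, and
    agreement-forest machinery for trees and mycorrhizal forests. Networks
    are read and written in extended Newick and plain edge-list formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
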