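Package: sheetfolds
Title: Enumeration and Frustration Classification of Open Beta-Sheet Topologies
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for exploring the fold space of alpha-beta proteins built on
    a single open beta-sheet. Exhaustively enumerates strand order and
    orientation patterns of three- to eight-stranded open sheets up to the
    rigid-body symmetries of the sheet, classifies every topology as
    frustration-free or frustrated under three beta-X-beta connection rules
    (jump distance, connection overlap, connection ending, with the Greek-key
    exemption), scores topologies by observation frequency over an ECOD-style
    Family/Homology domain hierarchy to nominate unobserved (novel) folds,
    extracts sheet topologies from protein coordinates, and compiles
    topologies into secondary-structure/ABEGO design blueprints and idealized
    mock coordinates.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
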