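Package: idrbuilder
Title: Conformer Ensembles for Missing Disordered Regions of Protein Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Generates backbone conformer ensembles for intrinsically
    disordered regions (IDRs) that are missing from experimental protein
    structures or carry low confidence in predicted models. Missing
    N-terminal tails, internal linkers and C-terminal tails are detected by
    comparing the template against the full-length sequence (or by trimming
    low-pLDDT residues), rebuilt by knowledge-based torsion sampling from a
    curated fragment library, attached to the template by Kabsch
    superposition, screened with a van der Waals clash check against the
    template and any environment atoms (e.g. a lipid bilayer), and, for
    internal gaps, closed geometrically by matching fragment pairs grown
    from both anchors and remodelling the junction carbonyl oxygen and
    amide hydrogen.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    jsonlite,
    bio3d,
    Biostrings,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
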