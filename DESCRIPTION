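Package: superdock
Title: Superhelical Matching and Geometric Hashing for Modular
    Peptide-Binder Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Design engine for modular peptide-binding repeat proteins.
    Repeat proteins and repeat peptides both trace superhelices; a necessary
    condition for in-register, one-repeat-to-one-repeat binding is that
    their superhelical parameters (rise, twist, radius) match. The package
    builds peptide and repeat-protein backbones from torsions, extracts
    superhelical parameters by screw-axis decomposition, precomputes binned
    hash tables of bidentate hydrogen-bond geometries (side-chain amide,
    carboxylate, serine/threonine classes, plus pi-stacking geometries),
    docks peptides onto proteins by a two-degree-of-freedom grid search
    with hash lookup, installs and refines the matched side chains, and
    provides the downstream selection machinery: interface metrics
    (shape complementarity, unsatisfied hydrogen bonds), threshold-based
    design selection, peptide/protein mutation scans, forward-docking
    convergence assessment, tandem-triplet proteome scanning, and
    site-saturation-mutagenesis enrichment analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
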