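Package: metharmonize
Title: Hierarchical Harmonization of Compounds and Atom-Resolved
    Metabolic Reactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for harmonizing metabolite structures and atom-resolved
    metabolic reactions across metabolic pathway databases.  Molecular
    structures are read from MDL molfile (V2000) and KEGG KCF connection
    tables, assigned neighborhood-specific atom colors and compound coloring
    identifiers, and compared with a chemically aware subgraph isomorphism
    search that understands R-group (generic) compounds.  Compound pairs are
    classified into equivalence, generic-specific and loose relationships;
    validators handle tautomers and ring-chain (linear versus cyclic sugar)
    representations.  Reactions are paired through Enzyme Commission numbers
    and the compound pair list in an iterative discovery loop, atom mappings
    are derived from KEGG RCLASS RDM descriptions, and mapping consistency is
    scored with a changed one-bond atom color fraction that corrects for
    resonance-equivalent atoms.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
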