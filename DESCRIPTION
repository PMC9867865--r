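Package: molenum
Title: Exhaustive Enumeration of Constitutional Isomers and Stereoisomers
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Exhaustive, duplicate-free generation of the constitutional
    isomers of a molecular formula by orderly enumeration of canonical
    adjacency matrices under fixed atom valences, followed by enumeration of
    all unique stereoisomers (tetrahedral and cis/trans) using the
    automorphism group of the adjacency matrix. Molecules are reported as
    stereo-annotated canonical SMILES strings and can be written to XML.
    Supports a flexible molecular-formula mini-language with count lists and
    ranges, implicit-hydrogen atom specifications, property restrictions
    (unsaturations, bond-order counts, cycles) and Ullmann substructure
    filters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, Rcpp, xml2
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse, jsonlite
Config/testthat/edition: 3
biocViews: Cheminformatics, GraphAndNetwork
RoxygenNote: 7.3.3
Collate: 
    'molenum-package.R'
    'AllClasses.R'
    'RcppExports.R'
    'graph.R'
    'filters.R'
    'smiles.R'
    'stereo.R'
    'formula.R'
    'enumerate.R'
    'xml.R'
    'cli.R'
    'oracle.R'
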