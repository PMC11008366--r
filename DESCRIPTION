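Package: hbscreen
Title: Screening of Complementary Hydrogen-Bonding End-Group Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for computational screening of planar aromatic end groups
    (DNA nucleobase analogues) that pair through ordered rows of hydrogen-bond
    donor and acceptor sites. Provides a shorthand codec for donor/acceptor
    site patterns, exhaustive shift-and-flip enumeration of binding registers,
    rigid construction of starting dimer geometries, a surrogate hydrogen-bond
    scoring model with secondary electrostatic cross-terms and a
    planarity-gated amine term, ingestion of quantum-chemistry energy tables
    (including counterpoise-corrected binding energies), binding-matrix and
    selectivity-contrast statistics, amine pyramidalization analysis, and
    mining of 2-letter and 4-letter molecular alphabets over sliding
    binding-energy windows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
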