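Package: ndscreen
Title: Cross-Species Integration of Neurodegeneration Modifier Screens
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrates hit lists from genetic modifier screens of
    neurodegenerative disease models in Caenorhabditis elegans,
    Saccharomyces cerevisiae and Drosophila melanogaster. Screen hits in
    native identifiers are normalized, projected onto the C. elegans gene
    space through packaged orthology maps (OrthoMCL-style groups or
    pairwise tables), deduplicated into a regulator catalog, and scanned
    for regulators recurring across independent studies. Recurrent
    regulators can be annotated with functional classes, human orthologues
    and neuronal-expression flags, connected into a protein-interaction
    subnetwork, and tested against a permutation null model for overlap
    significance. A synthetic-data generator emits fully ground-truthed
    input bundles so every pipeline stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table (>= 1.14),
    igraph,
    jsonlite,
    stats
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
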