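Package: cmsscan
Title: Comparative Organelle Genomics for Cytoplasmic Male Sterility Candidate Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterise the organelle-genome composition of alloplasmic
    cytoplasmic male sterility (CMS) lines and to rank candidate CMS genes. The
    package calls open reading frames on circular mitochondrial genomes, detects
    ORFs specific to a CMS line relative to its maintainer, predicts transmembrane
    segments with a Kyte-Doolittle hydropathy method, screens ORFs for chimeric
    fragments of core mitochondrial genes by local alignment, classifies coding
    substitutions (synonymous/non-synonymous, transition/transversion), inventories
    long direct and inverted repeats, computes collinearity blocks between genomes,
    and builds neighbor-joining trees for candidate-gene homolog sets. A synthetic
    three-genome (donor, recipient, cybrid) simulator with a complete truth table
    makes every pipeline stage testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    ape,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
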