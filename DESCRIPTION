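Package: barcodelim
Title: DNA Barcode Species Delimitation and Barcoding-Gap Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing COI DNA-barcode reference libraries:
    computational quality control (length filtering, mitochondrial
    stop-codon screening, haplotype collapsing), Kimura 2-parameter
    pairwise distances with pairwise deletion, neighbor-joining and UPGMA
    tree building with outgroup rooting and strict-clock time scaling,
    four families of single-locus species delimitation (threshold single
    linkage, automatic barcode-gap discovery, Poisson tree processes,
    generalized mixed Yule-coalescent), majority-rule consensus across
    delimitation partitions, and barcoding-gap summary statistics.
    Includes a coalescent simulator of multi-species barcode libraries
    with known ground truth for benchmarking every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
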