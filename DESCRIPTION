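Package: hgtident
Title: Detection of Horizontally Transferred Genes from Compositional Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies horizontally transferred (alien) genes in a single
    microbial genome by combining fifteen compositional-atypicality
    signatures -- Karlin's dinucleotide relative-abundance difference,
    Karlin's codon bias, positional GC deviation, chi-squared dinucleotide
    and codon biases, Jensen-Shannon divergences of nucleotide,
    dinucleotide and codon distributions, and k-mer frequency deviations
    for k = 1..7 -- in a radial-basis-function support vector machine.
    Includes genetic-algorithm wrapper feature-subset selection, SMOTE
    minority-class oversampling for the class-imbalance problem inherent
    to alien-gene detection, a single-signature multiple-threshold
    baseline detector, stratified cross-validation orchestration, and a
    synthetic-genome generator with planted transferred genes for
    end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    quadprog,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
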