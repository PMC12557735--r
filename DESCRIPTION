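Package: denovoscreen
Title: Selection Screens of Random Sequence Libraries for De Novo Gene Birth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and analysing selection screens of (semi-)random
    sequence libraries used as experimental models of de novo gene birth. Provides
    exact combinatorics of degenerate-codon library designs (codon expansion,
    amino-acid and stop-codon distributions, intact-ORF probabilities), a synthetic
    generator emulating library synthesis, multi-round phage selection with planted
    functional variants and paired-end amplicon sequencing, a read-processing
    pipeline (overlap merging, flank-anchored insert extraction, greedy
    identity clustering, frequency-threshold hit calling), open-reading-frame
    discovery with alternative start codons plus start-knockout and maximal
    synonymous-recoding designs, protein-pool characterisation (residue classes,
    Kyte-Doolittle hydrophobicity, effect sizes), and plaque/adsorption assay
    metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    png,
    tiff
Config/testthat/edition: 3
biocViews: Sequencing, Software, Clustering, MolecularEvolution
RoxygenNote: 7.3.3
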