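Package: cdr3phys
Title: Physicochemical Analysis of T Cell Receptor CDR3 Repertoires
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for single-cell T cell receptor (TCR) repertoire analysis
    centred on the physicochemical properties of the CDR3 loop. Reads 10x
    Genomics per-contig V(D)J annotation tables and AIRR Rearrangement files,
    defines amino-acid clonotypes, scores full and mid-hypervariable CDR3
    hydrophobicity on the Kyte-Doolittle and Wimley-White interface scales,
    quantifies clonal expansion and dominance, detects codon-redundancy
    (convergent-recombination) events in which distinct nucleotide
    rearrangements encode one amino-acid CDR3, tabulates clone sharing across
    phenotypic subsets and alpha-beta chain pairing, and performs the
    accompanying non-parametric group comparisons and ROC analysis. A seeded
    V(D)J repertoire simulator with planted clonal expansion,
    hydrophobicity-expansion coupling, length bimodality and synonymous
    convergence supports fully reproducible testing without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    seqinr,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
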