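Package: famscan
Title: Gene Family Identification, Evolution and Co-Expression Analysis for
    C2H2 Zinc-Finger Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable, fully tested pipeline for transcriptome-scale
    characterization of the C2H2 zinc-finger protein (C2H2-ZFP) gene family:
    pattern-based family identification (X2-C-X2/4-C-X12-H-X2/8-H), open
    reading frame detection, ProtParam-style physicochemical profiling,
    pan/core family-size analysis from alignment tables, Nei-Gojobori (1986)
    Ka/Ks estimation with Jukes-Cantor correction and duplication dating,
    named-motif and cis-regulatory element scanning, chi-square GO
    enrichment, Pearson co-expression network construction with a
    randomized-control network-formation tendency test and hub-gene
    detection, and 2^-ddCt quantification of qPCR stress-response assays.
    Every stage is exercisable on synthetic data with known ground truth
    produced by the bundled generators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
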