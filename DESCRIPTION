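Package: mapkcascades
Title: MAPKKK Family Classification, Molecular Evolution, Expression
    Screens, and MAPK Cascade Prediction
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for genome-wide analysis of the plant
    MAPK kinase kinase (MAPKKK) gene family, modelled on the Brachypodium
    distachyon family.  Classifies proteins into the MEKK, Raf and ZIK
    subfamilies from kinase-domain signature motifs and domain position;
    profiles exon/intron organisation and splice-site phases; classifies
    duplicate gene pairs (tandem vs chromosomal-segment), estimates Ka/Ks
    by the Nei-Gojobori (1986) counting method with Jukes-Cantor
    correction and dates duplications under a synonymous molecular clock;
    screens expression matrices with coefficient-of-variation, log2
    fold-change, SAM-style permutation and two-way ANOVA tests; detects
    diurnally cycling genes by cosine-template correlation; scans
    promoters for IUPAC cis-regulatory elements; and builds Mutual-Rank
    co-expression networks from which colocalised MAPKKK-MKK-MPK cascade
    triads are predicted.  A synthetic-data module generates sequence,
    structure, expression and promoter fixtures with known planted truth
    so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rcpp,
    ape,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
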