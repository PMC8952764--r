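Package: genrelate
Title: Comparative Genomic Relatedness and Insecticidal-Factor Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Fragment-based average nucleotide identity (ANIb), HSP-based
    digital DNA-DNA hybridization (dDDH) distances, and BLAST-score-ratio
    (BSR) gene-homology screening for fungal genome comparisons, built on a
    self-contained k-mer seeded local aligner with Karlin-Altschul bit
    scores. Includes taxonomic-relatedness degree encoding with linear
    regression and Pearson correlation analysis, one-way ANOVA with Fisher's
    LSD means separation and compact-letter display for dose-mortality
    bioassays, and a synthetic genome/gene-family/mortality simulator so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
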