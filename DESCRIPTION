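Package: editscreen
Title: Multi-Method Genotyping of CRISPR-Induced Mutations in Polyploids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies CRISPR/Cas9 editing outcomes in highly polyploid
    genomes (such as sugarcane) from four independent laboratory read-outs
    and compares them side by side. Implements conserved-sequence (CS)
    amplicon-read indel calling and Cas-Analyzer-style indicator-window
    calling from FASTQ, capillary-electrophoresis fragment-peak
    quantification, categorical scoring of in-vitro Cas9 ribonucleoprotein
    (RNP) cleavage assays from gel densitometry, and melt-curve /
    high-resolution melt (HRMA) difference-curve analysis. A seeded
    synthetic-data generator produces allele populations with planted indel
    spectra, amplicon reads, peak tables, gel lanes and melt curves with
    known ground truth, so every analysis stage can be validated against
    recoverable targets. Cross-method concordance reporting, chimerism
    detection over vegetative progenies, and a per-sample assay cost model
    are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
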