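Package: co2screen
Title: Fitness Analysis of Pooled CRISPRi Screens Under High-CO2 Cultivation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative toolkit for genome-wide CRISPR interference (CRISPRi)
    fitness screens of cyanobacteria grown under elevated CO2 with bicarbonate-
    buffered pH. Provides a carbonate-system dosing model (speciation at fixed pH,
    NaHCO3 dose prediction, equilibrium pH, titration simulation and pKa fitting),
    growth-curve utilities, readers and writers for pooled-screen count data, a
    count-normalization / log2 fold-change / area-under-curve fitness pipeline with
    correlation-weighted gene scores, Wilcoxon rank-sum and Benjamini-Hochberg hit
    statistics with impact and combined scores, bedGraph fitness track export, and
    a turbidostat selection simulator with ground truth for parameter-recovery
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    pracma
Config/testthat/edition: 3
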