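Package: p1bspipe
Title: Degenerate Promoter-Motif Screening, Comparative-CT qPCR and
    Nutrient-Transfer Statistics
Version: 1.0.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for genome-wide screening of degenerate (IUPAC)
    cis-regulatory elements such as the P1BS element GNATATNC in
    fixed-length upstream regulatory regions, including promoter
    extraction from genome FASTA plus GFF3 annotation; comparative-CT
    (delta-delta-CT) relative quantification of qPCR data normalized to
    a reference gene with amplification-efficiency quality control;
    radiotracer transfer percentages and anion-concentration group
    statistics (one-way ANOVA with Tukey HSD); synthetic-data
    generators with known ground truth for every stage; and a
    subcommand-style pipeline driver.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    data.table,
    GenomicRanges,
    jsonlite,
    methods,
    optparse,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
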