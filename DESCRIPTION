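Package: alkdeep
Title: Ultra-Deep Targeted Sequencing Analysis of ALK Kinase-Domain Hotspot Mutations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and quantification of low-frequency somatic point
    mutations in the ALK tyrosine-kinase domain (neuroblastoma hotspots
    F1174, F1245, R1275 and minor sites I1171, L1240) from ultra-deep
    amplicon or capture sequencing. Builds per-position allele counts over
    the ALK exon 21-25 target regions (hg19), estimates position- and
    allele-specific background error from control samples, classifies
    nucleotide frequencies exceeding five standard deviations of background
    as mutations, annotates substitutions to amino-acid changes on the
    minus strand, and classifies calls by clonality and Sanger
    detectability. Includes a synthetic read and pileup generator for
    spike-in and dilution-series validation, and cohort-level statistics
    (hotspot spectrum, genomic-subgroup associations, Kaplan-Meier
    survival).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    withr,
    jsonlite,
    Biostrings,
    survival
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
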