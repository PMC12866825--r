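Package: hydroxydyn
Title: Joint 5mC/5hmC Decomposition and Differential Hydroxymethylation
    Dynamics from Paired Bisulfite and APOBEC-Deamination Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing DNA 5-methylcytosine (5mC) and
    5-hydroxymethylcytosine (5hmC) dynamics from paired whole-genome
    bisulfite sequencing (WGBS, signal = 5mC + 5hmC) and APOBEC-coupled
    epigenetic sequencing (ACE-seq, signal = 5hmC) CpG count tables.
    Provides a closed-form constrained maximum-likelihood decomposition of
    per-CpG (unmodified, 5mC, 5hmC) levels with conflict filtering, a
    tile-and-sliding-window differential (hydroxy)methylation region
    caller with Benjamini-Hochberg control, cumulative-length Fisher
    enrichment of regions at genomic elements, enhancer-to-gene
    assignment, allele- and chromosome-resolved dynamics summaries
    (imprinting-control-region panels, X-versus-autosome comparisons,
    X/A expression ratios), a screen for genes reactivated by ectopic
    5hmC gain, and a seeded synthetic methylome generator that emulates
    stage-structured, allele-resolved embryo methylomes with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
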