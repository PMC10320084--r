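Package: motifguides
Title: Design of CRISPR sgRNAs Targeting Sequence Motifs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finds user-specified sequence motifs (plain, IUPAC, or derived
    from JASPAR/TRANSFAC count matrices) in target genomic regions and designs
    sgRNAs targeting them for Cas9 cutting or dCas9 blocking experiments.
    Supports NGG/NGA/NGCG PAMs, in-process mismatch-based off-target
    enumeration with CFD-style specificity scoring, genomic-context
    annotation against refGene-style gene models (coding exon, non-coding
    exon, intron, intergenic, closest TSS), result filtering and summary
    statistics, and Genome-Browser-ready BED track export. Includes a
    seed-deterministic synthetic fixture generator (toy genomes, planted
    motifs and off-targets, toy annotations) so the whole pipeline is
    testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    writexl
Config/testthat/edition: 3
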