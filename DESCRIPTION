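Package: methylpost
Title: Downstream Analysis of Whole-Genome Bisulfite Sequencing
    Methylation Calls
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-alignment toolkit for whole-genome bisulfite sequencing
    (WGBS): reads Bismark CX cytosine reports and BS-Seeker2 CGmap files,
    merges replicates, builds per-cytosine methylation tracks and
    context-resolved profiles (CpG/CHG/CHH summaries, 100-kb genome bins,
    promoter/gene/exon/intron/intergenic methylation, TSS metaprofiles),
    segments unmethylated and low-methylated regions (UMRs/LMRs), calls
    differentially methylated cytosines with an exact test and clusters
    them into regions under two rule sets, associates promoter hits with
    genes, and ships a synthetic methylome simulator so every stage is
    testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    withr,
    optparse
Config/testthat/edition: 3
biocViews: Epigenetics, DNAMethylation, MethylSeq, Sequencing, Coverage
RoxygenNote: 7.3.3
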