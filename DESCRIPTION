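Package: kmerDE
Title: Reference-Free Differential Expression from RNA-Seq k-mer Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects differentially expressed transcript variation directly
    from RNA-seq k-mer counts, without read mapping or transcript assembly.
    Libraries are decomposed into k-mers, counts are joined into a matrix,
    filtered for recurrence, masked against a reference transcriptome and
    tested for differential abundance (per k-mer t-test on log-normalized
    counts, or a negative-binomial GLM). Significant k-mers are extended
    into contigs through unique prefix-suffix overlaps, aligned to a
    reference genome, annotated against a GFF3 gene model and classified
    into biological event classes (splicing, polyadenylation, lincRNA,
    antisense RNA, SNV, intron retention, repeats, unmapped). Includes a
    synthetic-data generator producing a toy genome, annotation and
    two-condition read sets with spiked-in events of known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    stats,
    utils,
    methods,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    MASS,
    optparse
Config/testthat/edition: 3
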