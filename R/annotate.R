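#' Read a GFF3 gene annotation
#'
#' Imports a GFF3 file and extracts gene and exon features as `GRanges`
#' (1-based inclusive, as in the file; alignment coordinates are 0-based
#' half-open and converted where the two meet). Exons are linked to their
#' gene through the `Parent` transcript.
#'
#' @param gff3_path Path to a GFF3 file with gene/mRNA/exon features.
#' @return List with `genes` (GRanges, `gene_id` metadata) and `exons`
#'   (GRanges, `gene_id` and `transcript_id` metadata).
#' @export
read_annotation <- function(gff3_path) {
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  type <- gr$type
  genes <- gr[type == "gene"]
  genes$gene_id <- as.character(genes$ID)
  tx <- gr[type %in% c("mRNA", "transcript")]
  tx2gene <- stats::setNames(as.character(unlist(tx$Parent)),
                             as.character(tx$ID))
  exons <- gr[type == "exon"]
  if (length(exons)) {
    parent <- as.character(unlist(exons$Parent))
    exons$transcript_id <- parent
    exons$gene_id <- unname(tx2gene[parent])
  } else {
    exons$transcript_id <- character(0)
    exons$gene_id <- character(0)
  }
  list(genes = genes, exons = exons)
}

# GRanges of primary alignment spans (1-based) for mapped rows of an
# alignment table
.alignment_granges <- function(aln) {
  mapped <- which(aln$is_mapped)
  GenomicRanges::GRanges(
    seqnames = aln$chrom[mapped],
    ranges = IRanges::IRanges(start = aln$start[mapped] + 1L,
                              end = aln$end[mapped]),
    strand = aln$strand[mapped],
    contig_row = mapped)
}

#' Annotate aligned contigs against a gene model
#'
#' Derives, for each contig, the locus features consumed by the event
#' classifier: overlapped sense gene, antisense-only overlap, exonic /
#' intronic overlap (a contig spanning a boundary can be both), the SNV
#' flag (at least one mismatch or indel with a unique hit), the
#' trailing-poly(A) flag (3' clip of at least 5 bases whose last 5 are A),
#' the mapped-region size, and placeholders for the differential-usage
#' p-value and host-gene DE status filled in by the event stage. Unmapped
#' contigs get all locus features false/none.
#'
#' In unstranded mode strand is unknown: gene overlap on either strand sets
#' `gene_id` and `is_antisense` is never set (antisense calls require
#' stranded libraries).
#'
#' @param aln Alignment table from [align_builtin()] or
#'   [read_sam_alignments()].
#' @param annotation List from [read_annotation()] (or a GFF3 path).
#' @param stranded Logical; is the library stranded?
#' @return `data.table`: the alignment columns plus `gene_id`,
#'   `is_antisense`, `is_exonic`, `is_intronic`, `snv`, `ends_polyA`,
#'   `contig_length`, `mapped_region`, `du_pvalue`, `gene_is_de`.
#' @export
annotate_contigs <- function(aln, annotation, stranded = TRUE) {
  if (is.character(annotation)) annotation <- read_annotation(annotation)
  genes <- annotation$genes
  exons <- annotation$exons
  contig <- is_mapped <- mapped_region <- is_antisense <- is_exonic <-
    is_intronic <- snv <- nb_mismatches <- nb_indels <- nb_hits <-
    ends_polyA <- NULL # data.table NSE
  n <- nrow(aln)
  ann <- copy(aln)
  ann[, c("gene_id", "is_antisense", "is_exonic", "is_intronic",
          "snv", "ends_polyA", "contig_length", "mapped_region",
          "du_pvalue", "gene_is_de") :=
        .(NA_character_, FALSE, FALSE, FALSE, FALSE, FALSE,
          nchar(contig), NA_integer_, NA_real_, NA)]
  if (!n) return(ann[])
  ann[is_mapped == TRUE, mapped_region := end - start]
  gr <- .alignment_granges(ann)
  if (length(gr)) {
    known_chrom <- as.character(GenomicRanges::seqnames(gr)) %in%
      unique(as.character(GenomicRanges::seqnames(genes)))
    if (!all(known_chrom))
      warning("contig chromosome absent from annotation; ",
              "features default to intergenic")
    # sense gene overlap (any strand when unstranded)
    ov_sense <- GenomicRanges::findOverlaps(gr, genes,
                                            ignore.strand = !stranded)
    if (length(ov_sense)) {
      hh <- S4Vectors::queryHits(ov_sense)
      best <- !duplicated(hh)
      ann$gene_id[gr$contig_row[hh[best]]] <-
        genes$gene_id[S4Vectors::subjectHits(ov_sense)[best]]
    }
    if (stranded) {
      ov_any <- GenomicRanges::findOverlaps(gr, genes, ignore.strand = TRUE)
      if (length(ov_any)) {
        hh <- S4Vectors::queryHits(ov_any)
        as_rows <- gr$contig_row[unique(hh)]
        no_sense <- is.na(ann$gene_id[as_rows])
        set_rows <- as_rows[no_sense]
        if (length(set_rows)) {
          ann$is_antisense[set_rows] <- TRUE
          first <- !duplicated(hh)
          as_gene <- stats::setNames(
            genes$gene_id[S4Vectors::subjectHits(ov_any)[first]],
            gr$contig_row[hh[first]])
          ann$gene_id[set_rows] <- unname(as_gene[as.character(set_rows)])
        }
      }
    }
    ex_hit <- IRanges::overlapsAny(gr, exons, ignore.strand = !stranded)
    intr <- GenomicRanges::setdiff(
      GenomicRanges::reduce(genes, ignore.strand = FALSE),
      GenomicRanges::reduce(exons, ignore.strand = FALSE))
    in_hit <- IRanges::overlapsAny(gr, intr, ignore.strand = !stranded)
    ann$is_exonic[gr$contig_row] <- ex_hit
    ann$is_intronic[gr$contig_row] <- in_hit
    # antisense rows: the sense-side exon/intron flags do not apply
    ann[is_antisense == TRUE, c("is_exonic", "is_intronic") := FALSE]
  }
  ann[is_mapped == TRUE,
      snv := (nb_mismatches + nb_indels >= 1L) & nb_hits == 1L]
  tail_len <- ann$clipped_3p
  tail_ok <- !is.na(tail_len) & tail_len >= 5L
  last5 <- substring(ann$contig, ann$contig_length - 4L, ann$contig_length)
  ann[, ends_polyA := tail_ok & last5 == "AAAAA"]
  ann[]
}

#' Write mapped contigs as a BED6 display track
#'
#' BED is 0-based half-open; alignment spans are stored that way already.
#' The score is `min(1000, round(-10 * log10(padj)))`; the name is the
#' contig id. Unmapped contigs are omitted.
#'
#' @param ann Annotation table (needs `chrom`, `start`, `end`, `strand`,
#'   `contig_id`, `is_mapped`, `padj`).
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
emit_bed <- function(ann, path) {
  m <- ann[ann$is_mapped, ]
  score <- if (nrow(m)) pmin(1000, round(-10 * log10(pmax(m$padj, 1e-300))))
           else integer(0)
  lines <- if (nrow(m))
    paste(m$chrom, m$start, m$end, m$contig_id, score, m$strand, sep = "\t")
  else character(0)
  writeLines(lines, path)
  invisible(path)
}
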