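#' Host-gene expression from gene-unique k-mers
#'
#' Internal gene quantification used to separate differential usage from
#' whole-gene differential expression: each annotated gene is quantified as
#' the mean count, across its k-mers that occur in no other gene's
#' transcripts, of the recurrence-filtered (pre-masking) k-mer matrix.
#' Gene-level DE is then tested with the same engine as the k-mer stage
#' (t-test or NB GLM) and adjusted with Benjamini-Hochberg; a gene is DE at
#' adjusted p <= 0.05. A gene with no unique k-mer has undefined expression
#' (`is_de = NA`).
#'
#' @param matrix_prefilter Recurrence-filtered, unmasked
#'   [kmer_count_matrix()].
#' @param transcriptome_fasta Reference transcript FASTA; record names must
#'   be transcript ids present in the annotation.
#' @param annotation List from [read_annotation()] (or GFF3 path).
#' @param nf Normalization factors from [compute_nf()].
#' @param params [kmer_params()] used for the matrix.
#' @param method Test engine, `"ttest"` or `"glm"`.
#' @return List with `expr` (genes x samples matrix of NF-normalized mean
#'   counts; NA rows for genes without unique k-mers) and `de`
#'   (`data.table`: `gene_id`, `pvalue`, `padj`, `is_de`).
#' @export
gene_expression <- function(matrix_prefilter, transcriptome_fasta,
                            annotation, nf, params,
                            method = c("ttest", "glm")) {
  method <- match.arg(method)
  if (is.character(annotation)) annotation <- read_annotation(annotation)
  tx <- Biostrings::readDNAStringSet(transcriptome_fasta)
  names(tx) <- sub("\\s.*$", "", names(tx))
  tx2gene <- stats::setNames(annotation$exons$gene_id,
                             annotation$exons$transcript_id)
  tx2gene <- tx2gene[!duplicated(names(tx2gene))]
  gene_ids <- sort(unique(annotation$genes$gene_id))
  kmer <- gene <- count <- ng <- NULL # data.table NSE
  maps <- lapply(seq_along(tx), function(i) {
    km <- .window_kmers(as.character(tx[[i]]), params$k)
    if (params$strand_mode == "unstranded" && length(km)) km <- canonical(km)
    g <- unname(tx2gene[names(tx)[i]])
    if (is.na(g) || !length(km)) return(NULL)
    data.table(kmer = unique(km), gene = g)
  })
  kg <- unique(rbindlist(maps))
  n_gene <- kg[, .(ng = length(unique(gene))), by = kmer]
  uniq <- kg[kmer %chin% n_gene[ng == 1L]$kmer]
  samples <- matrix_prefilter$samples
  n <- nrow(samples)
  expr_raw <- matrix(NA_real_, length(gene_ids), n,
                     dimnames = list(gene_ids, samples$library_id))
  row_ix <- match(uniq$kmer, matrix_prefilter$kmers)
  uniq <- uniq[!is.na(row_ix)]
  row_ix <- row_ix[!is.na(row_ix)]
  if (nrow(uniq)) {
    for (g in unique(uniq$gene)) {
      rs <- row_ix[uniq$gene == g]
      expr_raw[g, ] <- colMeans(
        matrix_prefilter$counts[rs, , drop = FALSE])
    }
  }
  genes_with <- gene_ids[rowSums(is.na(expr_raw)) == 0 &
                           gene_ids %in% unique(uniq$gene)]
  de <- data.table(gene_id = gene_ids, pvalue = NA_real_,
                   padj = NA_real_, is_de = NA)
  if (length(genes_with)) {
    cnt <- round(expr_raw[genes_with, , drop = FALSE])
    storage.mode(cnt) <- "integer"
    groups <- samples$condition
    p <- if (method == "ttest") ttest_pvalue(cnt, nf, groups)
         else glm_chunk_pvalues(cnt, nf, groups)
    padj <- bh_adjust(p)
    ix <- match(genes_with, de$gene_id)
    de$pvalue[ix] <- p
    de$padj[ix] <- padj
    de$is_de[ix] <- padj <= 0.05
  }
  expr <- sweep(expr_raw, 2, nf, "/")
  list(expr = expr, de = de[])
}

#' Differential-usage p-value of a contig relative to its host gene
#'
#' Tests whether a contig's abundance changes relative to its host gene's
#' overall expression: per sample, `r_j = log2((c_j/NF_j + 1) /
#' (g_j + 1))` where `c_j` is the contig (label k-mer) count and `g_j` the
#' gene's normalized expression; a two-sided Welch t-test compares the
#' ratios between conditions. A constant ratio (e.g. contig and gene scaled
#' together) gives p near 1; zero within-group variance with equal means
#' gives p = 1 by convention. Undefined gene expression gives `NA` (the DU
#' event classes are then unreachable).
#'
#' @param contig_counts Integer vector of the contig's per-sample counts.
#' @param gene_expr Numeric vector of the host gene's normalized expression
#'   per sample (a row of `gene_expression()$expr`).
#' @param nf Normalization factors.
#' @param groups Condition labels, two levels.
#' @return Numeric p-value, or `NA` when the gene expression is undefined.
#' @export
du_test <- function(contig_counts, gene_expr, nf, groups) {
  if (anyNA(gene_expr)) return(NA_real_)
  r <- log2((contig_counts / nf + 1) / (gene_expr + 1))
  groups <- as.factor(groups)
  is_a <- groups == levels(groups)[1]
  ra <- r[is_a]; rb <- r[!is_a]
  va <- stats::var(ra); vb <- stats::var(rb)
  if (va + vb == 0)
    return(if (abs(mean(ra) - mean(rb)) < .Machine$double.eps^0.5) 1 else 0)
  na <- length(ra); nb <- length(rb)
  se2 <- va / na + vb / nb
  tstat <- (mean(rb) - mean(ra)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  2 * stats::pt(-abs(tstat), df)
}

#' Event classes
#'
#' The fixed rule order of the classifier: differential-usage variants
#' before their parent classes, specific classes before generic ones.
#'
#' @return Character vector of class names in rule order.
#' @export
event_classes <- function() {
  c("splicing_DU", "splicing", "polyA_DU", "polyA", "lincRNA", "asRNA",
    "SNV_DU", "intron_DU", "intron", "repeats", "unmapped", "unclassified")
}

#' Classify annotated contigs into event classes
#'
#' Applies the event rule set to each annotated contig; the first matching
#' rule wins. "Maps gene" means a sense-strand gene overlap; antisense
#' overlaps do not count as gene hits. The rules (with `du` the
#' differential-usage p-value, `J` the junction count, `hits` the number of
#' genomic hits, `len` the contig length and `region` the mapped span):
#'
#' * `splicing_DU`: du < 0.01, J > 0, gene, not antisense, hits = 1
#' * `splicing`: J > 0, gene, not antisense, hits = 1
#' * `polyA_DU`: du < 0.01, 3' clip >= 5 ending in >= 5 A, mapped, hits = 1
#' * `polyA`: as above without the DU condition
#' * `lincRNA`: intergenic, mapped, hits = 1, len > 200, mean normalized
#'   count > 20 in at least one condition, region < 10 kb
#' * `asRNA`: antisense only, mapped, hits = 1, len > 200, region < 10 kb
#' * `SNV_DU`: du < 0.01, gene, not antisense, mapped, SNV flag, exonic,
#'   hits = 1, host gene not DE
#' * `intron_DU` / `intron`: (du < 0.01) gene, not antisense, J = 0,
#'   mapped, intronic, hits = 1
#' * `repeats`: mapped, hits >= 5, len > 50
#' * `unmapped`: not mapped, len > 50
#' * otherwise `unclassified`
#'
#' @param ann Annotation table from [annotate_contigs()], with `du_pvalue`
#'   and `gene_is_de` filled in (NA allowed: DU classes and the SNV rule
#'   are then unreachable) and `meanA`/`meanB` normalized condition means.
#' @param du_threshold DU p-value cutoff (default 0.01, on the raw DU p).
#' @return The table with a `class` column appended.
#' @export
classify_contigs <- function(ann, du_threshold = 0.01) {
  class <- NULL # data.table NSE
  ann <- copy(ann)
  du <- ann$du_pvalue
  du_ok <- !is.na(du) & du < du_threshold
  maps_gene <- !is.na(ann$gene_id) & !ann$is_antisense
  anti <- ann$is_antisense %in% TRUE
  hits1 <- ann$nb_hits == 1L
  mapped <- ann$is_mapped %in% TRUE
  junc <- ifelse(is.na(ann$nb_junctions), 0L, ann$nb_junctions)
  len <- ann$contig_length
  region <- ann$mapped_region
  pa <- ann$ends_polyA %in% TRUE & !is.na(ann$clipped_3p) &
    ann$clipped_3p >= 5L
  expressed <- pmax(ann$meanA, ann$meanB) > 20
  gene_not_de <- !(ann$gene_is_de %in% TRUE)
  snv <- ann$snv %in% TRUE

  cls <- rep("unclassified", nrow(ann))
  rules <- list(
    splicing_DU = du_ok & junc > 0 & maps_gene & !anti & hits1,
    splicing    = junc > 0 & maps_gene & !anti & hits1,
    polyA_DU    = du_ok & pa & mapped & hits1,
    polyA       = pa & mapped & hits1,
    lincRNA     = !maps_gene & !anti & mapped & hits1 & len > 200 &
                    expressed & !is.na(region) & region < 10000,
    asRNA       = anti & mapped & hits1 & len > 200 &
                    !is.na(region) & region < 10000,
    SNV_DU      = du_ok & maps_gene & !anti & mapped & snv &
                    ann$is_exonic %in% TRUE & hits1 & gene_not_de &
                    !is.na(ann$gene_is_de),
    intron_DU   = du_ok & maps_gene & !anti & junc == 0 & mapped &
                    ann$is_intronic %in% TRUE & hits1,
    intron      = maps_gene & !anti & junc == 0 & mapped &
                    ann$is_intronic %in% TRUE & hits1,
    repeats     = mapped & ann$nb_hits >= 5L & len > 50,
    unmapped    = !mapped & len > 50
  )
  for (nm in names(rules)) {
    hit <- rules[[nm]] & cls == "unclassified"
    cls[hit] <- nm
  }
  ann[, class := cls]
  ann[]
}

#' Group classified contigs into loci
#'
#' A locus is an annotated gene, the opposite strand of an annotated gene,
#' or the genomic interval between two annotated genes (identified by its
#' flanking gene ids, ignoring strand). Every classified contig belongs to
#' exactly one locus; unmapped contigs are pooled into a dedicated
#' `unmapped` locus. Each locus reports its contig count and its best
#' contig (lowest adjusted p).
#'
#' @param classified Table from [classify_contigs()] (needs `gene_id`,
#'   `is_antisense`, `chrom`, `start`, `end`, `is_mapped`, `padj`,
#'   `contig_id`).
#' @param annotation List from [read_annotation()] (or GFF3 path).
#' @return `data.table`: `locus_id`, `n_contigs`, `best_contig`,
#'   `best_padj`.
#' @export
group_loci <- function(classified, annotation) {
  if (is.character(annotation)) annotation <- read_annotation(annotation)
  genes <- annotation$genes
  gdt <- data.table(gene_id = genes$gene_id,
                    chrom = as.character(GenomicRanges::seqnames(genes)),
                    gstart = GenomicRanges::start(genes),
                    gend = GenomicRanges::end(genes))
  setorderv(gdt, c("chrom", "gstart"))
  locus_of <- function(i) {
    row <- classified[i]
    if (!(row$is_mapped %in% TRUE)) return("unmapped")
    if (!is.na(row$gene_id)) {
      if (row$is_antisense %in% TRUE) return(paste0("as:", row$gene_id))
      return(row$gene_id)
    }
    g <- gdt[chrom == row$chrom]
    left <- g[gend <= row$start + 1L]
    right <- g[gstart >= row$end]
    paste0(if (nrow(left)) left$gene_id[nrow(left)] else ".", "|",
           if (nrow(right)) right$gene_id[1] else ".")
  }
  chrom <- gstart <- gend <- padj <- locus_id <- contig_id <- NULL
  if (!nrow(classified))
    return(data.table(locus_id = character(0), n_contigs = integer(0),
                      best_contig = character(0), best_padj = numeric(0)))
  loci <- vapply(seq_len(nrow(classified)), locus_of, character(1))
  dt <- copy(classified)[, locus_id := loci]
  out <- dt[order(padj)][, .(n_contigs = .N,
                             best_contig = contig_id[1],
                             best_padj = padj[1]), by = locus_id]
  setorderv(out, "locus_id")
  out[]
}
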