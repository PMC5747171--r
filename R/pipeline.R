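#' Pipeline configuration
#'
#' Collects every parameter of a full run. `samples` is the sample sheet:
#' one row per library with `library_id`, `condition` (two levels, at least
#' two libraries each) and `fastq` (path, or several paths separated by
#' `;` for paired files).
#'
#' @param samples `data.frame` sample sheet (see above).
#' @param genome_fasta Reference genome FASTA used for contig alignment.
#' @param gff3 GFF3 annotation used for contig annotation.
#' @param masking Reference transcriptome FASTA for masking, or `"none"`
#'   to bypass masking entirely.
#' @param output_dir Output directory.
#' @param kmer_length k-mer length (default 31).
#' @param min_recurrence Recurrence filter threshold; default = number of
#'   replicates in the smaller condition.
#' @param min_recurrence_abundance Abundance threshold of the recurrence
#'   filter (default 5).
#' @param min_abundance Per-library minimum k-mer count (default 2).
#' @param pvalue_threshold Adjusted-p cutoff for DE k-mers (default 0.05).
#' @param lib_type `"stranded"` or `"unstranded"`.
#' @param diff_method `"ttest"` or `"glm"`.
#' @param min_overlap Minimum contig-extension overlap (default 15).
#' @param seed Seed for the NF subsample and any other randomness.
#' @return A `pipeline_config` list (validated).
#' @export
pipeline_config <- function(samples, genome_fasta, gff3,
                            masking = "none", output_dir,
                            kmer_length = 31L, min_recurrence = NULL,
                            min_recurrence_abundance = 5L,
                            min_abundance = 2L,
                            pvalue_threshold = 0.05,
                            lib_type = c("stranded", "unstranded"),
                            diff_method = c("ttest", "glm"),
                            min_overlap = 15L, seed = 42L) {
  lib_type <- match.arg(lib_type)
  diff_method <- match.arg(diff_method)
  samples <- as.data.frame(samples)
  stopifnot(all(c("library_id", "condition", "fastq") %in% names(samples)))
  tab <- table(samples$condition)
  if (length(tab) != 2L || any(tab < 2L))
    stop("need two conditions with at least 2 libraries each", call. = FALSE)
  if (is.null(min_recurrence)) min_recurrence <- min(tab)
  structure(list(samples = samples, genome_fasta = genome_fasta,
                 gff3 = gff3, masking = masking, output_dir = output_dir,
                 kmer_length = as.integer(kmer_length),
                 min_recurrence = as.integer(min_recurrence),
                 min_recurrence_abundance = as.integer(min_recurrence_abundance),
                 min_abundance = as.integer(min_abundance),
                 pvalue_threshold = pvalue_threshold,
                 lib_type = lib_type, diff_method = diff_method,
                 min_overlap = as.integer(min_overlap),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' The file holds the scalar fields of [pipeline_config()] plus a
#' `samples` list of `{library_id, condition, fastq}` records.
#'
#' @param path YAML config path.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  samples <- do.call(rbind, lapply(y$samples, function(s)
    data.frame(library_id = s$library_id, condition = s$condition,
               fastq = s$fastq, stringsAsFactors = FALSE)))
  y$samples <- NULL
  do.call(pipeline_config, c(list(samples = samples), y))
}

#' Run the full differential k-mer pipeline
#'
#' Executes, in order: per-library k-mer counting, sorted dumps, matrix
#' join, recurrence filter, normalization factors (from the filtered,
#' pre-masking counts), transcriptome masking, differential testing,
#' contig extension, adapter screening, genome alignment, annotation,
#' gene-level expression and differential usage, event classification and
#' locus grouping. Intermediate tables are written to `output_dir`
#' (`filtered_counts.tsv.gz`, `masked-counts.tsv.gz`, `diff-counts.tsv.gz`,
#' `merged-diff-counts.tsv.gz`, `contig-summary.tsv.gz`,
#' `locus-summary.tsv`, `contigs.bed`) together with `run_log.txt`
#' recording every parameter and the row count surviving each stage.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the classified contig table
#'   (`contigs`), locus summary (`loci`), per-stage row counts
#'   (`stage_counts`), normalization factors (`nf`), gene DE table
#'   (`gene_de`) and all output paths (`paths`).
#' @export
run_pipeline <- function(config) {
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stage_counts <- list()
  log_lines <- c("kmerDE pipeline run", format(Sys.time()),
                 "", "parameters:")
  for (nm in setdiff(names(config), "samples"))
    log_lines <- c(log_lines, paste0("  ", nm, " = ",
                                     paste(config[[nm]], collapse = " ")))
  log_lines <- c(log_lines, paste0("  samples = ",
                                   paste(config$samples$library_id,
                                         collapse = " ")))

  params <- kmer_params(k = config$kmer_length,
                        strand_mode = config$lib_type,
                        min_abundance = config$min_abundance)

  # 1. count + dump per library
  dump_paths <- character(nrow(config$samples))
  for (i in seq_len(nrow(config$samples))) {
    fq <- strsplit(config$samples$fastq[i], ";", fixed = TRUE)[[1]]
    orient <- if (length(fq) == 2L) c("forward", "reverse") else "forward"
    tab <- count_library(fq, params, mate_orientations = orient,
                         library_id = config$samples$library_id[i])
    dump_paths[i] <- file.path(out, paste0(config$samples$library_id[i],
                                           "_counts.tsv.gz"))
    dump_sorted(tab, dump_paths[i])
  }

  # 2. join
  mat <- join_counts(dump_paths, config$samples[, c("library_id",
                                                    "condition")])
  stage_counts$raw_kmers <- length(mat$kmers)

  # 3. recurrence filter
  filt <- recurrence_filter(mat, config$min_recurrence,
                            config$min_recurrence_abundance)
  stage_counts$filtered_kmers <- length(filt$kmers)
  write_count_matrix(filt, file.path(out, "filtered_counts.tsv.gz"))

  # 4. normalization factors (pre-masking counts)
  nf <- compute_nf(filt, frac = 0.30, seed = config$seed)

  # 5. masking
  if (identical(config$masking, "none")) {
    masked <- filt
    mask <- character(0)
  } else {
    mask <- build_mask(config$masking, params)
    masked <- apply_mask(filt, mask)
  }
  stage_counts$masked_kmers <- length(masked$kmers)
  write_count_matrix(masked, file.path(out, "masked-counts.tsv.gz"))

  # 6. differential expression
  diff <- de_filter(masked, nf, method = config$diff_method,
                    pvalue_threshold = config$pvalue_threshold)
  stage_counts$de_kmers <- nrow(diff)
  write_diff_table(diff, file.path(out, "diff-counts.tsv.gz"))

  # 7. contig extension
  contigs <- merge_tags(diff, k = config$kmer_length,
                        min_overlap = config$min_overlap)
  stage_counts$contigs <- nrow(contigs)
  write_diff_table(contigs, file.path(out, "merged-diff-counts.tsv.gz"))

  # 8. adapter screen
  scr <- adapter_screen(contigs$contig)
  contig <- contig_id <- NULL # data.table NSE
  contigs <- contigs[contig %chin% scr$kept]
  stage_counts$contigs_after_adapter_screen <- nrow(contigs)

  # 9. alignment + annotation
  annotation <- read_annotation(config$gff3)
  gidx <- index_genome(config$genome_fasta)
  seqs <- contigs$contig
  names(seqs) <- sprintf("ctg%05d", seq_along(seqs))
  aln <- align_builtin(seqs, gidx, annotation)
  ann <- annotate_contigs(aln, annotation,
                          stranded = config$lib_type == "stranded")
  ann <- cbind(ann,
               contigs[match(ann$contig, contigs$contig),
                       !"contig", with = FALSE])
  stage_counts$contigs_mapped <- sum(ann$is_mapped)

  # 10. gene expression + differential usage
  sample_ids <- config$samples$library_id
  if (!identical(config$masking, "none")) {
    ge <- gene_expression(filt, config$masking, annotation, nf, params,
                          method = config$diff_method)
    groups <- config$samples$condition
    du <- rep(NA_real_, nrow(ann))
    gde <- rep(NA, nrow(ann))
    for (i in seq_len(nrow(ann))) {
      gid <- ann$gene_id[i]
      if (is.na(gid) || ann$is_antisense[i]) next
      gx <- ge$expr[gid, ]
      cc <- as.numeric(ann[i, sample_ids, with = FALSE])
      du[i] <- du_test(cc, gx, nf, groups)
      gde[i] <- ge$de$is_de[match(gid, ge$de$gene_id)]
    }
    ann$du_pvalue <- du
    ann$gene_is_de <- gde
  } else {
    ge <- NULL
  }

  # 11. classification + loci
  ann <- classify_contigs(ann)
  loci <- group_loci(ann, annotation)
  stage_counts$loci <- nrow(loci)

  paths <- list(
    contig_summary = file.path(out, "contig-summary.tsv.gz"),
    locus_summary = file.path(out, "locus-summary.tsv"),
    bed = file.path(out, "contigs.bed"),
    log = file.path(out, "run_log.txt"))
  write_diff_table(ann, paths$contig_summary)
  utils::write.table(loci, paths$locus_summary, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  emit_bed(ann, paths$bed)

  log_lines <- c(log_lines, "", "stage row counts:")
  for (nm in names(stage_counts))
    log_lines <- c(log_lines, paste0("  ", nm, " = ", stage_counts[[nm]]))
  writeLines(log_lines, paths$log)

  invisible(list(contigs = ann, loci = loci, stage_counts = stage_counts,
                 nf = nf, gene_de = if (is.null(ge)) NULL else ge$de,
                 diff = diff, paths = paths))
}
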