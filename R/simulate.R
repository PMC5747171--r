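#' Simulation configuration
#'
#' Parameters of the synthetic study: a toy genome with annotated multi-exon
#' genes on both strands, two conditions of `n_replicates` libraries each
#' with negative-binomial expression noise, and one spiked-in differential
#' event per biological class (novel splice junction, polyadenylated 3'
#' end, intergenic lincRNA, antisense transcript, exonic SNV with shifted
#' allelic balance in a non-DE gene, retained intron, tandem repeat,
#' exogenous sequence). Defaults emulate a 6 vs 6 stranded design.
#'
#' @param seed Integer seed; a fixed seed gives identical outputs.
#' @param genome_length Genome size in nt (default 100 kb, one chromosome).
#' @param n_genes Number of annotated genes (default 20, 2-4 exons each).
#' @param n_replicates Libraries per condition (default 6).
#' @param read_length Read length (default 75).
#' @param depth Mean reads per transcript per library (default 400).
#' @param nb_dispersion Negative-binomial dispersion of per-transcript
#'   library counts (default 0.1).
#' @param error_rate Per-base substitution error rate (default 0, so
#'   masking-completeness invariants are exact).
#' @param stranded Logical; stranded library prep (default TRUE).
#' @param spikes Character vector of event classes to spike (default all
#'   eight); subset of `c("splicing", "polyA", "lincRNA", "asRNA", "SNV",
#'   "intron", "repeats", "unmapped")`, or `NULL` for a spike-free (null)
#'   study.
#' @param polyA_tail Length of the non-genomic poly(A) tail appended to the
#'   polyadenylated isoform (default 60).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, genome_length = 100000L, n_genes = 20L,
                       n_replicates = 6L, read_length = 75L, depth = 400,
                       nb_dispersion = 0.1, error_rate = 0,
                       stranded = TRUE,
                       spikes = c("splicing", "polyA", "lincRNA", "asRNA",
                                  "SNV", "intron", "repeats", "unmapped"),
                       polyA_tail = 60L) {
  spikes <- if (is.null(spikes) || !length(spikes)) character(0)
            else match.arg(spikes, several.ok = TRUE)
  structure(list(seed = as.integer(seed), genome_length = genome_length,
                 n_genes = n_genes, n_replicates = n_replicates,
                 read_length = read_length, depth = depth,
                 nb_dispersion = nb_dispersion, error_rate = error_rate,
                 stranded = stranded, spikes = spikes,
                 polyA_tail = as.integer(polyA_tail)),
            class = "sim_config")
}

.rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = "")

.write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "wb"); on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Generate the synthetic genome, annotation and transcriptome
#'
#' Builds a random genome carrying non-overlapping multi-exon genes on
#' alternating strands (GT..AG dinucleotides are written at every annotated
#' intron boundary, in the gene's orientation), one intergenic 6-copy
#' tandem repeat array (66 nt unit) and one unannotated intergenic region
#' reserved for a lincRNA spike. The transcriptome FASTA contains one
#' spliced transcript per annotated gene, named `<gene>.t1`.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed); files `genome.fa`,
#'   `annotation.gff3` and `transcripts.fa` are written there.
#' @return List with paths (`genome_fasta`, `gff3`, `transcriptome_fasta`)
#'   and in-memory objects: `genome` (string), `genes` (`data.table`),
#'   `exons` (`data.table`), `transcripts` (named character),
#'   `repeat_region` (start, end, unit), `linc_region` (start, end).
#' @export
make_reference <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed)
  g <- sample(c("A", "C", "G", "T"), config$genome_length, TRUE)

  genes <- list(); exons <- list()
  cursor <- 500L
  repeat_region <- NULL; linc_region <- NULL
  unit <- .rand_dna(66L)
  for (i in seq_len(config$n_genes)) {
    n_ex <- sample(2:4, 1L)
    ex_len <- sample(150:300, n_ex, TRUE)
    in_len <- sample(200:350, max(n_ex - 1L, 0L), TRUE)
    span <- sum(ex_len) + sum(in_len)
    if (cursor + span + 2000L > config$genome_length)
      stop("genes cannot be placed; increase genome_length", call. = FALSE)
    strand <- if (i %% 2L == 1L) "+" else "-"
    gid <- sprintf("G%02d", i)
    s <- cursor
    pos <- s
    for (e in seq_len(n_ex)) {
      exons[[length(exons) + 1L]] <-
        data.table(gene_id = gid, exon = e, start = pos,
                   end = pos + ex_len[e] - 1L)
      pos <- pos + ex_len[e]
      if (e < n_ex) {
        istart <- pos; iend <- pos + in_len[e] - 1L
        if (strand == "+") {
          g[istart] <- "G"; g[istart + 1L] <- "T"
          g[iend - 1L] <- "A"; g[iend] <- "G"
        } else {
          g[istart] <- "C"; g[istart + 1L] <- "T"
          g[iend - 1L] <- "A"; g[iend] <- "C"
        }
        pos <- iend + 1L
      }
    }
    genes[[length(genes) + 1L]] <-
      data.table(gene_id = gid, strand = strand, start = s,
                 end = pos - 1L, n_exons = n_ex)
    cursor <- pos - 1L + sample(600:900, 1L)
    if (i == ceiling(config$n_genes / 3)) {
      # intergenic tandem repeat array (6 x 66 nt)
      arr <- strsplit(strrep(unit, 6L), "")[[1]]
      repeat_region <- c(start = cursor, end = cursor + length(arr) - 1L)
      g[cursor:(cursor + length(arr) - 1L)] <- arr
      cursor <- cursor + length(arr) + sample(600:900, 1L)
    }
    if (i == ceiling(2 * config$n_genes / 3)) {
      # intergenic region reserved for the lincRNA
      linc_region <- c(start = cursor, end = cursor + 399L)
      cursor <- cursor + 400L + sample(600:900, 1L)
    }
  }
  genome <- paste(g, collapse = "")
  genes <- rbindlist(genes)
  exons <- rbindlist(exons)

  # spliced transcripts (one per gene)
  transcripts <- character(0)
  gene_id <- NULL # data.table NSE
  for (i in seq_len(nrow(genes))) {
    gid <- genes$gene_id[i]
    ex <- exons[gene_id == gid]
    seq <- paste(substring(genome, ex$start, ex$end), collapse = "")
    if (genes$strand[i] == "-") seq <- revcomp(seq)
    transcripts[[paste0(gid, ".t1")]] <- seq
  }

  genome_fasta <- file.path(dir, "genome.fa")
  .write_fasta(list(chr1 = genome), genome_fasta)
  tx_fasta <- file.path(dir, "transcripts.fa")
  .write_fasta(as.list(transcripts), tx_fasta)
  gff3 <- file.path(dir, "annotation.gff3")
  .write_gff3(genes, exons, gff3)

  list(genome_fasta = genome_fasta, gff3 = gff3,
       transcriptome_fasta = tx_fasta,
       genome = genome, genes = genes, exons = exons,
       transcripts = transcripts,
       repeat_region = repeat_region, repeat_unit = unit,
       linc_region = linc_region)
}

.write_gff3 <- function(genes, exons, path) {
  con <- file(path, "wb"); on.exit(close(con))
  writeLines("##gff-version 3", con)
  gene_id <- NULL # data.table NSE
  for (i in seq_len(nrow(genes))) {
    gn <- genes[i]
    writeLines(paste("chr1", "sim", "gene", gn$start, gn$end, ".",
                     gn$strand, ".", paste0("ID=", gn$gene_id),
                     sep = "\t"), con)
    tid <- paste0(gn$gene_id, ".t1")
    writeLines(paste("chr1", "sim", "mRNA", gn$start, gn$end, ".",
                     gn$strand, ".",
                     paste0("ID=", tid, ";Parent=", gn$gene_id),
                     sep = "\t"), con)
    ex <- exons[gene_id == gn$gene_id]
    for (e in seq_len(nrow(ex))) {
      writeLines(paste("chr1", "sim", "exon", ex$start[e], ex$end[e], ".",
                       gn$strand, ".",
                       paste0("ID=", tid, ".e", e, ";Parent=", tid),
                       sep = "\t"), con)
    }
  }
  invisible(path)
}

# pick spike target genes deterministically from the reference layout
.spike_targets <- function(ref) {
  genes <- ref$genes
  gene_id <- strand <- n_exons <- NULL # data.table NSE
  plus <- genes[strand == "+"]
  t_spl <- plus[n_exons >= 3L]$gene_id[1]
  rest <- setdiff(plus$gene_id, t_spl)
  t_pa <- rest[1]; t_snv <- rest[2]; t_as <- rest[3]
  t_int <- setdiff(genes[n_exons >= 2L]$gene_id,
                   c(t_spl, t_pa, t_snv, t_as))[1]
  list(splicing = t_spl, polyA = t_pa, SNV = t_snv, asRNA = t_as,
       intron = t_int)
}

# novel isoform sequences for each spiked event; returns list of
# (name, sequence, host_gene or NA, truth row)
.build_spike_isoforms <- function(config, ref) {
  ex_all <- ref$exons
  gene_id <- NULL # data.table NSE
  tg <- .spike_targets(ref)
  iso <- list(); truth <- list()
  add <- function(name, seq, host, class, interval, novel, note = "") {
    iso[[name]] <<- seq
    truth[[length(truth) + 1L]] <<- data.table(
      event = class, name = name, host_gene = host,
      interval = interval, novel_seq = novel, direction = "up_in_B",
      note = note)
  }
  has <- function(cl) cl %in% config$spikes

  if (has("splicing")) {
    gid <- tg$splicing
    ex <- ex_all[gene_id == gid]
    keep <- ex[-2L]                     # skip exon 2: novel exon1-exon3 junction
    seq <- paste(substring(ref$genome, keep$start, keep$end), collapse = "")
    jl <- keep$end[1] - keep$start[1] + 1L   # junction position in isoform
    add("spike_splicing", seq, gid, "splicing",
        sprintf("chr1:%d-%d", ex$end[1], ex$start[3]),
        substring(seq, jl - 29L, jl + 30L),
        note = "exon-skipping isoform")
  }
  if (has("polyA")) {
    gid <- tg$polyA
    tx <- ref$transcripts[[paste0(gid, ".t1")]]
    seq <- paste0(tx, strrep("A", config$polyA_tail))
    ex <- ex_all[gene_id == gid]
    add("spike_polyA", seq, gid, "polyA",
        sprintf("chr1:%d-%d", ex$end[nrow(ex)], ex$end[nrow(ex)]),
        paste0(substring(tx, nchar(tx) - 29L, nchar(tx)), "AAAAA..."),
        note = sprintf("polyadenylated 3' end, %d-A tail", config$polyA_tail))
  }
  if (has("lincRNA")) {
    r <- ref$linc_region
    seq <- substring(ref$genome, r["start"], r["end"])
    add("spike_lincRNA", seq, NA_character_, "lincRNA",
        sprintf("chr1:%d-%d", r["start"], r["end"]),
        substring(seq, 1L, 40L), note = "unannotated intergenic transcript")
  }
  if (has("asRNA")) {
    gid <- tg$asRNA
    gn <- ref$genes[gene_id == gid]
    s <- gn$start + 20L
    seq <- revcomp(substring(ref$genome, s, s + 399L))
    add("spike_asRNA", seq, gid, "asRNA",
        sprintf("chr1:%d-%d", s, s + 399L),
        substring(seq, 1L, 40L), note = "antisense of an annotated gene")
  }
  if (has("SNV")) {
    gid <- tg$SNV
    ex <- ex_all[gene_id == gid]
    tx <- ref$transcripts[[paste0(gid, ".t1")]]
    pos <- nchar(substring(ref$genome, ex$start[1], ex$end[1])) %/% 2L
    if (pos < 35L) pos <- 40L
    refbase <- substring(tx, pos, pos)
    altbase <- setdiff(c("A", "C", "G", "T"), refbase)[1]
    alt <- tx
    substr(alt, pos, pos) <- altbase
    add("spike_SNV", alt, gid, "SNV",
        sprintf("chr1:%d", ex$start[1] + pos - 1L),
        paste0(refbase, ">", altbase),
        note = "alt allele at 50% in condition B only; gene total flat")
  }
  if (has("intron")) {
    gid <- tg$intron
    gn <- ref$genes[gene_id == gid]
    ex <- ex_all[gene_id == gid]
    # retained intron 1: exon1 + intron1 + remaining exons, genomic order
    parts <- c(substring(ref$genome, ex$start[1], ex$end[2]),
               if (nrow(ex) > 2L)
                 substring(ref$genome, ex$start[3:nrow(ex)],
                           ex$end[3:nrow(ex)]))
    seq <- paste(parts, collapse = "")
    if (gn$strand == "-") seq <- revcomp(seq)
    add("spike_intron", seq, gid, "intron",
        sprintf("chr1:%d-%d", ex$end[1] + 1L, ex$start[2] - 1L),
        substring(ref$genome, ex$end[1] - 10L, ex$end[1] + 30L),
        note = "retained intron 1")
  }
  if (has("repeats")) {
    # transcript shorter than unit + k: no k-mer phase cycle, so the
    # assembled contig is a faithful substring with 5 array hits
    r <- ref$repeat_region
    seq <- substring(ref$genome, r["start"] + 3L, r["start"] + 3L + 89L)
    add("spike_repeats", seq, NA_character_, "repeats",
        sprintf("chr1:%d-%d", r["start"], r["end"]),
        substring(ref$repeat_unit, 1L, 40L),
        note = "transcribed 6-copy tandem repeat")
  }
  if (has("unmapped")) {
    # isolated RNG stream: the insert is a pure function of the seed, so
    # repeated calls (and downstream truth checks) see the same sequence
    rng <- .save_rng()
    set.seed(config$seed + 7777L)
    seq <- .rand_dna(300L)
    .restore_rng(rng)
    add("spike_unmapped", seq, NA_character_, "unmapped", NA_character_,
        substring(seq, 1L, 40L), note = "exogenous insert absent from genome")
  }
  list(isoforms = iso, truth = rbindlist(truth), targets = tg)
}

#' Simulate two-condition FASTQ libraries with spiked events
#'
#' Samples per-library transcript counts from a negative binomial
#' (mean = `depth`, dispersion = `nb_dispersion`) for every annotated
#' (baseline) transcript in both conditions, and adds condition-B-specific
#' novel isoforms for each spiked event class: an exon-skipping isoform, a
#' polyadenylated read-through with a non-genomic A tail, an intergenic
#' lincRNA, an antisense transcript, an SNV allele at 50% frequency with
#' the host gene's total expression held flat, a retained-intron isoform,
#' a transcribed tandem-repeat region, and an exogenous insert. Reads of
#' length `read_length` are sampled uniformly along each transcript with
#' optional substitution errors, and written as one gzipped FASTQ per
#' library.
#'
#' @param config A [sim_config()].
#' @param ref Reference from [make_reference()].
#' @param dir Output directory for FASTQ files and `truth.tsv`.
#' @return List with `samples` (`data.frame`: `library_id`, `condition`,
#'   `fastq`), `truth` (`data.table` of spiked events), `spike_targets`,
#'   and `isoforms` (the spiked novel sequences, for truth evaluation).
#' @export
spike_and_simulate <- function(config, ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed + 1L)
  sp <- .build_spike_isoforms(config, ref)
  if ("intron" %in% config$spikes &&
      ref$genes[ref$genes$gene_id == sp$targets$intron]$n_exons < 2L)
    stop("intron spike targets a gene with no intron", call. = FALSE)

  # expression programme: named list of (sequence, meanA, meanB)
  prog <- list()
  for (nm in names(ref$transcripts))
    prog[[nm]] <- list(seq = ref$transcripts[[nm]],
                       meanA = config$depth, meanB = config$depth)
  dsp <- config$depth
  for (nm in names(sp$isoforms)) {
    cls <- sub("spike_", "", nm)
    prog[[nm]] <- list(seq = sp$isoforms[[nm]], meanA = 0, meanB = dsp)
  }
  if ("SNV" %in% config$spikes) {
    # hold the host gene's total flat: ref allele drops to 50% in B
    host_tx <- paste0(sp$targets$SNV, ".t1")
    prog[[host_tx]]$meanA <- config$depth
    prog[[host_tx]]$meanB <- config$depth / 2
    prog[["spike_SNV"]]$meanB <- config$depth / 2
  }

  n_rep <- config$n_replicates
  samples <- data.frame(
    library_id = c(sprintf("A%d", seq_len(n_rep)),
                   sprintf("B%d", seq_len(n_rep))),
    condition = rep(c("A", "B"), each = n_rep),
    stringsAsFactors = FALSE)
  samples$fastq <- file.path(dir, paste0(samples$library_id, ".fastq.gz"))

  rl <- config$read_length
  size <- 1 / config$nb_dispersion
  for (si in seq_len(nrow(samples))) {
    cond <- samples$condition[si]
    reads <- list()
    for (nm in names(prog)) {
      p <- prog[[nm]]
      mu <- if (cond == "A") p$meanA else p$meanB
      if (mu <= 0) next
      n_reads <- stats::rnbinom(1L, mu = mu, size = size)
      if (n_reads == 0L) next
      L <- nchar(p$seq)
      if (L < rl) next
      starts <- sample.int(L - rl + 1L, n_reads, replace = TRUE)
      reads[[nm]] <- substring(p$seq, starts, starts + rl - 1L)
    }
    seqs <- unlist(reads, use.names = FALSE)
    if (config$error_rate > 0 && length(seqs)) {
      n_err <- stats::rbinom(length(seqs), rl, config$error_rate)
      for (ri in which(n_err > 0)) {
        pos <- sample.int(rl, n_err[ri])
        s <- seqs[ri]
        for (pp in pos)
          substr(s, pp, pp) <- sample(c("A", "C", "G", "T"), 1L)
        seqs[ri] <- s
      }
    }
    con <- gzfile(samples$fastq[si], "wb")
    if (length(seqs)) {
      ids <- sprintf("@%s_read%06d", samples$library_id[si],
                     seq_along(seqs))
      qual <- strrep("I", rl)
      writeLines(rbind(ids, seqs, "+", qual), con)
    }
    close(con)
  }
  truth_path <- file.path(dir, "truth.tsv")
  utils::write.table(sp$truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(samples = samples, truth = sp$truth, spike_targets = sp$targets,
       isoforms = sp$isoforms, truth_path = truth_path)
}

#' Simulate negative-binomial k-mer count rows
#'
#' Stand-alone row simulator for calibration studies of the testing stage:
#' `n_null` rows with equal means in both conditions plus `n_spiked` rows
#' whose condition-B mean is `fold` times larger. Row means are drawn
#' log-uniformly from `mean_range`.
#'
#' @param n_null,n_spiked Number of null / differential rows.
#' @param n_per_group Samples per condition.
#' @param mean_range Range of baseline means (log-uniform draw).
#' @param dispersion NB dispersion.
#' @param fold Fold change of spiked rows (condition B).
#' @param seed Integer seed.
#' @return List: `counts` (matrix), `groups` (character), `is_spiked`
#'   (logical per row).
#' @export
simulate_count_rows <- function(n_null, n_spiked = 0L, n_per_group = 6L,
                                mean_range = c(10, 200), dispersion = 0.1,
                                fold = 8, seed = 1L) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  m <- n_null + n_spiked
  mu <- exp(stats::runif(m, log(mean_range[1]), log(mean_range[2])))
  is_spiked <- c(rep(FALSE, n_null), rep(TRUE, n_spiked))
  muA <- mu
  muB <- mu * ifelse(is_spiked, fold, 1)
  size <- 1 / dispersion
  counts <- cbind(
    matrix(stats::rnbinom(m * n_per_group, mu = rep(muA, n_per_group),
                          size = size), m, n_per_group),
    matrix(stats::rnbinom(m * n_per_group, mu = rep(muB, n_per_group),
                          size = size), m, n_per_group))
  colnames(counts) <- c(sprintf("A%d", seq_len(n_per_group)),
                        sprintf("B%d", seq_len(n_per_group)))
  list(counts = counts,
       groups = rep(c("A", "B"), each = n_per_group),
       is_spiked = is_spiked)
}
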