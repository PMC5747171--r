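# small deterministic reference shared by the alignment tests
make_tiny_ref <- function(seed = 71) {
  set.seed(seed)
  env <- new.env()
  env$genome <- rand_dna(6000)
  # one 6-copy tandem repeat of a 66-mer at 4000
  unit <- rand_dna(66)
  substr(env$genome, 4000, 4000 + 66 * 6 - 1) <- strrep(unit, 6)
  env$unit <- unit
  env$fa <- write_fasta(list(chr1 = env$genome), tempfile(fileext = ".fa"))
  env$gidx <- index_genome(env$fa)
  env
}
tiny <- make_tiny_ref()

test_that("adapter screening discards contigs sharing a 15-mer with an adapter", {
  ad <- toupper(as.character(Biostrings::readDNAStringSet(
    system.file("extdata", "adapters.fa", package = "kmerDE"))))[1]
  set.seed(61)
  with_adapter <- paste0(rand_dna(20), substr(ad, 1, 20), rand_dna(20))
  clean <- rand_dna(60)
  res <- adapter_screen(c(with_adapter, clean))
  expect_equal(res$discarded, with_adapter)
  expect_equal(res$kept, clean)
  # verify by enumeration that the kept contig shares no adapter 15-mer
  all_ad <- toupper(as.character(Biostrings::readDNAStringSet(
    system.file("extdata", "adapters.fa", package = "kmerDE"))))
  words <- unlist(lapply(c(all_ad, revcomp(all_ad)), function(s)
    substring(s, 1:(nchar(s) - 14), 15:nchar(s))))
  contig_words <- substring(clean, 1:(60 - 14), 15:60)
  expect_length(intersect(contig_words, words), 0L)
  expect_equal(adapter_screen(character(0)),
               list(kept = character(0), discarded = character(0)))
})

test_that("a verbatim genome contig aligns perfectly at the right coordinates", {
  ctg <- c(perfect = substr(tiny$genome, 1500, 1580))
  aln <- align_builtin(ctg, tiny$gidx)
  expect_true(aln$is_mapped)
  expect_equal(aln$chrom, "chr1")
  expect_equal(aln$start, 1499L)           # 0-based half-open
  expect_equal(aln$end, 1580L)
  expect_equal(aln$strand, "+")
  expect_equal(aln$nb_hits, 1L)
  expect_equal(aln$nb_mismatches, 0L)
  expect_equal(aln$clipped_5p + aln$clipped_3p, 0L)
  # reverse-complement maps to the minus strand at the same locus
  aln2 <- align_builtin(c(rc = revcomp(unname(ctg))), tiny$gidx)
  expect_equal(aln2$strand, "-")
  expect_equal(aln2$start, 1499L)
})

test_that("mismatches are counted and poly(A) tails are soft-clipped in contig orientation", {
  ctg <- substr(tiny$genome, 2000, 2080)
  substr(ctg, 40, 40) <- setdiff(c("A", "C", "G", "T"),
                                 substr(ctg, 40, 40))[1]
  aln <- align_builtin(c(mm = ctg), tiny$gidx)
  expect_equal(aln$nb_mismatches, 1L)
  expect_equal(aln$nb_hits, 1L)
  tailed <- paste0(substr(tiny$genome, 2500, 2544), strrep("A", 20))
  aln2 <- align_builtin(c(pa = tailed), tiny$gidx)
  expect_true(aln2$is_mapped)
  expect_gte(aln2$clipped_3p, 18L)   # tail may borrow a genomic A or two
  expect_equal(aln2$clipped_5p, 0L)
  # same tail on the minus strand still clips at the contig's 3' end
  aln3 <- align_builtin(c(par = paste0(revcomp(substr(tiny$genome, 2500,
                                                      2544)),
                                       strrep("A", 20))), tiny$gidx)
  expect_equal(aln3$strand, "-")
  expect_gte(aln3$clipped_3p, 18L)
})

test_that("spiked GT-AG junctions are detected as single splice gaps", {
  left <- substr(tiny$genome, 1000, 1030)
  right <- substr(tiny$genome, 1231, 1261)
  g2 <- tiny$genome
  substr(g2, 1031, 1032) <- "GT"; substr(g2, 1229, 1230) <- "AG"
  fa <- write_fasta(list(chr1 = g2), tempfile(fileext = ".fa"))
  gidx <- index_genome(fa)
  ctg <- paste0(substr(g2, 1000, 1030), substr(g2, 1231, 1261))
  aln <- align_builtin(c(j = ctg), gidx)
  expect_true(aln$is_mapped)
  expect_equal(aln$nb_junctions, 1L)
  expect_equal(aln$start, 999L)
  expect_equal(aln$end, 1261L)             # span includes the gap
  expect_equal(aln$nb_mismatches, 0L)
})

test_that("repeat contigs report all co-optimal hits (brute-force oracle)", {
  arr_start <- 4000L
  ctg <- substr(tiny$genome, arr_start + 3, arr_start + 3 + 99)
  aln <- align_builtin(c(rep = ctg), tiny$gidx)
  # brute-force full scan of the genome for <=0-mismatch occurrences
  hits <- 0L
  for (p in 1:(nchar(tiny$genome) - nchar(ctg) + 1)) {
    if (substr(tiny$genome, p, p + nchar(ctg) - 1) == ctg) hits <- hits + 1L
  }
  expect_gte(hits, 5L)
  expect_equal(aln$nb_hits, hits)
})

test_that("foreign sequence and too-short contigs are unmapped", {
  set.seed(67)
  aln <- align_builtin(c(x = rand_dna(120)), tiny$gidx)
  expect_false(aln$is_mapped)
  expect_equal(aln$nb_hits, 0L)
  short <- align_builtin(c(s = "ACGTACGT"), tiny$gidx)  # below seed length
  expect_false(short$is_mapped)
})

# --- annotation ---

tiny_gff <- function() {
  path <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t101\t700\t.\t+\t.\tID=G1",
    "chr1\ttest\tmRNA\t101\t700\t.\t+\t.\tID=G1.t1;Parent=G1",
    "chr1\ttest\texon\t101\t200\t.\t+\t.\tID=G1.t1.e1;Parent=G1.t1",
    "chr1\ttest\texon\t601\t700\t.\t+\t.\tID=G1.t1.e2;Parent=G1.t1"),
    path)
  path
}

fake_aln <- function(start, end, strand = "+", mapped = TRUE, mm = 0L,
                     clip3 = 0L, contig = strrep("C", 50)) {
  data.table::data.table(
    contig_id = "c1", contig = contig, chrom = "chr1",
    start = start, end = end, strand = strand, nb_hits = 1L,
    nb_junctions = 0L, nb_mismatches = mm, nb_indels = 0L,
    clipped_5p = 0L, clipped_3p = clip3, is_mapped = mapped)
}

test_that("sense, intronic and antisense overlaps are annotated correctly", {
  gff <- tiny_gff()
  exonic <- annotate_contigs(fake_aln(110L, 160L), gff)
  expect_equal(exonic$gene_id, "G1")
  expect_true(exonic$is_exonic)
  expect_false(exonic$is_antisense)
  intronic <- annotate_contigs(fake_aln(300L, 400L), gff)
  expect_equal(intronic$gene_id, "G1")
  expect_true(intronic$is_intronic)
  expect_false(intronic$is_exonic)
  anti <- annotate_contigs(fake_aln(110L, 160L, strand = "-"), gff)
  expect_true(anti$is_antisense)
  expect_equal(anti$gene_id, "G1")
  inter <- annotate_contigs(fake_aln(2000L, 2100L), gff)
  expect_true(is.na(inter$gene_id))
  unm <- annotate_contigs(fake_aln(NA_integer_, NA_integer_,
                                   strand = NA_character_, mapped = FALSE),
                          gff)
  expect_true(is.na(unm$gene_id))
  expect_false(unm$is_exonic || unm$is_intronic || unm$is_antisense)
})

test_that("unstranded mode sets gene on either strand and never calls antisense", {
  gff <- tiny_gff()
  res <- annotate_contigs(fake_aln(110L, 160L, strand = "-"), gff,
                          stranded = FALSE)
  expect_equal(res$gene_id, "G1")
  expect_false(res$is_antisense)
})

test_that("poly(A) flag requires a clipped tail of at least 5 trailing A", {
  gff <- tiny_gff()
  tail_ok <- annotate_contigs(
    fake_aln(110L, 150L, clip3 = 8L,
             contig = paste0(strrep("C", 42), strrep("A", 8))), gff)
  expect_true(tail_ok$ends_polyA)
  short_clip <- annotate_contigs(
    fake_aln(110L, 150L, clip3 = 3L,
             contig = paste0(strrep("C", 42), strrep("A", 8))), gff)
  expect_false(short_clip$ends_polyA)
  not_a <- annotate_contigs(
    fake_aln(110L, 150L, clip3 = 8L,
             contig = paste0(strrep("C", 42), "AAAAAGGG")), gff)
  expect_false(not_a$ends_polyA)
})

test_that("BED output uses 0-based half-open intervals and omits unmapped contigs", {
  gff <- tiny_gff()
  aln <- rbind(fake_aln(100L, 200L),
               fake_aln(NA_integer_, NA_integer_, strand = NA_character_,
                        mapped = FALSE))
  aln$contig_id <- c("c1", "c2")
  ann <- annotate_contigs(aln, gff)
  ann$padj <- c(0.01, 0.02)
  bed <- tempfile(fileext = ".bed")
  emit_bed(ann, bed)
  lines <- readLines(bed)
  expect_length(lines, 1L)
  f <- strsplit(lines, "\t")[[1]]
  expect_equal(f[1:4], c("chr1", "100", "200", "c1"))
  expect_equal(f[5], "20")                 # -10*log10(0.01)
  # a 1-based GFF gene at 101-200 corresponds to BED 100-200: re-intersect
  g <- read_annotation(gff)
  bed_gr <- GenomicRanges::GRanges("chr1",
                                   IRanges::IRanges(as.integer(f[2]) + 1L,
                                                    as.integer(f[3])))
  ov <- GenomicRanges::findOverlaps(bed_gr, g$genes, ignore.strand = TRUE)
  expect_equal(g$genes$gene_id[S4Vectors::subjectHits(ov)], "G1")
})

test_that("SAM ingestion reconstructs junctions, clips and hit counts", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6",
    "@SQ\tSN:chr1\tLN:6000",
    paste("c1", 0, "chr1", 1001, 60, "20M200N20M", "*", 0, 0,
          strrep("A", 40), "*", "NM:i:1", "NH:i:1", sep = "\t"),
    paste("c2", 16, "chr1", 2001, 60, "5S30M", "*", 0, 0,
          strrep("A", 35), "*", "NM:i:0", "NH:i:2", sep = "\t")),
    sam)
  contigs <- c(c1 = strrep("A", 40), c2 = strrep("A", 35), c3 = "ACGTACGT")
  aln <- read_sam_alignments(sam, contigs)
  expect_equal(aln$nb_junctions, c(1L, 0L, 0L))
  expect_equal(aln$start[1], 1000L)
  expect_equal(aln$end[1], 1000L + 20L + 200L + 20L)
  expect_equal(aln$nb_mismatches[1], 1L)
  # reverse-strand record: 5' soft clip in read coords is the contig 3' end
  expect_equal(aln$clipped_3p[2], 5L)
  expect_equal(aln$nb_hits[2], 2L)
  expect_false(aln$is_mapped[3])
})
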