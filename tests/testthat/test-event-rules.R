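# build a minimal annotation row with classifier-relevant fields
ann_row <- function(du = NA_real_, junctions = 0L, gene = NA_character_,
                    antisense = FALSE, clip3 = 0L, polyA = FALSE,
                    mapped = TRUE, snv = FALSE, exonic = FALSE,
                    intronic = FALSE, hits = 1L, len = 100L,
                    region = 1000L, meanA = 50, meanB = 50,
                    gene_de = NA) {
  data.table::data.table(
    contig_id = "c", contig = strrep("A", len), chrom = "chr1",
    start = 0L, end = region, strand = "+", nb_hits = hits,
    nb_junctions = junctions, nb_mismatches = 0L, nb_indels = 0L,
    clipped_5p = 0L, clipped_3p = clip3, is_mapped = mapped,
    gene_id = gene, is_antisense = antisense, is_exonic = exonic,
    is_intronic = intronic, snv = snv, ends_polyA = polyA,
    contig_length = len, mapped_region = if (mapped) region else NA_integer_,
    du_pvalue = du, gene_is_de = gene_de, meanA = meanA, meanB = meanB)
}

test_that("classifier reproduces the event rule table row by row", {
  cls <- function(row) classify_contigs(row)$class
  expect_equal(cls(ann_row(du = 0.5, junctions = 2L, gene = "G")),
               "splicing")
  expect_equal(cls(ann_row(du = 0.001, junctions = 1L, gene = "G")),
               "splicing_DU")
  expect_equal(cls(ann_row(du = 0.001, clip3 = 8L, polyA = TRUE)),
               "polyA_DU")
  expect_equal(cls(ann_row(du = 0.5, clip3 = 8L, polyA = TRUE)), "polyA")
  expect_equal(cls(ann_row(len = 250L, region = 2000L, meanB = 30)),
               "lincRNA")
  expect_equal(cls(ann_row(len = 150L, region = 2000L, meanB = 30)),
               "unclassified")            # too short for lincRNA
  expect_equal(cls(ann_row(len = 250L, region = 2000L, meanA = 5,
                           meanB = 5)),
               "unclassified")            # not expressed enough
  expect_equal(cls(ann_row(gene = "G", antisense = TRUE, len = 250L,
                           region = 2000L)),
               "asRNA")
  expect_equal(cls(ann_row(du = 0.001, gene = "G", snv = TRUE,
                           exonic = TRUE, gene_de = FALSE)), "SNV_DU")
  expect_equal(cls(ann_row(du = 0.001, gene = "G", snv = TRUE,
                           exonic = TRUE, gene_de = TRUE)),
               "unclassified")            # DE host gene blocks the SNV call
  expect_equal(cls(ann_row(du = 0.001, gene = "G", intronic = TRUE)),
               "intron_DU")
  expect_equal(cls(ann_row(du = 0.5, gene = "G", intronic = TRUE)),
               "intron")
  expect_equal(cls(ann_row(hits = 6L, len = 96L)), "repeats")
  expect_equal(cls(ann_row(mapped = FALSE, len = 289L)), "unmapped")
  expect_equal(cls(ann_row(mapped = FALSE, len = 40L)), "unclassified")
})

test_that("DU classes are unreachable when the DU p-value is undefined", {
  row <- ann_row(du = NA_real_, junctions = 1L, gene = "G")
  expect_equal(classify_contigs(row)$class, "splicing")
  row2 <- ann_row(du = NA_real_, gene = "G", snv = TRUE, exonic = TRUE,
                  gene_de = FALSE)
  expect_equal(classify_contigs(row2)$class, "unclassified")
})

test_that("classification is deterministic and multi-junction contigs stay splicing", {
  rows <- rbind(ann_row(du = 0.001, junctions = 1L, gene = "G"),
                ann_row(hits = 6L, len = 96L))
  c1 <- classify_contigs(rows)$class
  c2 <- classify_contigs(rows)$class
  expect_identical(c1, c2)
})

test_that("du_test is invariant to joint scaling and flags usage shifts", {
  nf <- rep(1, 12)
  groups <- rep(c("A", "B"), each = 6)
  gene <- c(rep(100, 6), rep(400, 6))
  # contig tracking the gene exactly: ratio constant -> p = 1
  contig <- (gene + 1) * 4 - 1
  expect_equal(du_test(contig, gene, nf, groups), 1)
  # contig present only in B of a flat gene: strong usage shift
  set.seed(73)
  gene2 <- rep(100, 12) + rnorm(12, 0, 5)
  contig2 <- c(rpois(6, 2), rpois(6, 150))
  expect_lt(du_test(contig2, gene2, nf, groups), 0.01)
  expect_true(is.na(du_test(contig2, rep(NA_real_, 12), nf, groups)))
})

test_that("gene expression from unique k-mers recovers an 8-fold gene spike", {
  # small reference; build the k-mer matrix directly from the transcripts
  # with gene G01 spiked 8-fold in condition B and all other genes flat
  cfg <- sim_config(seed = 881L, n_genes = 9L, genome_length = 40000L,
                    spikes = NULL)
  ref <- make_reference(cfg, file.path(tempdir(), "ge_ref"))
  params <- kmer_params(k = 31, min_abundance = 1)
  km_by_gene <- lapply(names(ref$transcripts), function(nm) {
    s <- ref$transcripts[[nm]]
    substring(s, 1:(nchar(s) - 30), 31:nchar(s))
  })
  names(km_by_gene) <- sub("\\.t1$", "", names(ref$transcripts))
  km <- unlist(km_by_gene, use.names = FALSE)
  gene_of <- rep(names(km_by_gene), lengths(km_by_gene))
  keep <- !duplicated(km)
  km <- km[keep]; gene_of <- gene_of[keep]
  o <- order(km, method = "radix")
  km <- km[o]; gene_of <- gene_of[o]
  set.seed(883)
  n <- 12L
  mu <- lapply(gene_of, function(g)
    if (g == "G01") c(rep(50, 6), rep(400, 6)) else rep(50, n))
  counts <- t(vapply(mu, function(m)
    rnbinom(n, mu = m, size = 10), numeric(n)))
  storage.mode(counts) <- "integer"
  samples <- data.frame(library_id = c(sprintf("A%d", 1:6),
                                       sprintf("B%d", 1:6)),
                        condition = rep(c("A", "B"), each = 6))
  mat <- kmer_count_matrix(km, counts, samples)
  nf <- rep(1, n)
  names(nf) <- samples$library_id
  ge <- gene_expression(mat, ref$transcriptome_fasta, ref$gff3, nf, params)
  expect_true(ge$de[ge$de$gene_id == "G01"]$is_de)      # 8-fold spike found
  flat <- ge$de[ge$de$gene_id != "G01" & !is.na(ge$de$is_de), ]
  expect_gt(nrow(flat), 4)
  expect_lt(mean(flat$is_de), 0.2)                      # flat genes stay flat
  # expression rows are normalized means over gene-unique k-mers
  expect_equal(rownames(ge$expr), sort(unique(ge$de$gene_id)))
})

test_that("the SNV host gene with flat total expression is not called DE", {
  study <- default_study()
  host_snv <- study$sim$truth[study$sim$truth$event == "SNV"]$host_gene
  expect_false(study$res$gene_de[
    study$res$gene_de$gene_id == host_snv]$is_de)
})

test_that("loci separate sense, antisense and intergenic contigs", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tt\tgene\t101\t700\t.\t+\t.\tID=GA",
    "chr1\tt\tmRNA\t101\t700\t.\t+\t.\tID=GA.t1;Parent=GA",
    "chr1\tt\texon\t101\t700\t.\t+\t.\tID=GA.t1.e1;Parent=GA.t1",
    "chr1\tt\tgene\t2001\t2600\t.\t-\t.\tID=GB",
    "chr1\tt\tmRNA\t2001\t2600\t.\t-\t.\tID=GB.t1;Parent=GB",
    "chr1\tt\texon\t2001\t2600\t.\t-\t.\tID=GB.t1.e1;Parent=GB.t1"),
    gff)
  rows <- rbind(
    ann_row(gene = "GA"), ann_row(gene = "GA"), ann_row(gene = "GA"),
    ann_row(gene = "GA", antisense = TRUE),
    ann_row(),                          # intergenic (no gene)
    ann_row(mapped = FALSE, len = 80L))
  rows$contig_id <- paste0("c", 1:6)
  rows$padj <- c(0.04, 0.01, 0.02, 0.01, 0.01, 0.01)
  rows$start <- c(rep(150L, 4), 1000L, NA)
  rows$end <- c(rep(250L, 4), 1100L, NA)
  cl <- classify_contigs(rows)
  loci <- group_loci(cl, gff)
  expect_equal(loci[loci$locus_id == "GA"]$n_contigs, 3L)
  expect_equal(loci[loci$locus_id == "GA"]$best_contig, "c2")
  expect_equal(loci[loci$locus_id == "as:GA"]$n_contigs, 1L)
  expect_equal(loci[loci$locus_id == "GA|GB"]$n_contigs, 1L)
  expect_equal(loci[loci$locus_id == "unmapped"]$n_contigs, 1L)
  expect_equal(sum(loci$n_contigs), nrow(rows))
})
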