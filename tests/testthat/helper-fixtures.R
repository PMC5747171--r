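# shared fixtures: built in code at test time, cached across test files

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

write_fastq <- function(seqs, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  if (length(seqs)) {
    lines <- rbind(sprintf("@r%04d", seq_along(seqs)), seqs, "+",
                   strrep("I", nchar(seqs)))
    writeLines(as.vector(lines), con)
  }
  path
}

write_fasta <- function(seqs, path) {
  con <- file(path, "wb"); on.exit(close(con))
  for (nm in names(seqs)) writeLines(c(paste0(">", nm), seqs[[nm]]), con)
  path
}

# brute-force window counter: the independent oracle for k-mer counting
oracle_count <- function(reads, k, min_abundance = 1L, canonical = FALSE) {
  wins <- unlist(lapply(reads, function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    w <- substring(s, 1:(L - k + 1), k:L)
    w[!grepl("[^ACGT]", w)]
  }))
  if (canonical && length(wins)) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(wins)))
    wins <- pmin(wins, rc)
  }
  tab <- table(wins)
  tab <- tab[tab >= min_abundance]
  cnt <- as.integer(tab)
  names(cnt) <- names(tab)
  cnt[order(names(cnt), method = "radix")]
}

# one full synthetic study + pipeline run, computed once per test session
.study_cache <- new.env(parent = emptyenv())
default_study <- function(method = "ttest") {
  key <- paste0("study_", method)
  if (!is.null(.study_cache[[key]])) return(.study_cache[[key]])
  root <- file.path(tempdir(), paste0("kmerde_study_", method))
  cfg <- sim_config(seed = 101L)
  ref <- make_reference(cfg, file.path(root, "ref"))
  sim <- spike_and_simulate(cfg, ref, file.path(root, "reads"))
  pc <- pipeline_config(samples = sim$samples,
                        genome_fasta = ref$genome_fasta, gff3 = ref$gff3,
                        masking = ref$transcriptome_fasta,
                        output_dir = file.path(root, "out"),
                        diff_method = method, seed = 7L)
  res <- suppressWarnings(run_pipeline(pc))
  out <- list(cfg = cfg, ref = ref, sim = sim, pc = pc, res = res)
  .study_cache[[key]] <- out
  out
}

# expected parent class per spiked event (DU variants share a parent)
parent_class <- function(cls) {
  sub("_DU$", "", cls)
}
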