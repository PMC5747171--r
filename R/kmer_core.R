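#' @import data.table
#' @importFrom stats median p.adjust pnorm pt rbinom rnbinom runif setNames
#' @importFrom utils head tail write.table
NULL

#' k-mer extraction parameters
#'
#' Bundle of the parameters governing k-mer decomposition of a sequencing
#' library: the word length `k`, how strand is handled, and the minimum
#' per-library abundance for a k-mer to be recorded at all.
#'
#' @param k Integer k-mer length in nucleotides. Must satisfy 15 < k <= 63.
#'   The pipeline default is 31.
#' @param strand_mode Either `"stranded"` (reads in the reverse orientation
#'   relative to the transcript are reverse-complemented before windowing, so
#'   k-mers keep transcript orientation) or `"unstranded"` (every k-mer is
#'   replaced by its canonical form).
#' @param min_abundance Minimum number of occurrences in a library for a
#'   k-mer to be recorded; the default 2 drops most singleton sequencing
#'   errors.
#' @return An object of class `kmer_params`.
#' @export
kmer_params <- function(k = 31L, strand_mode = c("stranded", "unstranded"),
                        min_abundance = 2L) {
  strand_mode <- match.arg(strand_mode)
  k <- as.integer(k)
  min_abundance <- as.integer(min_abundance)
  if (is.na(k) || k <= 15L || k > 63L)
    stop("k must satisfy 15 < k <= 63 (got ", k, ")", call. = FALSE)
  if (is.na(min_abundance) || min_abundance < 1L)
    stop("min_abundance must be >= 1", call. = FALSE)
  structure(list(k = k, strand_mode = strand_mode,
                 min_abundance = min_abundance),
            class = "kmer_params")
}

# internal: relaxed constructor used by unit-scale examples (k >= 2)
.kmer_params_unchecked <- function(k, strand_mode = "stranded",
                                   min_abundance = 1L) {
  structure(list(k = as.integer(k), strand_mode = strand_mode,
                 min_abundance = as.integer(min_abundance)),
            class = "kmer_params")
}

.check_dna <- function(x) {
  bad <- grepl("[^ACGT]", x)
  if (any(bad))
    stop("invalid sequence: non-ACGT character in ",
         paste(utils::head(x[bad], 3), collapse = ", "), call. = FALSE)
  invisible(x)
}

#' Reverse-complement DNA strings
#'
#' Vectorized reverse complement of uppercase ACGTN strings.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Canonical form of a k-mer
#'
#' The canonical form is the lexicographically smaller of a k-mer and its
#' reverse complement; unstranded counting stores only canonical k-mers so
#' that a sequence and its reverse complement are counted as one species.
#'
#' @param kmer Character vector of uppercase ACGT k-mers.
#' @return Character vector of canonical k-mers.
#' @export
canonical <- function(kmer) {
  if (length(kmer) == 0L) return(character(0))
  .check_dna(kmer)
  rc <- revcomp(kmer)
  ifelse(kmer <= rc, kmer, rc)
}

# Window one or more reads into k-mers. Returns a character vector; windows
# containing a non-ACGT base (e.g. N) are dropped, so a read of length L
# yields L - k + 1 k-mers only when it is N-free.
.window_kmers <- function(seqs, k) {
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  keep <- lens >= k
  if (!any(keep)) return(character(0))
  seqs <- seqs[keep]
  lens <- lens[keep]
  out <- vector("list", length(seqs))
  for (L in unique(lens)) {
    idx <- which(lens == L)
    n_win <- L - k + 1L
    # matrix of windows: one substring() call per offset, vectorized over reads
    wins <- vapply(seq_len(n_win),
                   function(i) substring(seqs[idx], i, i + k - 1L),
                   character(length(idx)))
    if (length(idx) == 1L) wins <- matrix(wins, nrow = 1L)
    for (j in seq_along(idx)) out[[idx[j]]] <- wins[j, ]
  }
  km <- unlist(out, use.names = FALSE)
  km[!grepl("[^ACGT]", km)]
}

#' Extract k-mers from a read
#'
#' Slides a window of length `k` across a read. In stranded mode a read
#' sequenced in the reverse orientation relative to the transcript is
#' reverse-complemented first, so all k-mers carry transcript orientation;
#' in unstranded mode every window is canonicalized. Windows overlapping a
#' non-ACGT base (such as N) are skipped entirely.
#'
#' @param read_sequence A single DNA string (may contain N).
#' @param params A [kmer_params()] object.
#' @param read_orientation `"forward"` or `"reverse"`, the orientation of the
#'   read relative to the transcript (only consulted in stranded mode).
#' @return Character vector of k-mers in window order (empty for short reads).
#' @export
extract_kmers <- function(read_sequence, params,
                          read_orientation = c("forward", "reverse")) {
  read_orientation <- match.arg(read_orientation)
  stopifnot(length(read_sequence) == 1L)
  seq <- toupper(read_sequence)
  if (params$strand_mode == "stranded" && read_orientation == "reverse")
    seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  km <- .window_kmers(seq, params$k)
  if (params$strand_mode == "unstranded" && length(km)) km <- canonical(km)
  km
}

# read a FASTQ (possibly gzipped) into a character vector of read sequences
.read_fastq_seqs <- function(path) {
  out <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq"),
    error = function(e)
      stop("malformed FASTQ in '", path, "': ", conditionMessage(e),
           call. = FALSE))
  as.character(out)
}

#' Count k-mers in a sequencing library
#'
#' Decomposes one library (one or more FASTQ files, e.g. two mates) into
#' k-mers and tallies their occurrences, keeping only k-mers seen at least
#' `params$min_abundance` times in the whole library. The result does not
#' depend on read order.
#'
#' @param fastq_paths Character vector of FASTQ / FASTQ.gz paths.
#' @param params A [kmer_params()] object.
#' @param mate_orientations Orientation of each file's reads relative to the
#'   transcript, `"forward"` or `"reverse"`, recycled along `fastq_paths`.
#'   The usual stranded paired-end convention is mate 1 forward, mate 2
#'   reverse.
#' @param library_id Library identifier stored in the result; defaults to the
#'   basename of the first file.
#' @return A `kmer_count_table`: list with `library_id`, `params`, and
#'   `counts`, a `data.table` with columns `kmer` and `count` sorted in
#'   C-locale lexicographic k-mer order.
#' @export
count_library <- function(fastq_paths, params,
                          mate_orientations = "forward",
                          library_id = NULL) {
  mate_orientations <- rep_len(mate_orientations, length(fastq_paths))
  if (is.null(library_id))
    library_id <- sub("\\.(fastq|fq)(\\.gz)?$", "", basename(fastq_paths[1]))
  all_km <- vector("list", length(fastq_paths))
  for (i in seq_along(fastq_paths)) {
    seqs <- .read_fastq_seqs(fastq_paths[i])
    if (params$strand_mode == "stranded" && mate_orientations[i] == "reverse")
      seqs <- revcomp(toupper(seqs))
    km <- .window_kmers(seqs, params$k)
    if (params$strand_mode == "unstranded" && length(km)) {
      rc <- revcomp(km)
      km <- ifelse(km <= rc, km, rc)
    }
    all_km[[i]] <- km
  }
  km <- unlist(all_km, use.names = FALSE)
  kmer <- count <- NULL # data.table NSE
  if (length(km)) {
    dt <- data.table(kmer = km)[, .(count = .N), by = kmer]
    dt <- dt[count >= params$min_abundance]
    setorderv(dt, "kmer")              # radix sort: C-locale order
  } else {
    dt <- data.table(kmer = character(0), count = integer(0))
  }
  structure(list(library_id = library_id, params = params, counts = dt),
            class = "kmer_count_table")
}

#' @export
print.kmer_count_table <- function(x, ...) {
  cat("k-mer count table for library '", x$library_id, "': ",
      nrow(x$counts), " k-mers (k=", x$params$k, ", ",
      x$params$strand_mode, ", min_abundance=", x$params$min_abundance,
      ")\n", sep = "")
  invisible(x)
}

#' Write a sorted two-column k-mer dump
#'
#' Writes `kmer<TAB>count` lines in strictly increasing lexicographic k-mer
#' order (the on-disk interchange format between the counting and joining
#' stages). Round-trips losslessly through [read_kmer_dump()].
#'
#' @param table A `kmer_count_table` from [count_library()].
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
dump_sorted <- function(table, path) {
  dt <- table$counts
  stopifnot(is.data.frame(dt))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  if (nrow(dt)) {
    o <- order(dt$kmer, method = "radix")
    writeLines(paste0(dt$kmer[o], "\t", dt$count[o]), con)
  }
  invisible(path)
}

#' Read a two-column k-mer dump
#'
#' @param path Path written by [dump_sorted()] (optionally gzipped).
#' @param library_id Library id to attach; defaults to the file basename.
#' @return A `data.table` with columns `kmer`, `count`.
#' @export
read_kmer_dump <- function(path, library_id = NULL) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (!length(lines))
    return(data.table(kmer = character(0), count = integer(0)))
  parts <- tstrsplit(lines, "\t", fixed = TRUE)
  if (length(parts) != 2L)
    stop("malformed k-mer dump: ", path, call. = FALSE)
  data.table(kmer = parts[[1]], count = as.integer(parts[[2]]))
}
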