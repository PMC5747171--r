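#' Construct a k-mer count matrix object
#'
#' @param kmers Character vector of k-mer strings (row names), in strictly
#'   increasing lexicographic order.
#' @param counts Integer matrix, one row per k-mer, one column per sample.
#' @param samples `data.frame` with columns `library_id` and `condition`
#'   (two levels, "A"/"B" by convention), one row per matrix column.
#' @return A `kmer_count_matrix` object.
#' @export
kmer_count_matrix <- function(kmers, counts, samples) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  stopifnot(length(kmers) == nrow(counts),
            nrow(samples) == ncol(counts),
            all(c("library_id", "condition") %in% names(samples)))
  if (length(kmers) > 1L && is.unsorted(kmers, strictly = TRUE))
    stop("k-mer rows must be in strictly increasing lexicographic order",
         call. = FALSE)
  colnames(counts) <- samples$library_id
  rownames(counts) <- NULL
  structure(list(kmers = as.character(kmers), counts = counts,
                 samples = as.data.frame(samples)),
            class = "kmer_count_matrix")
}

#' @export
print.kmer_count_matrix <- function(x, ...) {
  tab <- table(x$samples$condition)
  cat("k-mer count matrix: ", length(x$kmers), " k-mers x ",
      ncol(x$counts), " samples (",
      paste(names(tab), tab, sep = "=", collapse = ", "), ")\n", sep = "")
  invisible(x)
}

# refill one merge source's line buffer (up to `block` lines); tracks the
# 1-based line number of the last line read for error reporting
.refill_source <- function(src, block) {
  if (src$eof) return(src)
  lines <- readLines(src$con, n = block)
  if (length(lines) < block) src$eof <- TRUE
  if (length(lines)) {
    parts <- tstrsplit(lines, "\t", fixed = TRUE)
    if (length(parts) != 2L || anyNA(parts[[2]] <- suppressWarnings(as.integer(parts[[2]]))))
      stop("malformed k-mer dump '", src$path, "' near line ",
           src$lineno + 1L, call. = FALSE)
    km <- parts[[1]]
    full <- c(src$last_kmer, km)
    if (length(full) > 1L) {
      cmp <- full[-length(full)] >= full[-1]
      if (any(cmp)) {
        bad <- which(cmp)[1]
        stop("unsorted k-mer dump '", src$path, "' at line ",
             src$lineno + bad - (length(full) - length(km)) + 1L,
             " ('", full[bad + 1L], "' after '", full[bad], "')",
             call. = FALSE)
      }
    }
    src$lineno <- src$lineno + length(lines)
    src$last_kmer <- km[length(km)]
    src$buf_kmer <- c(src$buf_kmer, km)
    src$buf_count <- c(src$buf_count, parts[[2]])
  }
  src
}

#' Join sorted per-library k-mer dumps into a count matrix
#'
#' Performs a streaming k-way merge of lexicographically sorted two-column
#' dumps (as written by [dump_sorted()]): the union of all k-mers becomes the
#' row set, with absent entries filled with 0. Files are consumed in bounded
#' blocks, so memory scales with the block size times the number of open
#' files, not with the total number of k-mers. Unsorted input is detected and
#' reported with the offending file and line.
#'
#' @param paths Character vector of dump paths, one per sample.
#' @param samples `data.frame` with `library_id` and `condition`, parallel to
#'   `paths`.
#' @param block Number of lines read per file per refill.
#' @return A [kmer_count_matrix()].
#' @export
join_counts <- function(paths, samples, block = 50000L) {
  stopifnot(length(paths) == nrow(samples))
  ns <- length(paths)
  srcs <- vector("list", ns)
  for (i in seq_len(ns)) {
    con <- if (grepl("\\.gz$", paths[i])) gzfile(paths[i], "rt")
           else file(paths[i], "rt")
    srcs[[i]] <- new.env(parent = emptyenv())
    srcs[[i]]$con <- con; srcs[[i]]$path <- paths[i]
    srcs[[i]]$eof <- FALSE; srcs[[i]]$lineno <- 0L
    srcs[[i]]$last_kmer <- character(0)
    srcs[[i]]$buf_kmer <- character(0); srcs[[i]]$buf_count <- integer(0)
  }
  on.exit(for (s in srcs) try(close(s$con), silent = TRUE))

  kmer <- NULL # data.table NSE
  chunks <- list()
  repeat {
    for (s in srcs) if (!s$eof && !length(s$buf_kmer)) .refill_source(s, block)
    active <- Filter(function(s) length(s$buf_kmer) > 0L, srcs)
    if (!length(active)) break
    # safe emission bound: min over non-exhausted sources of their buffered
    # tail k-mer; everything <= bound is complete across all sources
    sentinel <- strrep("Z", 100L)  # sorts after any ACGT k-mer
    tails <- vapply(active, function(s)
      if (s$eof) sentinel else s$buf_kmer[length(s$buf_kmer)], character(1))
    bound <- min(tails)
    pieces <- list()
    for (i in seq_len(ns)) {
      s <- srcs[[i]]
      if (!length(s$buf_kmer)) next
      take <- s$buf_kmer <= bound
      n_take <- sum(take)
      if (!n_take) next
      pieces[[length(pieces) + 1L]] <-
        data.table(kmer = s$buf_kmer[seq_len(n_take)],
                   count = s$buf_count[seq_len(n_take)], sample = i)
      s$buf_kmer <- s$buf_kmer[-seq_len(n_take)]
      s$buf_count <- s$buf_count[-seq_len(n_take)]
    }
    long <- rbindlist(pieces)
    wide <- dcast(long, kmer ~ sample, value.var = "count", fill = 0L)
    miss <- setdiff(as.character(seq_len(ns)), names(wide))
    for (m in miss) wide[, (m) := 0L]
    setcolorder(wide, c("kmer", as.character(seq_len(ns))))
    setorderv(wide, "kmer")
    chunks[[length(chunks) + 1L]] <- wide
  }
  if (length(chunks)) {
    full <- rbindlist(chunks)
    kmers <- full$kmer
    counts <- as.matrix(full[, -1, with = FALSE])
  } else {
    kmers <- character(0)
    counts <- matrix(integer(0), 0, ns)
  }
  kmer_count_matrix(kmers, counts, samples)
}

#' Recurrence of a k-mer count vector
#'
#' The recurrence of a k-mer at abundance threshold `a` is the number of
#' samples in which it occurs strictly more than `a` times; it is the
#' statistic of the low-recurrence filter.
#'
#' @param row Integer vector (counts across samples) or matrix (rows =
#'   k-mers).
#' @param a Integer abundance threshold.
#' @return Integer recurrence (or vector of recurrences for a matrix).
#' @export
recurrence <- function(row, a) {
  if (is.matrix(row)) rowSums(row > a) else sum(row > a)
}

#' Filter a count matrix on k-mer recurrence
#'
#' Retains exactly the k-mers occurring more than `min_recurrence_abundance`
#' times in at least `min_recurrence` samples; row order is preserved. The
#' usual defaults are `min_recurrence` = number of replicates per condition
#' and `min_recurrence_abundance` = 5.
#'
#' @param matrix A [kmer_count_matrix()].
#' @param min_recurrence Minimum number of samples exceeding the abundance
#'   threshold.
#' @param min_recurrence_abundance Abundance threshold `a` (strict
#'   inequality: a count must exceed, not equal, `a`).
#' @return Filtered [kmer_count_matrix()].
#' @export
recurrence_filter <- function(matrix, min_recurrence,
                              min_recurrence_abundance = 5L) {
  stopifnot(min_recurrence >= 1L, min_recurrence <= ncol(matrix$counts),
            min_recurrence_abundance >= 0L)
  keep <- recurrence(matrix$counts, min_recurrence_abundance) >= min_recurrence
  kmer_count_matrix(matrix$kmers[keep],
                    matrix$counts[keep, , drop = FALSE], matrix$samples)
}

#' Build a masking set from a reference transcriptome
#'
#' Extracts every k-mer of every FASTA record under the same parameters as
#' read counting. In stranded mode only the annotated (sense) strand is
#' indexed, so antisense k-mers survive masking; in unstranded mode k-mers
#' are canonicalized, which covers both strands.
#'
#' @param transcriptome_fasta Path to a FASTA file of reference transcripts.
#' @param params A [kmer_params()] object.
#' @return Character vector: the set of reference k-mers.
#' @export
build_mask <- function(transcriptome_fasta, params) {
  seqs <- as.character(Biostrings::readDNAStringSet(transcriptome_fasta))
  if (!length(seqs)) {
    warning("empty FASTA: ", transcriptome_fasta, "; mask is empty")
    return(character(0))
  }
  km <- .window_kmers(seqs, params$k)
  if (params$strand_mode == "unstranded" && length(km)) {
    rc <- revcomp(km)
    km <- ifelse(km <= rc, km, rc)
  }
  unique(km)
}

#' Subtract reference k-mers from a count matrix
#'
#' Removes every row whose k-mer occurs in the mask. Rows are removed, never
#' altered; an empty mask is the identity (masking can be bypassed wholesale).
#'
#' @param matrix A [kmer_count_matrix()].
#' @param mask Character vector from [build_mask()] (or `character(0)`).
#' @return Masked [kmer_count_matrix()].
#' @export
apply_mask <- function(matrix, mask) {
  if (!length(mask)) return(matrix)
  if (length(matrix$kmers) &&
      nchar(mask[1]) != nchar(matrix$kmers[1]))
    stop("mask k-mer length (", nchar(mask[1]),
         ") does not match matrix k-mer length (",
         nchar(matrix$kmers[1]), ")", call. = FALSE)
  keep <- !(matrix$kmers %chin% mask)
  kmer_count_matrix(matrix$kmers[keep],
                    matrix$counts[keep, , drop = FALSE], matrix$samples)
}

#' Write a count matrix as (gzipped) TSV
#'
#' Column 1 is `tag` (the k-mer), followed by one integer column per sample
#' named by library id.
#'
#' @param matrix A [kmer_count_matrix()].
#' @param path Output path; `.gz` triggers compression.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(matrix, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  header <- paste(c("tag", matrix$samples$library_id), collapse = "\t")
  writeLines(header, con)
  if (length(matrix$kmers)) {
    body <- do.call(paste, c(list(matrix$kmers),
                             lapply(seq_len(ncol(matrix$counts)),
                                    function(j) matrix$counts[, j]),
                             sep = "\t"))
    writeLines(body, con)
  }
  invisible(path)
}

#' Read a count matrix written by [write_count_matrix()]
#'
#' @param path TSV (optionally gzipped) path.
#' @param samples `data.frame` with `library_id` and `condition`; matched to
#'   the file header by library id.
#' @return A [kmer_count_matrix()].
#' @export
read_count_matrix <- function(path, samples) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  ids <- header[-1]
  stopifnot(setequal(ids, samples$library_id))
  samples <- samples[match(ids, samples$library_id), , drop = FALSE]
  if (length(lines) > 1L) {
    parts <- tstrsplit(lines[-1], "\t", fixed = TRUE)
    kmers <- parts[[1]]
    counts <- vapply(parts[-1], as.integer, integer(length(kmers)))
    if (length(kmers) == 1L) counts <- matrix(counts, nrow = 1L)
  } else {
    kmers <- character(0)
    counts <- matrix(integer(0), 0, length(ids))
  }
  kmer_count_matrix(kmers, counts, samples)
}
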