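#' Screen contigs against sequencing adapters
#'
#' A contig is discarded when it shares an exact match of at least
#' `word_size` nucleotides (default 15) with any adapter sequence, on either
#' strand. A small FASTA of common Illumina adapters ships with the package
#' (`system.file("extdata", "adapters.fa", package = "kmerDE")`).
#'
#' @param contigs Character vector of contig sequences.
#' @param adapter_fasta Path to an adapter FASTA (default: shipped file).
#' @param word_size Exact-match word size.
#' @return List with `kept` and `discarded` logical-indexed character
#'   vectors of contigs.
#' @export
adapter_screen <- function(contigs,
                           adapter_fasta = system.file("extdata",
                                                       "adapters.fa",
                                                       package = "kmerDE"),
                           word_size = 15L) {
  if (!length(contigs)) return(list(kept = character(0),
                                    discarded = character(0)))
  ad <- toupper(as.character(Biostrings::readDNAStringSet(adapter_fasta)))
  words <- unique(.window_kmers(c(ad, revcomp(ad)), word_size))
  hit <- vapply(contigs, function(s) {
    w <- .window_kmers(s, word_size)
    any(w %chin% words)
  }, logical(1), USE.NAMES = FALSE)
  list(kept = contigs[!hit], discarded = contigs[hit])
}

#' Index a genome for seed lookup
#'
#' Builds an exact-match seed index (default seed length 15) over the
#' forward strand of every chromosome, used by [align_builtin()].
#'
#' @param genome_fasta Path to the genome FASTA.
#' @param seed_len Seed length.
#' @return A `genome_index` object.
#' @export
index_genome <- function(genome_fasta, seed_len = 15L) {
  seqs <- toupper(as.character(Biostrings::readDNAStringSet(genome_fasta)))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seed <- chrom <- pos <- NULL # data.table NSE
  tabs <- lapply(names(seqs), function(ch) {
    s <- seqs[[ch]]
    L <- nchar(s)
    if (L < seed_len) return(NULL)
    p <- seq_len(L - seed_len + 1L)
    data.table(seed = substring(s, p, p + seed_len - 1L), chrom = ch, pos = p)
  })
  idx <- rbindlist(tabs)
  idx <- idx[!grepl("[^ACGT]", seed)]
  setkey(idx, seed)
  structure(list(seqs = seqs, seed_len = seed_len, index = idx),
            class = "genome_index")
}

# compare query to the genome window starting at `start` (1-based) on the
# forward strand of `chromseq`; returns logical match vector (TRUE = match),
# out-of-range positions are mismatches
.match_vector <- function(query, chromseq, start) {
  len <- nchar(query)
  L <- nchar(chromseq)
  lo <- max(1L, start); hi <- min(L, start + len - 1L)
  if (hi < lo) return(rep(FALSE, len))
  g <- substring(chromseq, lo, hi)
  qv <- strsplit(query, "", fixed = TRUE)[[1]]
  gv <- strsplit(g, "", fixed = TRUE)[[1]]
  m <- rep(FALSE, len)
  off <- lo - start
  m[(off + 1L):(off + length(gv))] <- qv[(off + 1L):(off + length(gv))] == gv
  m
}

# maximum-scoring local window (match +1, mismatch -4, Kadane), so terminal
# mismatch runs (e.g. poly(A) tails) are clipped rather than absorbed;
# rejected outright when its mismatch count exceeds max_mm.
# returns c(i, j, mism) or NULL
.best_window <- function(m, max_mm, mm_penalty = 4L) {
  v <- ifelse(m, 1L, -mm_penalty)
  best_sum <- 0L; best <- NULL
  cur <- 0L; cur_start <- 1L
  for (j in seq_along(v)) {
    if (cur + v[j] < v[j]) { cur <- v[j]; cur_start <- j }
    else cur <- cur + v[j]
    if (cur > best_sum) { best_sum <- cur; best <- c(cur_start, j) }
  }
  if (is.null(best)) return(NULL)
  i <- best[1]; j <- best[2]          # ends fall on matches by construction
  mm <- sum(!m[i:j])
  if (mm > max_mm) return(NULL)
  c(i, j, mm)
}

# candidate diagonals for a query: genome start positions implied by seed hits
.candidate_diagonals <- function(query, gidx, max_cand = 500L) {
  len <- nchar(query)
  sl <- gidx$seed_len
  if (len < sl) return(data.table(chrom = character(0), diag = integer(0)))
  offs <- unique(c(seq(1L, len - sl + 1L, by = max(1L, sl %/% 2)),
                   len - sl + 1L))
  seed <- chrom <- diag <- pos <- NULL # data.table NSE
  q <- data.table(seed = substring(query, offs, offs + sl - 1L), off = offs)
  hits <- gidx$index[q, on = "seed", nomatch = NULL, allow.cartesian = TRUE]
  if (!nrow(hits)) return(data.table(chrom = character(0), diag = integer(0)))
  hits[, diag := pos - off + 1L]
  out <- unique(hits[, .(chrom, diag)])
  if (nrow(out) > max_cand) out <- out[seq_len(max_cand)]
  out
}

# evaluate one ungapped candidate; returns a one-row data.table or NULL
.eval_ungapped <- function(query, chromseq, diag, max_mm) {
  m <- .match_vector(query, chromseq, diag)
  w <- .best_window(m, max_mm)
  if (is.null(w)) return(NULL)
  len <- nchar(query)
  data.table(gstart = diag + w[1] - 1L, gend = diag + w[2] - 1L,
             q5clip = w[1] - 1L, q3clip = len - w[2],
             mism = w[3], njunc = 0L,
             intron_start = NA_integer_, intron_end = NA_integer_)
}

# evaluate a spliced (one-gap) candidate from a pair of diagonals d1 < d2:
# contig prefix on d1, suffix shifted to d2; splice motif must match the
# aligned strand (GT..AG read on that strand)
.eval_spliced <- function(query, chromseq, d1, d2, max_mm, strand,
                         known_introns = NULL) {
  len <- nchar(query)
  gap <- d2 - d1
  m1 <- .match_vector(query, chromseq, d1)
  m2 <- .match_vector(query, chromseq, d2)
  c1 <- cumsum(!m1)
  c2r <- rev(cumsum(rev(!m2)))            # mismatches in suffix b+1..len on d2
  best <- NULL
  for (b in seq_len(len - 1L)) {
    mm <- c1[b] + (if (b + 1L <= len) c2r[b + 1L] else 0L)
    if (mm > max_mm) next
    if (!m1[b] || !m2[b + 1L]) next       # junction flanks must match
    istart <- d1 + b; iend <- d2 + b - 1L # intron, 1-based inclusive
    if (iend - istart + 1L < 20L) next
    ok <- FALSE
    if (!is.null(known_introns) &&
        nrow(known_introns[J(istart, iend), nomatch = NULL])) ok <- TRUE
    if (!ok) {
      don <- substring(chromseq, istart, istart + 1L)
      acc <- substring(chromseq, iend - 1L, iend)
      motif_ok <- if (strand == "+") don == "GT" && acc == "AG"
                  else don == "CT" && acc == "AC"
      ok <- motif_ok
    }
    if (!ok) next
    if (is.null(best) || mm < best$mism) {
      best <- data.table(gstart = d1, gend = d2 + len - 1L,
                         q5clip = 0L, q3clip = 0L, mism = mm, njunc = 1L,
                         intron_start = istart, intron_end = iend, b = b)
    }
  }
  if (is.null(best)) return(NULL)
  # trim terminal mismatches into clips
  b <- best$b
  i <- 1L; while (i <= b && !m1[i]) i <- i + 1L
  j <- len; while (j > b && !m2[j]) j <- j - 1L
  best$gstart <- d1 + i - 1L
  best$gend <- d2 + j - 1L
  best$q5clip <- i - 1L
  best$q3clip <- len - j
  best$mism <- best$mism - sum(!m1[seq_len(i - 1L)]) -
    (if (j < len) sum(!m2[(j + 1L):len]) else 0L)
  best$b <- NULL
  best
}

#' Align contigs to a genome with the built-in seed-and-extend aligner
#'
#' Desk-scale splice-aware aligner: exact seeds (length 15) anchor candidate
#' diagonals on both strands; candidates are extended ungapped with terminal
#' soft-clipping and up to `max(3, round(3 * length / 31))` mismatches, and
#' pairs of same-strand diagonals 20 to 100,000 nt apart are evaluated as
#' single-gap spliced alignments whose gap must read GT..AG on the aligned
#' strand or match an annotated intron. All co-optimal locations (fewest
#' mismatches, then least clipping) are counted in `nb_hits` up to a cap;
#' the primary alignment is the leftmost best one. A contig is mapped when
#' its best alignment covers at least `min(length - 10, 25)` non-clipped
#' bases: short contigs must align near-fully, while a long contig counts
#' as mapped once it has a solid local alignment (poly(A) tails and other
#' non-reference extensions are soft-clipped, not penalized).
#'
#' Clipping is reported in contig orientation: `clipped_3p` counts
#' unaligned bases at the contig's own 3' end regardless of genome strand.
#'
#' @param contigs Character vector of contig sequences (names used as ids;
#'   defaults to `contig_1`, ...).
#' @param gidx A [index_genome()] object.
#' @param annotation Optional GFF3 annotation (path or `GRanges`) whose
#'   introns are accepted as junction gaps regardless of motif.
#' @param max_hits Cap on reported co-optimal locations (default 50).
#' @return `data.table`, one row per contig: `contig_id`, `contig`, `chrom`,
#'   `start`, `end` (0-based half-open, spanning any junction gap),
#'   `strand`, `nb_hits`, `nb_junctions`, `nb_mismatches`, `nb_indels`,
#'   `clipped_5p`, `clipped_3p`, `is_mapped`.
#' @export
align_builtin <- function(contigs, gidx, annotation = NULL, max_hits = 50L) {
  ids <- names(contigs)
  if (is.null(ids)) ids <- paste0("contig_", seq_along(contigs))
  known_introns <- .annotation_introns(annotation)
  rows <- vector("list", length(contigs))
  for (ci in seq_along(contigs)) {
    contig <- toupper(contigs[[ci]])
    len <- nchar(contig)
    max_mm <- max(3L, as.integer(round(3 * len / 31)))
    cands <- list()
    for (strand in c("+", "-")) {
      query <- if (strand == "+") contig else revcomp(contig)
      diags <- .candidate_diagonals(query, gidx)
      if (!nrow(diags)) next
      for (r in seq_len(nrow(diags))) {
        ch <- diags$chrom[r]
        a <- .eval_ungapped(query, gidx$seqs[[ch]], diags$diag[r], max_mm)
        if (!is.null(a)) {
          a[, c("chrom", "strand") := .(ch, strand)]
          cands[[length(cands) + 1L]] <- a
        }
      }
      # spliced: pairs of diagonals on the same chromosome
      for (ch in unique(diags$chrom)) {
        dd <- sort(diags[chrom == ch]$diag)
        if (length(dd) < 2L) next
        for (i1 in seq_len(length(dd) - 1L)) for (i2 in (i1 + 1L):length(dd)) {
          gap <- dd[i2] - dd[i1]
          if (gap < 20L || gap > 100000L) next
          a <- .eval_spliced(query, gidx$seqs[[ch]], dd[i1], dd[i2], max_mm,
                             strand, known_introns)
          if (!is.null(a)) {
            a[, c("chrom", "strand") := .(ch, strand)]
            cands[[length(cands) + 1L]] <- a
          }
        }
      }
    }
    rows[[ci]] <- .pick_best(ids[ci], contig, cands, len, max_hits)
  }
  rbindlist(rows)
}

.annotation_introns <- function(annotation) {
  if (is.null(annotation)) return(NULL)
  gff <- if (is.character(annotation)) read_annotation(annotation)
         else annotation
  ex <- gff$exons
  if (is.null(ex) || !length(ex)) return(NULL)
  istart <- iend <- NULL # data.table NSE
  bytx <- split(ex, ex$transcript_id)
  outs <- lapply(bytx, function(g) {
    g <- GenomicRanges::sort(g)
    if (length(g) < 2L) return(NULL)
    data.table(istart = GenomicRanges::end(g)[-length(g)] + 1L,
               iend = GenomicRanges::start(g)[-1] - 1L)
  })
  dt <- unique(rbindlist(outs))
  if (!nrow(dt)) return(NULL)
  setkey(dt, istart, iend)
  dt
}

.unmapped_row <- function(id, contig, len) {
  data.table(contig_id = id, contig = contig, chrom = NA_character_,
             start = NA_integer_, end = NA_integer_, strand = NA_character_,
             nb_hits = 0L, nb_junctions = 0L, nb_mismatches = NA_integer_,
             nb_indels = NA_integer_, clipped_5p = NA_integer_,
             clipped_3p = NA_integer_, is_mapped = FALSE)
}

.pick_best <- function(id, contig, cands, len, max_hits) {
  if (!length(cands)) return(.unmapped_row(id, contig, len))
  all <- rbindlist(cands)
  clip <- mism <- njunc <- chrom <- gstart <- strand <- NULL # data.table NSE
  all[, clip := q5clip + q3clip]
  all <- unique(all, by = c("chrom", "gstart", "gend", "strand"))
  o <- order(all$mism, all$clip, all$njunc, all$chrom, all$gstart,
             all$strand != "+", method = "radix")
  all <- all[o]
  top <- all[mism == all$mism[1] & clip == all$clip[1] &
               njunc == all$njunc[1]]
  n_hits <- min(nrow(top), max_hits)
  b <- all[1]
  aligned <- len - b$clip
  mapped <- aligned >= min(len - 10L, 25L)
  if (!mapped) return(.unmapped_row(id, contig, len))
  # clips in contig orientation (query was revcomp on "-")
  c5 <- if (b$strand == "+") b$q5clip else b$q3clip
  c3 <- if (b$strand == "+") b$q3clip else b$q5clip
  data.table(contig_id = id, contig = contig, chrom = b$chrom,
             start = b$gstart - 1L, end = b$gend, strand = b$strand,
             nb_hits = n_hits, nb_junctions = b$njunc,
             nb_mismatches = b$mism, nb_indels = 0L,
             clipped_5p = c5, clipped_3p = c3, is_mapped = TRUE)
}

#' Ingest external alignments from a SAM file
#'
#' Alternative to [align_builtin()] for real genomes: reads a (text) SAM
#' file produced by an external aligner and derives the same per-contig
#' alignment features. The query name must equal the contig id. Junctions
#' are N CIGAR operations of at least 20 nt; mismatches come from the NM
#' tag (minus indel bases); `nb_hits` comes from the NH tag when present,
#' otherwise from the number of records per query.
#'
#' @param sam_path Path to a SAM file.
#' @param contigs Named character vector of contig sequences (ids = names).
#' @return `data.table` in the same layout as [align_builtin()].
#' @export
read_sam_alignments <- function(sam_path, contigs) {
  lines <- readLines(sam_path)
  lines <- lines[!startsWith(lines, "@")]
  ids <- names(contigs)
  recs <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 11L) next
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) > 0L) next      # unmapped record
    cigar <- f[6]
    ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
    n <- as.integer(sub("[A-Z=]", "", ops))
    op <- sub("[0-9]+", "", ops)
    ref_len <- sum(n[op %in% c("M", "D", "N", "=", "X")])
    njunc <- sum(op == "N" & n >= 20L)
    nindel <- sum(op %in% c("I", "D"))
    clip5 <- if (length(op) && op[1] %in% c("S", "H")) n[1] else 0L
    clip3 <- if (length(op) && op[length(op)] %in% c("S", "H")) n[length(op)] else 0L
    nm <- suppressWarnings(as.integer(sub("^NM:i:", "",
                                          grep("^NM:i:", f, value = TRUE)[1])))
    nh <- suppressWarnings(as.integer(sub("^NH:i:", "",
                                          grep("^NH:i:", f, value = TRUE)[1])))
    indel_bases <- sum(n[op %in% c("I", "D")])
    mism <- if (is.na(nm)) 0L else max(0L, nm - indel_bases)
    rev <- bitwAnd(flag, 16L) > 0L
    recs[[length(recs) + 1L]] <- data.table(
      contig_id = f[1], chrom = f[3], start = as.integer(f[4]) - 1L,
      end = as.integer(f[4]) - 1L + ref_len,
      strand = if (rev) "-" else "+",
      nb_junctions = njunc, nb_mismatches = mism, nb_indels = nindel,
      clipped_5p = if (rev) clip3 else clip5,
      clipped_3p = if (rev) clip5 else clip3,
      nb_hits = nh, secondary = bitwAnd(flag, 256L) > 0L)
  }
  contig_id <- secondary <- nb_hits <- NULL # data.table NSE
  dt <- rbindlist(recs)
  out <- vector("list", length(contigs))
  for (i in seq_along(contigs)) {
    sub <- if (nrow(dt)) dt[contig_id == ids[i]] else dt
    if (!nrow(sub)) {
      out[[i]] <- .unmapped_row(ids[i], contigs[[i]], nchar(contigs[[i]]))
      next
    }
    prim <- sub[!(secondary)][1]
    if (is.na(prim$contig_id)) prim <- sub[1]
    hits <- if (!is.na(prim$nb_hits)) prim$nb_hits else nrow(sub)
    row <- prim[, !"secondary"]
    row[, nb_hits := hits]
    row <- cbind(data.table(contig = contigs[[i]]), row)
    row[, c("is_mapped") := TRUE]
    setcolorder(row, c("contig_id", "contig", "chrom", "start", "end",
                       "strand", "nb_hits", "nb_junctions", "nb_mismatches",
                       "nb_indels", "clipped_5p", "clipped_3p", "is_mapped"))
    out[[i]] <- row
  }
  rbindlist(out, use.names = TRUE)
}
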