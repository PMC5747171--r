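#' Unique prefix-suffix overlaps at a fixed overlap length
#'
#' A pair (u, v) of distinct sequences overlaps at length `olen` when the
#' `olen`-suffix of u equals the `olen`-prefix of v. Extension only follows
#' overlaps that are unique on both sides: u must have exactly one outgoing
#' and v exactly one incoming overlap at this length — extension stops as
#' soon as a fork is encountered.
#'
#' @param contigs Character vector of distinct sequences.
#' @param olen Overlap length (>= 1).
#' @return Two-column `data.table` (`from`, `to`) of unique overlap pairs.
#' @export
unique_overlaps <- function(contigs, olen) {
  stopifnot(olen >= 1L)
  from <- to <- pre <- suf <- n_out <- n_in <- NULL # data.table NSE
  contigs <- contigs[nchar(contigs) >= olen]
  if (length(contigs) < 2L)
    return(data.table(from = character(0), to = character(0)))
  dt_s <- data.table(from = contigs,
                     suf = substring(contigs, nchar(contigs) - olen + 1L))
  dt_p <- data.table(to = contigs, pre = substring(contigs, 1L, olen))
  pairs <- dt_s[dt_p, on = c(suf = "pre"), allow.cartesian = TRUE,
                nomatch = NULL][from != to]
  if (!nrow(pairs))
    return(data.table(from = character(0), to = character(0)))
  pairs[, n_out := .N, by = from]
  pairs[, n_in := .N, by = to]
  out <- pairs[n_out == 1L & n_in == 1L, .(from, to)]
  setorderv(out, "from")
  out[]
}

# collapse the chains implied by a set of unique-overlap pairs; returns the
# merged sequence set plus a mapping from new contigs to old member indices
.collapse_chains <- function(seqs, pairs, olen, members) {
  nxt <- stats::setNames(pairs$to, pairs$from)
  has_in <- seqs %in% pairs$to
  starts <- names(nxt)[!(names(nxt) %in% pairs$to)]
  in_chain <- unique(c(pairs$from, pairs$to))
  # cycles: components where every node has an incoming edge; break each at
  # its lexicographically smallest member
  cyc_nodes <- setdiff(in_chain, c(starts, unlist(lapply(starts, function(s) {
    path <- s
    while (!is.na(nxt[path[length(path)]])) {
      path <- c(path, unname(nxt[path[length(path)]]))
    }
    path
  }))))
  if (length(cyc_nodes)) {
    warning("overlap cycle detected at overlap length ", olen,
            "; breaking at lexicographically smallest member")
    remaining <- cyc_nodes
    while (length(remaining)) {
      s <- min(remaining)
      path <- s
      while (!is.na(nxt[path[length(path)]]) &&
             unname(nxt[path[length(path)]]) != s) {
        path <- c(path, unname(nxt[path[length(path)]]))
      }
      starts <- c(starts, s)
      remaining <- setdiff(remaining, path)
    }
  }
  starts <- sort(starts)   # deterministic processing order
  keep <- !(seqs %in% in_chain)
  new_seqs <- seqs[keep]
  new_members <- members[keep]
  idx_of <- stats::setNames(seq_along(seqs), seqs)
  for (s in starts) {
    path <- s
    while (!is.na(nxt[path[length(path)]])) {
      nx <- unname(nxt[path[length(path)]])
      if (nx %in% path) break  # broken cycle closes here
      path <- c(path, nx)
    }
    merged <- path[1]
    for (q in path[-1]) merged <- paste0(merged, substring(q, olen + 1L))
    new_seqs <- c(new_seqs, merged)
    new_members <- c(new_members,
                     list(unlist(members[idx_of[path]], use.names = FALSE)))
  }
  list(seqs = new_seqs, members = new_members)
}

#' One extension round at a fixed overlap length
#'
#' Repeatedly merges contigs joined by unique prefix-suffix overlaps of
#' length `olen` (u + v with the duplicated overlap removed) until no merge
#' applies. The output is deterministic: candidate chains are processed in
#' lexicographic order of their first member, and a cycle is broken at its
#' lexicographically smallest member (with a warning).
#'
#' @param contigs Character vector of sequences.
#' @param olen Overlap length.
#' @return Character vector of merged sequences.
#' @export
merge_round <- function(contigs, olen) {
  res <- .merge_round_tracked(contigs, olen,
                              members = as.list(seq_along(contigs)))
  res$seqs
}

.merge_round_tracked <- function(seqs, olen, members) {
  repeat {
    # guard: identical sequences (possible after merging) are collapsed into
    # one contig whose member set is the union
    if (anyDuplicated(seqs)) {
      grp <- split(seq_along(seqs), seqs)
      members <- lapply(grp, function(ix)
        unlist(members[ix], use.names = FALSE))
      seqs <- names(grp)
      names(members) <- NULL
    }
    pairs <- unique_overlaps(seqs, olen)
    if (!nrow(pairs)) break
    res <- .collapse_chains(seqs, pairs, olen, members)
    seqs <- res$seqs
    members <- res$members
  }
  o <- order(seqs, method = "radix")
  list(seqs = seqs[o], members = members[o])
}

#' Extend differentially expressed k-mers into contigs
#'
#' The extension procedure merges DE k-mers that share unique prefix-suffix
#' overlaps into contigs, starting at overlap length k-1 and repeating with
#' k-2, k-3, ... down to `min_overlap` (default 15), each round taking the
#' previous round's contigs as input. Each contig is labeled by its
#' constituent k-mer of lowest raw p-value (ties broken by the
#' lexicographically smallest k-mer) and inherits that k-mer's statistics
#' and counts.
#'
#' @param de_kmers `data.table` from [de_filter()] (columns `tag`, `pvalue`,
#'   `padj`, ... plus per-sample counts), all tags distinct and of length k.
#' @param k k-mer length.
#' @param min_overlap Minimum overlap length chased (default 15; must be
#'   >= 1 and < k).
#' @return A `data.table` with columns `contig`, `contig_length`,
#'   `nb_merged_kmers`, `tag` (label k-mer) and the label k-mer's statistic
#'   and count columns, sorted by increasing `pvalue`.
#' @export
merge_tags <- function(de_kmers, k, min_overlap = 15L) {
  stopifnot(min_overlap >= 1L, min_overlap < k)
  if (!nrow(de_kmers)) {
    out <- data.table(contig = character(0), contig_length = integer(0),
                      nb_merged_kmers = integer(0))
    return(cbind(out, de_kmers))
  }
  stopifnot(!anyDuplicated(de_kmers$tag),
            all(nchar(de_kmers$tag) == k))
  seqs <- de_kmers$tag
  members <- as.list(seq_along(seqs))
  for (olen in seq(k - 1L, min_overlap)) {
    res <- .merge_round_tracked(seqs, olen, members)
    seqs <- res$seqs
    members <- res$members
  }
  pvalue <- NULL # data.table NSE
  lab <- vapply(members, function(ix) {
    p <- de_kmers$pvalue[ix]
    cand <- ix[p == min(p)]
    cand[order(de_kmers$tag[cand], method = "radix")][1]
  }, integer(1))
  out <- data.table(contig = seqs,
                    contig_length = nchar(seqs),
                    nb_merged_kmers = lengths(members))
  out <- cbind(out, de_kmers[lab])
  setorderv(out, c("pvalue", "contig"))
  out[]
}
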