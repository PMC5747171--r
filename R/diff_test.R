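#' Median-of-ratios normalization factors
#'
#' Computes one positive scaling factor per sample by the median-of-ratios
#' method: each sample's counts are divided by a pseudo-reference (the
#' per-k-mer geometric mean across samples, using only rows with all counts
#' positive), and the NF is the median of those ratios. To avoid scanning
#' the complete table, a random subset of the rows (default 30%) is used.
#' NFs are finally rescaled to have geometric mean 1 (they multiply to 1),
#' which fixes the otherwise arbitrary global scale.
#'
#' NFs are computed once, from the recurrence-filtered (pre-masking) matrix,
#' and reused by every downstream test.
#'
#' @param matrix A [kmer_count_matrix()] (after the recurrence filter,
#'   before masking).
#' @param frac Fraction of rows to subsample (default 0.30; 1 = all rows).
#' @param seed Integer seed for the row subsample.
#' @return Named numeric vector of normalization factors (one per sample,
#'   named by library id), multiplying to 1.
#' @export
compute_nf <- function(matrix, frac = 0.30, seed = 42L) {
  stopifnot(frac > 0, frac <= 1)
  counts <- matrix$counts
  m <- nrow(counts)
  if (m == 0L) stop("empty count matrix", call. = FALSE)
  if (frac < 1) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(as.integer(seed))
    idx <- sort(sample.int(m, size = max(1L, round(frac * m))))
    counts <- counts[idx, , drop = FALSE]
  }
  pos <- rowSums(counts > 0L) == ncol(counts)
  if (!any(pos))
    stop("no k-mer has positive counts in all samples; ",
         "cannot compute normalization factors (try more depth or smaller k)",
         call. = FALSE)
  counts <- counts[pos, , drop = FALSE]
  geo <- exp(rowMeans(log(counts)))
  nf <- apply(counts / geo, 2, stats::median)
  nf <- nf / exp(mean(log(nf)))
  stats::setNames(nf, matrix$samples$library_id)
}

# preserve caller's RNG state around seeded internals
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# Vectorized Welch t-test on log2(count/NF + 1), rows of `counts`.
# Degenerate convention: zero variance in both groups -> p = 1 if the means
# are equal, else p = 0 (perfect separation).
.row_welch_log <- function(counts, nf, is_a) {
  y <- log2(sweep(counts, 2, nf, "/") + 1)
  ya <- y[, is_a, drop = FALSE]; yb <- y[, !is_a, drop = FALSE]
  na <- ncol(ya); nb <- ncol(yb)
  ma <- rowMeans(ya); mb <- rowMeans(yb)
  va <- rowSums((ya - ma)^2) / (na - 1)
  vb <- rowSums((yb - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tstat <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  degen <- se2 == 0
  p[degen & abs(mb - ma) < .Machine$double.eps^0.5] <- 1
  p[degen & abs(mb - ma) >= .Machine$double.eps^0.5] <- 0
  p
}

#' Per-k-mer t-test p-value on log-normalized counts
#'
#' Two-sided Welch (unequal-variance) two-sample t-test on
#' `log2(count / NF + 1)`. When both groups have zero within-group variance
#' and equal means the p-value is 1 by convention.
#'
#' @param row Integer vector of counts across samples, or a matrix (rows =
#'   k-mers) for the vectorized form.
#' @param nf Normalization factors from [compute_nf()].
#' @param groups Factor/character of condition labels, two levels.
#' @return Numeric p-value(s) in \[0, 1\].
#' @export
ttest_pvalue <- function(row, nf, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L)
    stop("exactly two conditions are required", call. = FALSE)
  if (min(table(groups)) < 2L)
    stop("the t-test needs at least 2 samples per condition", call. = FALSE)
  is_a <- groups == levels(groups)[1]
  m <- if (is.matrix(row)) row else matrix(row, nrow = 1L)
  p <- .row_welch_log(m, nf, is_a)
  if (is.matrix(row)) p else p[1]
}

# NB log-likelihood derivative wrt log(size r), summed per row.
# mu: matrix of fitted means, y: counts, r: per-row size (1/dispersion)
.nb_dl_dlogr <- function(y, mu, r) {
  rr <- matrix(r, nrow = length(r), ncol = ncol(y))
  dldr <- rowSums(digamma(y + rr) - digamma(rr) + log(rr / (rr + mu)) +
                    (mu - y) / (rr + mu))
  r * dldr
}

# Newton update of per-row group mean on the log scale, given dispersion.
# mu_ij = s_j * m_i ; returns updated m
.nb_update_mean <- function(y, s, m, alpha) {
  for (it in 1:12) {
    mu <- m %o% s
    w <- 1 + alpha * mu
    f <- rowSums((y - mu) / w)                  # d loglik / d log m (x m^-1 terms folded)
    fp <- -rowSums(mu * (1 + alpha * y) / w^2)  # derivative wrt log m
    step <- f / fp
    step[!is.finite(step)] <- 0
    step <- pmax(pmin(step, 2), -2)
    m <- m * exp(-step)
    if (max(abs(step)) < 1e-8) break
  }
  m
}

#' Per-k-mer negative-binomial GLM p-values (chunk-safe)
#'
#' Fits, independently for each row, a negative-binomial generalized linear
#' model with the condition as single covariate and `log(NF)` as per-sample
#' offset, and returns the two-sided Wald p-value on the condition
#' coefficient. The per-row dispersion is estimated by maximum likelihood
#' (Newton iterations on the log of the size parameter), started from — and
#' falling back to — a method-of-moments estimate when the likelihood fit
#' fails. The Wald statistic is referred to a t distribution with n - 2
#' degrees of freedom, which keeps small-sample type-I error near nominal.
#' Fitted group means are floored at 0.5 / sum(NF) within the group so that
#' an all-zero group yields a finite (large) statistic.
#'
#' No information is shared across rows, so p-values are identical however
#' the matrix is chunked.
#'
#' @param counts Integer matrix (k-mers x samples) — one chunk.
#' @param nf Normalization factors from [compute_nf()].
#' @param groups Condition labels, two levels.
#' @return Numeric vector of raw p-values, one per row. Rows with identical
#'   counts everywhere (or degenerate fits) get p = 1.
#' @export
glm_chunk_pvalues <- function(counts, nf, groups) {
  groups <- as.factor(groups)
  stopifnot(nlevels(groups) == 2L)
  if (!is.matrix(counts)) counts <- matrix(counts, nrow = 1L)
  is_a <- groups == levels(groups)[1]
  n <- ncol(counts)
  ya <- counts[, is_a, drop = FALSE]; yb <- counts[, !is_a, drop = FALSE]
  sa <- nf[is_a]; sb <- nf[!is_a]
  na <- ncol(ya); nb <- ncol(yb)

  # moment start: pooled within-group variance of normalized counts
  qa <- sweep(ya, 2, sa, "/"); qb <- sweep(yb, 2, sb, "/")
  ma0 <- pmax(rowSums(ya) / sum(sa), 0.5 / sum(sa))
  mb0 <- pmax(rowSums(yb) / sum(sb), 0.5 / sum(sb))
  ss <- rowSums((qa - rowMeans(qa))^2) + rowSums((qb - rowMeans(qb))^2)
  mbar <- (rowSums(ya) + rowSums(yb)) / sum(nf)
  alpha_mom <- pmin(pmax((ss / (n - 2) - mbar) / mbar^2, 1e-8), 100)
  alpha_mom[!is.finite(alpha_mom)] <- 1e-8

  # alternate mean / ML-dispersion updates
  alpha <- alpha_mom
  ma <- ma0; mb <- mb0
  for (outer in 1:8) {
    ma <- pmax(.nb_update_mean(ya, sa, ma, alpha), 0.5 / sum(sa))
    mb <- pmax(.nb_update_mean(yb, sb, mb, alpha), 0.5 / sum(sb))
    mu <- cbind(ma %o% sa, mb %o% sb)
    y <- cbind(ya, yb)
    logr <- -log(alpha)
    u <- .nb_dl_dlogr(y, mu, exp(logr))
    h <- 0.05
    up <- .nb_dl_dlogr(y, mu, exp(logr + h))
    um <- .nb_dl_dlogr(y, mu, exp(logr - h))
    du <- (up - um) / (2 * h)
    step <- u / du
    step[!is.finite(step) | du >= 0] <- 0   # non-concave spots: keep current
    step <- pmax(pmin(step, 2), -2)
    logr <- logr - step
    alpha_new <- exp(-logr)
    bad <- !is.finite(alpha_new)
    alpha_new[bad] <- alpha_mom[bad]
    alpha <- pmin(pmax(alpha_new, 1e-8), 100)
  }

  # Wald test on log(mb) - log(ma) with observed-information variance
  ia <- rowSums((ma %o% sa) / (1 + alpha * (ma %o% sa)))
  ib <- rowSums((mb %o% sb) / (1 + alpha * (mb %o% sb)))
  se <- sqrt(1 / ia + 1 / ib)
  z <- (log(mb) - log(ma)) / se
  p <- 2 * stats::pt(-abs(z), df = n - 2)
  # degenerate rows: identical counts everywhere, or failed fits
  flat <- apply(counts, 1, function(r) length(unique(r)) == 1L)
  p[flat | !is.finite(p)] <- 1
  pmin(p, 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment with monotonicity
#' enforcement, clipped to 1.
#'
#' @param pvalues Numeric vector of raw p-values in \[0, 1\].
#' @return Numeric vector of adjusted p-values.
#' @export
bh_adjust <- function(pvalues) {
  stats::p.adjust(pvalues, method = "BH")
}

#' Differential k-mer test and filter
#'
#' Runs the selected test on every row of a (masked) count matrix, adjusts
#' p-values over all tested k-mers jointly with Benjamini-Hochberg, and
#' returns the k-mers whose adjusted p-value passes the threshold, together
#' with their counts, raw and adjusted p-values, normalized condition means
#' and log2 fold change (B vs A, pseudocount 1).
#'
#' @param matrix A (masked) [kmer_count_matrix()].
#' @param nf Normalization factors from [compute_nf()].
#' @param method `"ttest"` (Welch t on log-normalized counts) or `"glm"`
#'   (negative-binomial GLM, slower but more sensitive for small samples).
#' @param pvalue_threshold Adjusted-p cutoff (default 0.05).
#' @param chunk_size Rows per chunk for the glm method (results are
#'   chunk-invariant; chunking only bounds memory).
#' @return A `data.table` with columns `tag`, `pvalue`, `padj`, `meanA`,
#'   `meanB`, `log2FC`, then one count column per sample; sorted by
#'   increasing `pvalue`.
#' @export
de_filter <- function(matrix, nf, method = c("ttest", "glm"),
                      pvalue_threshold = 0.05, chunk_size = 1e6L) {
  method <- match.arg(method)
  stopifnot(pvalue_threshold > 0, pvalue_threshold <= 1)
  counts <- matrix$counts
  groups <- as.factor(matrix$samples$condition)
  if (nrow(counts) == 0L) {
    warning("empty matrix: no k-mers to test")
    return(.empty_diff_table(matrix$samples$library_id))
  }
  if (method == "ttest") {
    p <- ttest_pvalue(counts, nf, groups)
  } else {
    idx <- seq_len(nrow(counts))
    chunks <- split(idx, ceiling(idx / chunk_size))
    p <- numeric(nrow(counts))
    for (ch in chunks)
      p[ch] <- glm_chunk_pvalues(counts[ch, , drop = FALSE], nf, groups)
  }
  padj <- bh_adjust(p)
  is_a <- groups == levels(groups)[1]
  norm <- sweep(counts, 2, nf, "/")
  meanA <- rowMeans(norm[, is_a, drop = FALSE])
  meanB <- rowMeans(norm[, !is_a, drop = FALSE])
  keep <- which(padj <= pvalue_threshold)
  dt <- data.table(tag = matrix$kmers[keep],
                   pvalue = p[keep], padj = padj[keep],
                   meanA = meanA[keep], meanB = meanB[keep],
                   log2FC = log2((meanB[keep] + 1) / (meanA[keep] + 1)))
  cnt <- as.data.table(counts[keep, , drop = FALSE])
  setnames(cnt, matrix$samples$library_id)
  dt <- cbind(dt, cnt)
  setorderv(dt, c("pvalue", "tag"))
  dt[]
}

.empty_diff_table <- function(library_ids) {
  dt <- data.table(tag = character(0), pvalue = numeric(0),
                   padj = numeric(0), meanA = numeric(0), meanB = numeric(0),
                   log2FC = numeric(0))
  for (id in library_ids) dt[, (id) := integer(0)]
  dt[]
}

#' Write / read the differential k-mer table
#'
#' @param diff `data.table` from [de_filter()].
#' @param path Output TSV path (`.gz` compresses).
#' @return `path`, invisibly.
#' @export
write_diff_table <- function(diff, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  utils::write.table(diff, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
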