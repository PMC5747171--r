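---
title: "Reference-free differential k-mer analysis: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free differential k-mer analysis: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`kmerDE` detects differential transcript variation in two-condition
RNA-seq without mapping reads or assembling transcripts. This vignette is
the package's account of the underlying models, the tunable parameters,
the numerical choices, and what the synthetic studies used in the test
suite do and do not demonstrate.

## The unit of analysis

A k-mer (default k = 31 nt) is the unit of both quantification and
testing. The choice of k trades specificity (longer k-mers are more often
unique in a transcriptome) against robustness (each sequencing error
corrupts k consecutive k-mers) and table size; 31 is the field's common
default and the package accepts 15 < k ≤ 63. Counting is exact and
hash-based. In stranded mode, reads sequenced in the reverse orientation
relative to the transcript are reverse-complemented before windowing, so
k-mers carry transcript orientation; in unstranded mode every window is
replaced by its canonical form (the lexicographic minimum of the window
and its reverse complement). Windows containing a non-ACGT base are
skipped entirely — no sequence is fabricated around an N — and quality
strings are ignored. A per-library minimum abundance (default 2) drops
most error singletons at the counting stage.

## Filtering and masking

Joining per-library counts gives a k-mer × sample matrix. Two filters
remove the bulk of uninteresting rows:

* **Recurrence.** `recurrence(x, a)` is the number of samples where k-mer
  x occurs strictly more than `a` times. Rows with
  `recurrence(x, min_recurrence_abundance) < min_recurrence` are dropped.
  Defaults: `min_recurrence_abundance = 5`, `min_recurrence` = replicates
  per condition — a biologically real k-mer is expected to recur across
  the replicates of at least one condition.
* **Masking.** K-mers occurring in a user-supplied reference transcriptome
  are removed; what survives is, by construction, non-reference sequence.
  In stranded mode only the sense strand of each transcript is indexed,
  deliberately: masking both strands would erase antisense transcription,
  and the asRNA event class exists only because sense-only masking lets
  antisense k-mers through. Masking can be bypassed (`masking = "none"`),
  which enlarges the DE set to include reference k-mers whose abundance
  changes.

The pipeline order is fixed: join → recurrence filter → mask.
Normalization factors are computed between the last two steps, from the
recurrence-filtered but **unmasked** matrix — the masked matrix contains
only condition-skewed rows and would bias the factors (a regression test
pins this call order).

## Normalization and testing

Per-sample normalization factors use the median-of-ratios method: each
sample's counts are divided by a pseudo-reference (the per-row geometric
mean across samples, computed over rows with all counts positive; rows
containing a zero carry no information about relative depth and are
dropped), and the factor is the median ratio. A random 30% row subsample
(seeded, reproducible) stands in for the full table. The resulting
factors are rescaled to have geometric mean 1; the scale of the factors
is otherwise unidentified and this convention makes runs comparable.

Two per-k-mer test engines share this normalization:

* **t-test engine.** Welch's unequal-variance t-test on
  `log2(count/NF + 1)`. Base 2 with pseudocount 1 keeps zeros at zero and
  makes effect sizes readable as fold changes. Welch rather than pooled
  variance because per-condition variances of k-mer counts are routinely
  unequal; the statistic is exact under normality of the transformed
  counts, an approximation that degrades at very low counts. When both
  groups have zero variance the p-value is 1 for equal means and 0
  otherwise.
* **GLM engine.** A from-scratch negative-binomial GLM per k-mer with the
  condition as single covariate and log(NF) as per-sample offset, Wald
  test on the condition coefficient. The dispersion is estimated per row
  by maximum likelihood (Newton iterations on the log of the size
  parameter), started from and falling back to a method-of-moments
  estimate; unlike shrinkage-based tools no information is shared across
  rows, which keeps p-values exactly invariant to how the matrix is
  chunked (chunks exist only to bound memory, default ~1e6 rows). Two
  small-sample safeguards matter numerically: the Wald statistic is
  referred to a t distribution with n − 2 degrees of freedom rather than
  a normal, and fitted group means are floored at 0.5/sum(NF) within the
  group so an all-zero group yields a large finite statistic instead of
  an infinite one.

Raw p-values from either engine are adjusted with Benjamini–Hochberg over
**all** tested k-mers jointly (not per chunk), and rows with adjusted
p ≤ `pvalue_threshold` (default 0.05) proceed. The test suite verifies,
on simulated negative-binomial rows at 6 vs 6 and dispersion 0.1 (50,000
null rows, 50 spiked at fold 8), that both engines hold their type-I
error within twice nominal at α = 0.05, reach sensitivity ≥ 0.9 at
FDR ≤ 0.1, and that the GLM engine is at least as sensitive as the
t-test — and strictly more sensitive in low-count regimes.

## Contig extension

DE k-mers covering the same event (one splice junction corrupts up to k
consecutive k-mers; one SNV likewise) are merged by unique prefix–suffix
overlap: at overlap length L, pair (u, v) is merged only when the
L-suffix of u equals the L-prefix of v and the overlap is unique on both
sides — extension stops at forks. Rounds run at L = k−1 first, repeating
until stable, then L = k−2, and so on down to `min_overlap` = 15
inclusive; 15 is where spurious overlaps between unrelated 31-mers become
likely. Within a round, chains are processed in lexicographic order of
their first member, and a cyclic chain (which arises naturally from
tandem-repeat k-mers and homopolymer runs) is broken at its
lexicographically smallest member — both rules exist purely to make the
output order-independent and deterministic. Uniqueness at L < k−1 is
evaluated among the current contigs, not the original k-mers. Contigs are
built on the stored k-mer strand; in unstranded mode reverse-complement
overlaps are not chased.

Each contig is labeled by its constituent k-mer of lowest raw p-value
(ties: lexicographically smallest), and carries that k-mer's counts and
statistics. Two length signatures recur: an unextendable k-mer stays a
31-bp "orphan", and a single exonic SNV yields a 61-bp contig — 31
overlapping 31-mers around one variant base — which the end-to-end test
reproduces from raw reads.

## Alignment and annotation

Contigs are screened against Illumina adapters (discard on any shared
15-mer, either strand), then aligned to the genome. The built-in aligner
is a desk-scale splice-aware seed-and-extend: exact 15-mer seeds anchor
candidate diagonals on both strands; each candidate is extended as the
maximum-scoring local window (match +1, mismatch −4), so terminal
mismatch runs such as poly(A) tails are soft-clipped rather than
absorbed; at most `max(3, 3·len/31)` mismatches are allowed. Same-strand
diagonal pairs 20–100,000 nt apart are evaluated as single-gap spliced
alignments; the gap must read GT..AG on the aligned strand or coincide
with an annotated intron. All co-optimal locations (same mismatches,
clipping and junction count) are counted in `nb_hits` (cap 50); the
primary alignment is the leftmost best, with ungapped preferred over
spliced at equal score. A contig is mapped when its best alignment covers
at least `min(length − 10, 25)` non-clipped bases: short contigs must
align near-fully, while a long contig with a solid ≥25-nt local anchor
counts as mapped however long its non-reference extension is — a poly(A)
contig's genomic stub can never exceed k−1 = 30 nt while its tail can be
arbitrarily long, so any rule demanding near-full coverage would
misclassify exactly the contigs the polyA class is for. For real genomes
the same interface ingests SAM from an external aligner; clipping is
always reported in contig orientation (the contig's own 3' end),
including on minus-strand alignments.

Annotation intersects the primary alignment span (0-based half-open
internally; GFF3's 1-based inclusive coordinates are converted on entry)
with the gene model: a same-strand gene overlap sets the gene; an
opposite-strand-only overlap sets the antisense flag; exon overlap and
gene-minus-exon overlap set the exonic/intronic flags (a contig spanning
a boundary is both). In unstranded mode strand is unknown, so gene
overlap on either strand counts and antisense is never called. The SNV
flag requires at least one mismatch or indel **and** a unique hit.

## Gene expression, differential usage, and event classes

To separate isoform-level change from whole-gene change, each annotated
gene is quantified internally as the mean count of its k-mers that occur
in no other gene's transcripts (pre-masking matrix, NF-normalized), and
tested for DE with the same engine as the k-mer stage (gene DE at
adjusted p ≤ 0.05). The differential-usage (DU) p-value of a contig is a
Welch t-test, between conditions, of
`log2((contig_count/NF + 1)/(gene_expr + 1))` — a contig that simply
tracks its host gene has a flat ratio and p near 1. The DU threshold is
0.01 on the raw DU p-value, with no multiple-testing adjustment: DU is a
secondary annotation on an already-selected contig set, not a discovery
test. When a gene has no unique k-mer its expression is undefined and the
DU classes are unreachable for its contigs.

Classification applies a fixed first-match rule order: DU variants before
their parent classes, specific classes before generic ones —
splicing_DU, splicing, polyA_DU, polyA, lincRNA, asRNA, SNV_DU,
intron_DU, intron, repeats, unmapped, else unclassified. The auxiliary
conditions are: polyA requires a 3' clip ≥ 5 ending in ≥ 5 A; lincRNA
requires an intergenic unique mapping, length > 200 nt, mean normalized
count > 20 in at least one condition and a mapped span < 10 kb; asRNA the
antisense analogue (span < 10 kb); SNV_DU additionally requires the host
gene **not** DE (otherwise allele-frequency shift is confounded with
expression change); repeats requires ≥ 5 genomic hits and length > 50;
unmapped requires length > 50. The attachment of the auxiliary rules to
classes, and the rule order itself, are pinned choices of this package.
Loci group contigs by gene, antisense-of-gene, or the intergenic interval
between two flanking genes.

## The synthetic study

The generator builds a 100-kb single-chromosome genome with 20
non-overlapping genes (2–4 exons, 150–300 nt each; introns 200–350 nt)
on alternating strands, writing GT..AG at every intron boundary in the
gene's orientation; one intergenic 6-copy tandem array of a 66-nt unit;
and one unannotated intergenic region. Library counts per transcript are
negative binomial (mean `depth` = 400 reads/transcript, dispersion 0.1 —
the model the GLM engine assumes, enabling calibration tests), with 6
replicates per condition, 75-nt single-end stranded reads sampled
uniformly along each transcript, and substitution errors off by default
so that masking-completeness invariants are exact (reads drawn entirely
from annotated transcripts leave zero k-mers after masking). `depth` was
chosen so that interior k-mers of a spiked transcript comfortably clear
the recurrence filter (coverage ≈ depth × 45/length ≈ 15–25×) in every
replicate.

One event per class is spiked into condition B: an exon-skipping isoform;
a polyadenylated isoform with a 60-A non-genomic tail (long enough that
k-mers deep into the tail retain full read coverage); an intergenic
lincRNA (400 nt); an antisense transcript (400 nt); an exonic SNV allele
at 50% in B with the host gene's total held flat (so the
gene-not-DE rule of SNV_DU is genuinely exercised); a retained intron; a
90-nt transcript of the tandem array (shorter than unit + k, so its
k-mers form no phase cycle and the assembled contig occurs ≥ 5 times);
and a 300-nt exogenous insert drawn from an isolated seeded stream so it
is a pure function of the seed. Spiked isoforms are absent from condition
A, giving unambiguous direction-of-change truth; several host genes
consequently double their total expression in B, which is realistic and
exercises the DU tests.

What passing the end-to-end test shows: every stage's contracts compose —
counting through classification — and each event class's defining
signature survives the full path from raw reads. What it does not show:
robustness to sequencing error, coverage bias, PCR duplicates, paired-end
fragment effects, annotation incompleteness at real-genome scale, or
aligner ambiguity on repetitive mammalian genomes — the built-in aligner
is deliberately desk-scale, and real use should ingest external SAM.

## Numerical choices and degenerate inputs

* All k-mer ordering is C-locale lexicographic (radix sort); dumps are
  strictly increasing and the streaming join verifies this, naming the
  offending file and line.
* The streaming join reads bounded line blocks per file and emits rows up
  to the minimum buffered tail, so memory scales with block size × open
  files, not total k-mers.
* Empty inputs degrade gracefully: empty FASTA masks warn and match
  nothing; an empty DE set yields an empty contig table; contigs shorter
  than the seed are unmapped.
* Determinism: a fixed simulation seed gives byte-identical FASTQ and
  pipeline tables; merge rounds and tie-breaks are order-independent by
  construction; the NF subsample and GLM use seeded streams that are
  saved and restored around every internal `set.seed`.

## Problem sizes in the test suite

The suite runs the full synthetic study (12 libraries, ~14,000 distinct
k-mers, 8 spiked events) twice (masked and mask-bypassed) plus a
determinism re-run; DE calibration uses 50,000 null and 50 spiked rows
per engine; oracle-equivalence checks use 125 random small instances
across counting, overlap detection, recurrence, normalization and BH.
These sizes were chosen so the whole suite completes in a few minutes on
one CPU while keeping every statistical check adequately powered.
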