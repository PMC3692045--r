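---
title: "Methods: learning regulatory sequence vocabularies with kmer-SVMs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: learning regulatory sequence vocabularies with kmer-SVMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmersvm)
```

## The problem and the model

ChIP-seq and DNase-seq experiments yield sets of genomic regions bound by a
transcription factor or lying in open chromatin. The question this package
answers is: *what DNA sequence vocabulary distinguishes those regions from
the rest of the genome?* Rather than searching for one over-represented
motif, it trains a discriminative classifier over the complete set of
kmers and reads the answer off the model's coefficients.

Each sequence $s$ is mapped to a kmer count vector. Because transcription
factors bind double-stranded DNA, a kmer and its reverse complement are the
same physical feature: both occurrences are accumulated into a single
*canonical* representative (the lexicographic minimum of the pair), and the
redundant partner is dropped from the feature set so nothing is counted
twice. For kmer length $k$ this leaves

$$ D_k = \frac{4^k + p(k)}{2}, \qquad
   p(k) = \begin{cases} 4^{k/2} & k \text{ even}\\ 0 & k \text{ odd}\end{cases} $$

features ($p(k)$ counts reverse-complement palindromes); $D_6 = 2080$. The
count vector is scaled to unit Euclidean norm, so the *spectrum kernel*
$K(s, t) = \phi(s) \cdot \phi(t)$ satisfies $K(s, s) = 1$ and lies in
$[0, 1]$. The *weighted spectrum kernel* concatenates the blocks for a
contiguous range of $k$, each block independently unit-normalized and
weighted $1/\sqrt{\#k}$, so the composite vector is again unit-norm. We
normalize per block *before* concatenation; this realizes "equal weighting"
of the kmer lengths regardless of how many windows each contributes.
Windows containing `N` are skipped rather than imputed, and counting is
case-insensitive — soft-masking is metadata for the sampler (below), not
sequence content.

A soft-margin linear SVM is trained directly in this explicit feature
space. Since the spectrum kernel is the inner product of an explicit map,
the primal model is mathematically identical to the kernelized dual, and
the primal weight vector *is* the per-kmer weight table — the package's
main scientific output. The test suite verifies the identity numerically:
scores via the weight table agree with the dual expansion
$\sum_i \alpha_i y_i (x_i \cdot x + 1)$ to below $10^{-6}$.

### Solver

The fit minimizes
$$ \tfrac{1}{2}\lVert w\rVert^2 + \sum_i C_i \max(0,\, 1 - y_i\, w \cdot x_i), $$
with per-instance costs $C_i = C \cdot PSW$ for positives and $C$ for
negatives, by dual coordinate descent over the $\alpha_i$ — the standard
algorithm for linear SVMs at this scale, implemented in C++ with a
platform-independent xorshift PRNG for the per-epoch coordinate
permutation, so training is bit-reproducible for a given seed. The bias is
carried as an augmented constant feature (the usual convention for this
solver family), which mildly regularizes the intercept; the dual-expansion
kernel is correspondingly $x \cdot z + 1$. The tolerance parameter `E`
bounds the largest projected-gradient violation per epoch; loosening it can
only stop the identical trajectory earlier, so iteration counts are
monotone in `E`, and cross-validated AUROC is insensitive to it over
`1e-3`–`1e-5` (property-tested).

### Class imbalance: the positive-set weight

With a 10-fold larger negative set, symmetric costs would let the model
buy accuracy by ignoring positives. The default positive-set weight is

$$ PSW = 1 + \ln(N/P), $$

floored at 1 when $N < P$ (the floor is this package's choice; a weight
below 1 would *penalize* the minority class). The logarithm is natural —
the base is a documented choice, giving $PSW = 1$ for balanced sets and
$\approx 3.30$ at $N = 10P$.

## Profile-matched null sequences

Sequence features must not be predictive merely because the negative set
differs in composition. The sampler therefore matches each negative to a
randomly chosen source positive in **length** (exactly), **GC fraction**
and **repeat fraction** (each within an absolute tolerance, default 0.02),
drawn from the *same chromosome*, overlapping no positive, excluded region,
or previously accepted negative by even one base pair. Repeat fraction is
defined as the fraction of soft-masked (lowercase) bases — the form in
which RepeatMasker annotation travels in genome FASTA; GC is computed over
non-N bases, and windows more than 10% N (assembly gaps) are ineligible.
Tolerances are absolute (percentage points), not relative; positives are
cycled in a seeded random order, one accepted negative per visit, so every
positive is represented `fold_increase` times.

All window statistics come from a per-chromosome prefix-sum index (counts
of G/C, lowercase and N bases), making each candidate test O(1) and exact
in integer arithmetic; the index is property-tested against direct
recomputation on random windows.

Sampling is rejection-based: uniform random starts, tested against the
index. After `max_attempts` (default 10 000) failed draws the sampler does
**not** immediately relax the tolerance — it scans every window start on
the chromosome at the *strict* tolerance (cheap with the prefix sums) and
samples uniformly among the feasible, non-overlapping candidates. Only
when no strict match exists anywhere are both tolerances doubled, once,
for a second exhaustive scan; after that the positive is skipped with a
warning and recorded. This guarantees that a tolerance-conforming negative
is found whenever one exists, so the accepted set's "100% within
tolerance" property is deterministic rather than a function of sampling
luck, while the random fast path keeps typical cost low. `match_quality()`
reports two-sample KS distances between the positive and negative
length/GC/repeat distributions plus the per-negative tolerance audit.

## Cross-validation and calibration

Folds are stratified by class (with 10× negatives, unstratified folds can
starve a fold of positives), seeded, and exhaustive: every sequence is
scored exactly once as a held-out test item. The reported weight table
comes from a final model trained on *all* data — it uses all evidence —
while performance and calibration use only the pooled held-out CV scores.

Because the scale of SVM scores is arbitrary (only the ranking is
meaningful), scores are mapped to posterior probabilities by Platt
scaling: $P(+\mid s) = 1/(1 + e^{As + B})$, fitted by regularized maximum
likelihood with the standard numerically stable Newton iteration and
out-of-sample target values. Fitting on CV scores rather than training
scores avoids resubstitution bias. For symmetric, separable score
distributions the fitted sigmoid passes near $P(0) = 0.5$ with $B \approx
0$; in floating point the sigmoid is clamped to the open interval so
posteriors never print as exactly 0 or 1.

## Evaluation

ROC sweeps every distinct score as a threshold with tied scores stepping
jointly, so the trapezoidal AUROC equals the Mann–Whitney statistic — the
probability that a random positive outscores a random negative, ties
counted half — exactly (tested to $10^{-12}$ against brute-force pairwise
concordance). The PR curve uses non-interpolated average precision
(precision summed over recall increments), the standard untrapped
estimator; under heavy negative imbalance AUPRC degrades while AUROC is
stable, which is why both are reported. Pooled CV scores give a single
curve; per-fold averaging is deliberately not offered.

## Motif tools

Top- and bottom-weighted kmers export as consensus-delta PWMs:
probability $1 - 3\alpha$ on the kmer's base per position, $\alpha = 0.01$
elsewhere (keeping log-odds finite), in MEME minimal format, at most 50
kmers per request. Scanning reports the maximum of
$\sum_j \log_2 (p_j(b_j)/q(b_j))$ over all offsets and both strands (bits,
uniform background by default, `N` contributing 0) — the classical
single-PWM baseline the kmer-SVM is compared against. PWM pairs are
compared column-wise under three per-position scores — Pearson correlation
of the 4-vectors, negated Euclidean distance, and the Sandelin–Wasserman
score $2 - \sum_b (p_b - q_b)^2$ — maximized over ungapped offsets and
both orientations with at least 4 aligned columns, reporting the mean
per-column score. Raw similarity ranking replaces null-model E/q-values,
which belong to dedicated motif-comparison software.

## The synthetic benchmark

The generator emulates the structure of a ChIP-seq training problem
without any downloads: iid background at a stated GC with one planted
occurrence per motif per sequence (uniform position, random strand), a
toy multi-chromosome genome with contiguous 1-kb soft-masked stretches,
and seeded byte-determinism throughout. The standard conditions are
**1000 positives × 100 bp** (the element length used when extending peak
midpoints), **AAGGTC planted at 0.9**, **GC 0.42**, **10× negatives**,
spectrum kernel with $k = 6$, $C = 1$, $E = 10^{-5}$, $PSW$ auto, 5-fold
CV. Two auxiliary scenarios are fixed alongside: a *repressor* variant
planting the palindrome CACGTG at 0.5 in negatives only (its weight must
come out negative — absence predicting the positive class), and a
*combinatorial* set of 500 positives requiring at least one of two
accessory kmers (GGGTAC, TTAGCC, each at 0.6), on which the kmer-SVM's
pooled CV AUROC is compared against the best single delta-PWM.

What passing these benchmarks does **not** show: real regulatory sequence
has dinucleotide structure, repeat families, copy-number and mappability
artifacts, and motif grammar (spacing, orientation) that iid background
cannot exhibit; planted consensus kmers are sharper than degenerate
binding sites. The benchmark validates the machinery — feature map,
matching, training, calibration, evaluation — not biological effect sizes.

## Numerical and design choices

- Coordinates are 0-based half-open BED throughout; FASTA wraps at 60
  columns; ids are headers up to the first whitespace.
- Non-ACGTN codes are mapped to `N` with a warning (tolerant ingestion);
  all-N sequences profile as `gc = 0` with an `gc_defined = FALSE` flag.
- Canonicalization uses the lexicographic minimum; palindromic kmers are
  counted once per occurrence (no doubling).
- Ranked tables break weight ties lexicographically; motif-match ties
  break by target name — all outputs are deterministic.
- `split_genome` starts windows at multiples of $c - v$; a final short
  window is emitted only when at least $c/2$ bp would remain uncovered,
  avoiding near-empty windows at chromosome ends. Sequences shorter than
  the smallest $k$ score as the bias alone, with a flag.
- Problem sizes in the test suite (hundreds of sequences for unit tests,
  the 11 000-sequence standard benchmark for end-to-end checks) are the
  package's standard benchmark conditions; the full benchmark trains in
  about a minute on one core.

## Limitations

Exact-match spectrum kernels only — no mismatch, gapped, or
position-specific kernels, and no nonlinear kernels; single-label binary
classification; negatives are matched on three profile statistics only
(length, GC, repeat), not on dinucleotide composition; the Tomtom-style
comparison reports raw similarities, not significance. Genomes are held
in memory as character vectors with prefix-sum indices (~24 bytes/bp),
comfortable for toy and invertebrate-scale genomes; chromosome-by-
chromosome streaming for mammalian genomes is future work.
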