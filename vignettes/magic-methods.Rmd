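---
title: "Methods: signal-distribution enrichment of transcription factors and cofactors"
author: "magicr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signal-distribution enrichment of transcription factors and cofactors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magicr)
```

## The problem

Given a list of differentially expressed genes, which transcription factors
(TFs) and cofactors drove the change? Motif scanning cannot see cofactors
(they do not bind DNA), and ChIP-seq-based tools that first split genes into
"targets" and "non-targets" of each Factor must draw an arbitrary cutoff
through signal distributions that are heavily non-Gaussian — many genes carry
very low but detectable ChIP signal. The MAGIC approach implemented here
avoids the binarization entirely: for every ChIP-seq track it compares the
*full distribution* of peak signals over the query genes against the
distribution over a background list (the genes detectable in the experiment),
and ranks Factors by how strongly the query is shifted toward high signal.

## The signal matrix

The unit of evidence is a genes × tracks matrix of maximal ENCODE-style
narrowPeak `signalValue`s. Each gene is assigned a *domain* under one of
three definitions — gene body ± 1 kb, gene body ± 5 kb, or a promoter window
of 1 kb upstream of the TSS plus 300 bp downstream (strand-aware: the TSS is
`tx_start` on `+` genes and `tx_end` on `-` genes, and "upstream" means
5′-ward along the gene's strand). The matrix cell for (gene, track) is the
largest `signalValue` of any peak whose interval intersects the domain by at
least 1 bp; genes with no overlapping peak get 0, so every gene contributes
a value to the distributions below. All coordinates are treated as 0-based
half-open, the convention of the BED-family input files.

Two conventions deserve a note because the field genuinely varies:

* **Any-overlap vs summit-in-domain.** A peak is counted if it intersects
  the domain at all. This is the most permissive reading of "within the
  gene domain"; a summit-based rule would only move peaks at domain edges
  and is not implemented.
* **Duplicate symbols.** Annotations with several transcripts per symbol
  are collapsed to the union of the isoform extremes (one row per symbol is
  an invariant of the matrix), falling back to the longest individual span
  when duplicates disagree on chromosome or strand.

Tracks for Factors that were engineered into their cell line (CRISPR,
stable transfection) are flagged in the track manifest and excluded unless
requested, mirroring the two families of published matrices. Whether a
track is engineered is metadata supplied by the user; it is not inferred.

## The enrichment statistic

For one query list of size $X$ inside a background of size $N$ (both
filtered to the matrix's gene universe; the query is a subset of the
background), each track yields two empirical cumulative distribution
functions over ChIP signal $c$:

$$B(c) = \frac{1}{N}\sum_{i=1}^{N} \mathbf{1}[B_i \le c], \qquad
  Q(c) = \frac{1}{X}\sum_{i=1}^{X} \mathbf{1}[Q_i \le c].$$

The statistic is the one-sided supremum difference

$$D_{\sup} = \sup_c\, \big(B(c) - Q(c)\big),$$

which is large when query genes are concentrated at high signal (their
cumulative lags the background's). The supremum is evaluated on the grid of
distinct background values plus a point below the support where both
cumulatives vanish, so $D_{\sup} \ge 0$ always. Its argument — the
**Critical ChIP** — is the smallest signal value attaining the supremum;
query genes with signal *strictly above* it are the Factor's **target
genes**. When the supremum is only attained below the support the Critical
ChIP is $-\infty$ and the whole query is the target set.

**Triage.** A track with fewer than five target genes is triaged: reported
with its $D$ (negated in the raw-results file, the sorting convention) but
excluded from multiple-testing correction and scoring. Degenerate tracks
whose background top-tail mean is zero are triaged for the same reason —
they carry no usable signal.

**Tail enrichment.** With $n = \lceil 0.05\,X\rceil$ (floored at 1 so small
queries still have a tail), the ratio

$$r = \mu_q / \mu_b$$

compares the mean of the top $n$ query signals with the mean of the top $n$
signals in the whole background. Note that $r$ can be below 1 even for a
genuinely enriched Factor: the top $n$ of $N \gg X$ background genes are far
more extreme order statistics than the top $n$ of $X$ query genes.

**P-values.** A Kolmogorov–Smirnov test is performed on $N$, $X$ and
$D_{\sup}$ through the effective size $N_e = NX/(N+X)$. Four modes ship:

| mode | formula | character |
|---|---|---|
| `asymptotic` (default) | two-sided Kolmogorov survival at $\sqrt{N_e}\,D$ | what a stock two-sample KS routine reports; conservative here |
| `onesided` | $\exp(-2 N_e D^2)$ | one-sided tail, same scaling |
| `nested` | $\exp\!\big(-2\,\tfrac{NX}{N-X} D^2\big)$ | finite-population correction for $Q \subseteq B$ |
| `permutation` | empirical tail over resampled queries | exact for the nested scheme (compiled hot loop) |

The nested sampling scheme — the query is drawn from *within* the
background, which also contains its signals — violates the independence
assumption of the standard two-sample test. Under resampling without
replacement the variance of $B(c) - Q(c)$ carries a finite-population
factor, so the correct asymptotic scaling is $NX/(N-X)$, not $NX/(N+X)$;
the default is therefore systematically conservative (never
anti-conservative — verified against the permutation oracle in the test
suite), and `nested` or `permutation` should be used when calibrated
p-values matter. We keep the conventional form as the default because it is
what the method as published describes feeding to a KS routine, and because
conservatism only attenuates, never inflates, significance. No closed form
matches the permutation oracle to within its Monte-Carlo error at desk
sizes: with heavy zero-inflation the null distribution of $D_{\sup}$ is
strongly discrete, and the tie-induced error of any continuous
approximation (several percent) dwarfs the oracle's standard error at
$10^5$ resamples. The test suite quantifies both gaps rather than hiding
them.

**Correction and Score.** Raw p-values of the non-triaged tracks of one
query are Benjamini–Hochberg corrected (each query list is its own family;
triaged tracks are removed *before* correction, since they are "not
considered further"). The ranking statistic is

$$S = -\log_{10}(P_{\mathrm{corr}}) \times r,$$

with $P_{\mathrm{corr}}$ floored at the smallest positive normalized double
before the logarithm. Base 10 is a display choice: a change of base rescales
every Score equally and cannot change ranks. Factors are sorted by
descending Score (ties: ascending corrected p, then track id — deterministic
output files); tracks with $P_{\mathrm{corr}} < 10\%$ are flagged
significant, and where a Factor has several tracks the best-scoring one
represents it in the summary table.

## Output surface

`run_magic()` writes, per query: a Details table (nine statistical columns
plus a significance flag), a best-track-per-Factor Summary, a GMX gene-set
file (background, query, then one column of target genes per significant
Factor) consumable by GSEA, an auxiliary directory with raw results for
*all* tracks (triaged D values negated), the query sub-matrix and triage
listings, per-significant-Factor target CSVs, and — optionally — CDF
diagnostics (background and query cumulatives, the Critical ChIP line,
per-gene ticks, and lollipop markers on the $n$ top-signal genes of each
list) plus a Score bar graph. Tables are plain tab-delimited text; re-running
the pipeline on its own `Accepted_Lists.txt` and `Platform_Matrix.txt`
reproduces the report byte-for-byte (filtering is idempotent).

## Evaluation protocol

To benchmark ranked Factor predictions against an experiment in which one
Factor was manipulated, the positive class is that Factor plus its
*potential interactors*: partners in a protein-links table with combined
score strictly greater than 300 (the 75th percentile of STRING combined
scores). Each algorithm's best-first Factor list becomes a **calls vector**
with scaled ranks $i/m$; a Factor listed at several ranks contributes one
call per entry.

* **PR/ROC.** Treating $1 - \text{scaled rank}$ as the score, standard
  precision–recall and ROC point sets are swept out with no class
  balancing (the classes are imbalanced, so PR is the headline metric).
  AUCs are trapezoidal areas over the emitted points; an
  average-precision variant of the PR AUC is available because generic
  curve routines differ in exactly this choice, which moves the second
  decimal.
* **Rank cumulatives.** The scaled ranks of positive calls — after
  collapsing each contiguous block of positives to the rank of its first
  element — are cumulated into $D(r)$, and the excess $D(r) - r$ over the
  uniform baseline is the curve of interest. The emitted polyline traces
  the exact step function, so its trapezoidal AUC is the exact integral.
  Distributions from two conditions are compared with a two-sample KS test
  on the block-adjusted rank samples.
* **Weighting.** Curves or AUCs can be multiplied by the fractional rank
  $F_R = 1/\text{rank}$ of the manipulated Factor, folding "did it call
  the right Factor first" into "did it recover the interactome".

Symbol matching is case-insensitive and exact; no alias resolution is
attempted.

## Synthetic validation data

Because the real matrix requires bulk ENCODE downloads, every pipeline
stage is validated on generated fixtures:

* **Signal matrices** (`simulate_magic_matrix()`): per track, each gene is
  zero with probability 0.6 and otherwise log-normal(meanlog 1, sdlog 1) —
  a zero-inflated heavy-tailed law mimicking tracks with many weak but
  detectable sites. One planted track has the query genes' nonzero signals
  multiplied by a fold-change `effect` (default 3); `effect = 0` disables
  planting and serves as the null. The generator deliberately does *not*
  model correlated tracks, realistic genome coordinates, or chromatin
  state, so passing tests demonstrate statistical correctness of the
  machinery, not performance on real ENCODE data.
* **Peak fixtures** (`simulate_peak_fixture()`): genes laid on a synthetic
  chromosome far enough apart that domains never overlap, one short peak
  per nonzero cell placed at the TSS (inside all three domain
  definitions), signal values printed at full precision — so building a
  matrix from the emitted narrowPeak files reproduces the intended matrix
  exactly, exercising the whole reader/overlap/writer path.
* **Co-regulated backgrounds** (`simulate_coregulated_matrix()`): a
  universe in which the true background genes are systematically
  better-bound (log-mean shifted by 1) and the query is a null draw from
  that background. Running the analysis against the full universe instead
  of the proper background inflates low-FDR calls — the qualitative
  background-sensitivity phenomenon, asserted by a paired one-sided rank
  test over 50 replicates.
* **Ranked lists** (`simulate_ranked_list()`): a quality dial interpolating
  uniform shuffles (ROC AUC ≈ 0.5) and perfect orderings (PR AUC = 1) for
  the evaluation module.

Validation problem sizes — chosen as the smallest at which the asymptotics
and recovery rates stabilize — are 2000 genes × 50 tracks with queries of
100 for recovery and null calibration (20 replicates each), 1000 × 20 for
background sensitivity (50 replicates), instances up to $N = 1000$ for the
brute-force $D_{\sup}$ oracle, and $10^5$ permutation resamples per
instance for p-value calibration.

## Numerical choices and edge cases

* Kolmogorov survival: alternating series for $\lambda \ge 1$, the
  Jacobi-theta dual form below (the alternating series converges slowly
  near zero); clamped to $[0, 1]$.
* Critical-ChIP ties: the smallest attaining value, which maximizes the
  target set and is deterministic.
* $P_{\mathrm{corr}} = 0$ (possible only by underflow) is floored at
  `.Machine$double.xmin` before the log; Scores stay finite and ordered.
* Matrix files store 17 significant digits, so write→read round-trips are
  exact; malformed rows, duplicate symbols and ragged lines are rejected
  with the offending line named.
* Unreadable narrowPeak lines are skipped and counted in one warning;
  genes on chromosomes absent from a track get signal 0.

## Known limitations

The statistic inherits the background list's content: changing the
universe moves $B(c)$ and therefore $D_{\sup}$, its argument and every
p-value — this sensitivity is by design (and is what the background
sensitivity simulation measures), but it means results are only as
meaningful as the supplied background. Domains ignore distal enhancers
entirely. The default p-value mode is conservative under the nested
sampling scheme, as quantified above. Evaluation consumes symbol-level
ranked lists and link tables; mapping database-specific protein identifiers
to symbols is out of scope.
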