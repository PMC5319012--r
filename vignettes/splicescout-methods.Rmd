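---
title: "Detecting alternative splicing events with splicescout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting alternative splicing events with splicescout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicescout)
```

## The model

`splicescout` detects alternative splicing events (ASEs) — primarily
cassette-exon skipping, but also alternative donor/acceptor usage — between
sample conditions in RNA-seq data. It deliberately avoids isoform-level
abundance estimation: for complex genes, isoform quantification is
ill-posed, whereas individual splice junctions and per-base coverage are
directly observed. Two independent statistics are computed per candidate
exon, so that a call can be triaged by the kind of evidence behind it.

### Coordinates and structural scaffold

All internal coordinates are 0-based half-open; GTF (1-based inclusive)
and STAR `SJ.out.tab` (1-based intron first/last base) are converted at
the I/O boundary, so interval lengths are always `end - start` and a
junction is identified by its intron `(chrom, donor_end, acceptor_start,
strand)` with `donor_end` equal to one past the last exonic base of the
upstream exon.

From the annotation we derive **meta-exons**: maximal regions spanned by
transitively overlapping exons (minimum start to maximum end). Book-ended
exons — sharing a boundary but no base — are *not* merged, since they
share zero bases and merging them would fuse genuinely distinct exonic
units. Meta-exons partition the exonic bases of the gene and are the unit
at which events are called. Unstranded annotations are rejected outright:
the sense/antisense overlap classification that protects against
antisense-driven false positives is meaningless without strand.

Unannotated junctions inside a known gene are representable as
**incomplete isoforms**: two-exon transcripts reduced to flanking stubs of
50 bp (any positive stub length preserves the construction; 50 bp is large
enough to be visible in plots and smaller than most exons) ending at the
junction donor and starting at its acceptor.

### The greedy PSI score

For a sample $s$, one inclusion junction (intron abutting the target
meta-exon) and one exclusion junction (intron spanning it):

$$\mathrm{PSI}_s = \frac{n^{incl}_s}{n^{incl}_s + n^{excl}_s}$$

on size-factor-adjusted counts. A single junction measures inclusion
because terminal exons are only ever supported by one junction, and exons
connected to multiple neighbors have imbalanced neighboring junction
counts; a greedy single-junction estimate sidesteps both. All
inclusion/exclusion combinations for a meta-exon are scored and the pair
with the largest absolute between-condition difference in mean PSI wins.
Ties are broken by larger total adjusted count (more evidence), then by
smallest junction coordinates (determinism). Per-sample PSI values are
compared across the two conditions with a Welch t-test; the unequal-
variance form is the robust default since nothing guarantees equal PSI
variance across conditions. A sample with zero counts on both junctions
carries no information about inclusion; its PSI is undefined and excluded
from means and tests rather than imputed. When the winning pair contains
an unannotated junction, the best known-only pair is reported alongside
it, so a call never rests invisibly on an unvalidated junction.

### The coverage-ratio test

With $m_c(p)$ the mean adjusted coverage of condition $c$ at base $p$,

$$r(p) = \frac{m_A(p)}{m_A(p) + m_B(p)}$$

is constant across all exons whose inclusion does not change (at
$\tfrac{f}{f+1}$ for an overall expression ratio $f$), regardless of
expression differences — which is exactly what makes it useful: a global
expression shift moves the plateau, not the shape. The defined ratios of
each nucleotide of the query exon group are tested (Welch) against the
per-group mean ratios of the remaining exon groups. Using group means on
the background side keeps the background sample size honest (one value per
group rather than thousands of autocorrelated bases) and makes the test
conservative when the gene has few exons: with fewer than two remaining
groups, or fewer than two covered target bases, the result is flagged
untestable instead of being forced. Bases where both conditions have zero
coverage have undefined ratio and are excluded (and drawn as gaps, not
zeros).

The ratio is a two-condition construct; projects with more conditions are
analyzed over all unordered condition pairs.

### Isoform pre-selection and exon groups

Before ratio testing, isoforms containing exons with insufficient coverage
are discarded: a transcript is kept iff every exon has at least
`min_frac = 0.7` of its bases at mean adjusted coverage `min_depth = 5` in
at least one condition. Unexpressed isoforms otherwise drag unexpressed
exons into the background group set and dilute the test. If nothing
qualifies, the best-scoring transcript is kept — a gene is never left
without a scaffold. "Exon groups" are then simply the meta-exons of the
selected isoforms; junction-level detection is not affected by the
selection, since junction counts are observed data regardless of
annotation.

### Candidate assembly

A candidate is emitted per meta-exon and condition pair when either test
passes (defaults: $p \le 0.05$ and $|\Delta| \ge 0.1$; changes below
10–15% inclusion are rarely biologically compelling, which motivates the
delta gate). The support class records which path passed. P-values are
used to *sort* the list, not to make calibrated discovery claims — no
multiple-testing correction is applied for filtering, though a
Benjamini–Hochberg column is included for reference. Only exon-skipping
events supported by both tests are highlighted on the meta-exon track:
other event classes are more easily confounded by unexpressed isoform
selection. Genes with no junction evidence yield no candidates. Signed
deltas (`mean_A - mean_B`, with conditions in sorted label order) are
reported so that swapping condition labels negates them; thresholds apply
to the absolute value.

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `p_threshold` | 0.05 | probability | conventional screening level; sorts rather than certifies |
| `min_delta_psi` | 0.1 | PSI (fraction) | below ~0.1–0.15 events are weak and poorly reproducible |
| `min_delta_ratio` | 0.1 | ratio (fraction) | same scale and rationale as PSI |
| `min_depth` | 5 | mean adjusted reads/base | below this, "covered" is mostly noise |
| `min_frac` | 0.7 | fraction of exon bases | tolerates ragged exon edges while rejecting unexpressed exons |
| novel-junction flank | 50 | bp | visible stub size; any positive value preserves the construction |
| `intron_px` | 50 | base-equivalents | fixed plotted intron width in compressed mode |

All are overridable from the CLI, whose defaults are the library defaults
(single source of truth).

## Size factors

The console tool estimates per-sample size factors by median-of-ratios on
per-meta-exon coverage sums: the reference per region is the geometric
mean over samples (regions containing zeros are excluded), a sample's
factor is the median ratio to that reference, and factors are rescaled to
geometric mean 1 to make them identifiable. This estimator is the standard
count-based normalization in differential-expression practice and is
deliberately compatible with externally supplied factors (a `size_factor`
project column or `--size-factors` file takes precedence). Whether factors
derive from whole-genome bins or gene regions is a genuine design freedom;
we compute them from the gene loci under analysis, which keeps the tool
self-contained and is documented as this package's choice. Counts and
coverage are *divided* by the factor, so scaling a sample's data by $f_s$
and passing those factors is exactly a no-op — a property the test suite
asserts.

Whether PSI should use adjusted or raw junction counts is not decidable
from first principles (PSI is a within-sample ratio, so the factor cancels
whenever both junctions share it); we adjust by default and expose
`raw_junction_psi` as a switch. With shared per-sample factors the two
options are numerically identical.

## Tissue specificity

The tau index over $n \ge 2$ tissues,
$\tau = \sum_i (1 - x_i/x_{max})/(n-1)$, is 0 for uniform expression and 1
for single-tissue expression, is scale-invariant, and never decreases when
a non-maximal tissue is zeroed. It is the standard specificity index with
exactly the 0–1 semantics required here, and is our declared choice of
score; per-meta-exon scores are computed columnwise from a tissue ×
exonic-part TSV matrix.

## The synthetic generator

`sim_scenario()`/`simulate_counts()`/`simulate_reads()` emulate a
single-gene experiment: a 5-exon gene (exons 200 bp, introns 300 bp —
typical compact mammalian geometry) with an inclusion and a skipping
isoform, a central cassette exon with per-condition true PSI (defaults
0.8 vs 0.3), 3 samples per condition and depth 200. Junction counts follow
$n^{incl}_s \sim \mathrm{Binomial}(N_s, \mathrm{PSI}_c)$,
$n^{excl}_s = N_s - n^{incl}_s$, $N_s \sim \mathrm{Poisson}(depth \cdot
libsize_s)$; constitutive junctions are independent Poisson draws; exonic
coverage is piecewise-constant at the isoform-weighted depth with per-base
Poisson noise. The binomial model matches PSI's definition and yields
analytic expectations; everything is deterministic under a fixed seed.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: positional coverage biases (GC, fragmentation,
3' bias), read-level artifacts (soft-clipping, multimappers), overdispersed
biological replicate variability beyond Poisson, overlapping gene
expression leaking into coverage, and annotation errors. Results on the
generator certify the statistical machinery, not robustness to library
artifacts.

## Numerical choices and degenerate inputs

* Welch t-test throughout; when both groups are constant the test is
  degenerate and we return $p = 1$ for equal means, $p = 0$ otherwise.
  Fewer than two defined values in either group yields an undefined
  p-value, which can never pass a threshold.
* Quantile bands in plots use linear-interpolation percentiles
  (`quantile type 7`), pinned so that vector output is byte-stable.
* Junctions with zero counts across all samples are dropped at merge; they
  cannot influence any PSI.
* Strand of an undefined-strand junction is inherited from a matching
  annotated intron, else from the unique gene containing it; otherwise it
  stays undefined and is usable only as a novel junction.
* Rendering is pure: identical inputs and spec give byte-identical SVG.

## Problem sizes used in the shipped checks

The test-suite simulations use the generator's default conditions: 500
replicates for delta-PSI recovery and detection rate, 100 null replicates
for the type-I check, 200 replicates for ratio-test calibration, and 100
random instances per combinatorial oracle comparison. These sizes give
two-digit stability on the reported rates while keeping the whole suite
fast on a single CPU.

## Known limitations

* Intron retention is not called, and completely novel genes are invisible
  (novel junctions are only represented within known genes).
* The PSI path needs at least 2 samples per condition with defined PSI;
  single-replicate designs yield undefined p-values by design.
* The ratio test needs at least three expressed exon groups; two-exon
  genes are untestable on that path.
* P-value sorting is not FDR control; the emitted BH column is advisory.
* GFF3 and CDS/UTR modeling are out of scope; annotation must be stranded
  GTF with `gene_id`/`transcript_id`.
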