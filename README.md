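# splicescout

Detection and visualization of alternative splicing events (ASEs) from
RNA-seq splice-junction counts and per-base read coverage.

Automated splicing callers produce long candidate lists riddled with false
positives, so candidates need evidence that can be inspected: which
junctions support the call, what the coverage looks like, and whether an
overlapping transcript could explain the signal. `splicescout` scores each
candidate exon with two independent lines of evidence and renders static,
publication-ready views of both, aimed at bioinformaticians analyzing bulk
(or pooled single-cell) RNA-seq experiments with two or more sample
conditions.

## Method

The unit of analysis is the **meta-exon**: the chromosomal region defined
by the minimum start and maximum end of all transitively overlapping
annotated exons of a gene. For each meta-exon and each pair of conditions:

**1. Junction-pair PSI score.** Every junction whose intron abuts the
meta-exon is an *inclusion* junction; every junction whose intron spans it
is an *exclusion* junction. For a sample *s* with size-factor-adjusted
counts *n<sub>incl,s</sub>* and *n<sub>excl,s</sub>*, the percent spliced
in is

&nbsp;&nbsp;&nbsp;&nbsp;PSI<sub>s</sub> = n<sub>incl,s</sub> / (n<sub>incl,s</sub> + n<sub>excl,s</sub>)

This is a deliberately greedy, single-junction estimate: terminal exons are
supported by only one junction, and exons connected to several neighbors
have imbalanced neighboring junction counts, so summing junctions can
mislead. All inclusion/exclusion combinations are scored and the pair with
the largest between-condition PSI difference is kept (ties: larger total
count, then smallest coordinates); per-sample PSI values are compared with
a Welch t-test. If the best pair involves an unannotated junction, the best
pair using only known junctions is reported alongside it.

**2. Coverage-ratio test.** At each base *p*, with *m<sub>c</sub>(p)* the
mean adjusted coverage of condition *c*,

&nbsp;&nbsp;&nbsp;&nbsp;r(p) = m<sub>A</sub>(p) / (m<sub>A</sub>(p) + m<sub>B</sub>(p))

is flat across constitutive exons and deviates at differentially included
ones. The per-nucleotide ratios of the query exon group are tested (Welch)
against the per-group mean ratios of the remaining exon groups of the
gene, after an automated isoform pre-selection discards isoforms containing
exons with insufficient coverage.

A candidate is emitted when either test passes (default p ≤ 0.05 and
|Δ| ≥ 0.1) and is labeled `psi_only`, `ratio_only` or `both`; exon-skipping
candidates with `both` support are highlighted on the meta-exon track of
the isoform plot. Library-size differences are corrected with
median-of-ratios size factors estimated from per-meta-exon coverage sums
(compatible with user-supplied factors, e.g. from DEXSeq). A tau index
(0 = unspecific, 1 = single-tissue) scores tissue specificity of genes and
exonic parts from an expression matrix.

## Worked example

Simulate a 3 + 3 sample cassette-exon experiment (true PSI 0.8 vs 0.3),
then run the pipeline:

```sh
SS="$(Rscript -e 'cat(system.file("cli", "splicescout", package = "splicescout"))')"
Rscript "$SS" simulate    --out demo --seed 11
Rscript "$SS" sizefactors --project demo/project.tsv --gtf demo/annotation.gtf --out demo/sf.tsv
Rscript "$SS" detect      --project demo/project.tsv --gtf demo/annotation.gtf \
                          --size-factors demo/sf.tsv --out demo/results.tsv
Rscript "$SS" plot        --project demo/project.tsv --gtf demo/annotation.gtf \
                          --gene SIMGENE --results demo/results.tsv --out-dir demo/plots
```

`demo/results.tsv` (columns abridged):

```
gene     meta_exon_start  meta_exon_end  event_type     delta_psi  psi_pvalue  delta_ratio  ratio_pvalue  support_class  highlight
SIMGENE  2000             2200           exon_skipping  0.513      3.1e-04     0.227        5.3e-204      both           TRUE
```

The caller recovered the simulated cassette exon at chrS:2000–2200: the
best junction pair estimates a PSI difference of 0.51 (truth 0.5), the
cassette exon's coverage ratio deviates from the constitutive background by
0.23 (expected 0.8/(0.8+0.3) − 0.5 ≈ 0.23), both tests pass, and the event
is highlighted in red on the meta-exon track of
`demo/plots/SIMGENE.isoforms.svg`. The same objects are available
programmatically: `sim_scenario()` / `simulate_counts()` /
`detect_events()` / `render_coverage()` etc.; see the package help and the
methods vignette (`vignettes/splicescout-methods.Rmd`).

### Input formats

* **Project file** — TSV with header
  `sample condition bigwig junctions [size_factor]`, one row per sample
  (paths relative to the project file).
* **Junction counts** — STAR `SJ.out.tab`
  (`chr1  1001  2000  1 1 1 15 0 30`: 1-based intron first/last base,
  unique-read count in column 7) or minimal TSV
  (`chr1  1000  2000  15`: 0-based `donor_end`, `acceptor_start`, count).
* **Coverage** — bigwig (`.bw`) or bedgraph (`chr1  0  10  5.0`).
* **Annotation** — Ensembl/GENCODE-style GTF with `gene_id` and
  `transcript_id` attributes.
* **Tissue expression** — TSV, first column `tissue`, remaining columns
  named `chrom:start-end`.

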