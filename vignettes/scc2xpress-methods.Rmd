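---
title: "Methods: models, statistics and design choices in scc2xpress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, statistics and design choices in scc2xpress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scc2xpress)
library(GenomicRanges)
```

# Scope

scc2xpress packages the computational stages used to dissect the
gene-expression and translation phenotype of a budding-yeast cohesin-loader
(*scc2*) mutant: metagene ChIP-seq profiling of gene groups, a
junction-based splicing-efficiency statistic (Percent Spliced Out, PSO),
MA/enrichment summaries of expression tables, Kolmogorov–Smirnov (KS)
comparison of flow-cytometry distributions, dual-luciferase
translational-fidelity calculators, and maximal-growth-rate estimation.
Every stage can run on seeded synthetic inputs, so the complete pipeline is
testable without any external download.

Differential-expression testing itself is deliberately out of scope: DE
tables (log ratios and adjusted p-values) are *consumed*, as produced by a
negative-binomial DE tool, and only summarised here.

# Coordinates and containers

Internally all intervals are `GRanges` (1-based, inclusive), the native
convention of the Bioconductor stack. BED input (0-based, half-open) and
GFF3/GTF input (1-based, inclusive) are converted losslessly on import by
rtracklayer, so a BED feature `chr1 100 200` is the range 101..200 and its
`+`-strand TSS is base 101 (0-based 100). Aligned reads are a
`GRangesList`, one element per read holding its blocks; a read with more
than one block is a split (junction-spanning) read. BAM blocks come from
the CIGAR (`N` gaps), BED12 blocks from the block fields.

# Metagene profiling

ChIP reads are single-block; each is anchored at its 5′ end and extended in
the 3′ direction to 150 bp (the approximate fragment size) before coverage
is computed. Coverage is normalised to reads per million (RPM = raw ×
10⁶ / library size). For a gene group, the RPM values at every offset in
−600..+600 bp around each gene's TSS are averaged per base, after
orienting − strand windows so that negative offsets are always upstream in
transcription sense.

Parameters and defaults:

* `target_len = 150` bp — extension length; reads already at least this
  long are left unchanged (never trimmed).
* `width = 600` bp — half-window; 1201 profile points.
* Window positions that fall off a chromosome contribute 0 *and remain in
  the denominator*: profiles keep a fixed length, at the cost of a
  documented downward bias at contig edges.
* Anchors are an ordinary width-1 `GRanges`, so any anchor definition
  (TSS, gene midpoint, summit) can be supplied; `anchors_from_annotation()`
  implements the TSS convention used for all gene groups, including
  gene-body-bound classes such as tDNAs and snoDNAs.
* No mapping-quality filter is applied by default (`min_mapq = NULL` in
  `read_alignments()`); whether ChIP reads should be MAPQ-filtered before
  coverage is left configurable.

# Percent Spliced Out

For one splicing unit (an intron with its two flanking exons), PSO is

> PSO = 100 × (junction-spanning read count) / (mean per-base read-block
> coverage over the two flanking exons)

A read supports the junction only when two consecutive blocks leave an
inner gap *exactly* equal to the annotated intron; a `tolerance` argument
(default 0 bp) can relax each boundary. Exact matching is conservative and
unambiguous; tolerant matching is exposed rather than guessed. The
denominator is Σ(block coverage over both exons) / (summed exon length).

Numerical conventions:

* PSO is not capped at 100: short exons under deep junction support can
  legitimately exceed it.
* Exonic coverage 0 yields a *missing* PSO (`NA`, reason "no coverage"),
  never 0; such units are dropped from testing with a logged count.
* Units whose exonic coverage is below 1 read-per-base are flagged
  `low_confidence` but still reported.
* Junction matching ignores strand: library strandedness is not modelled.

Per unit, a one-way fixed-effects ANOVA of PSO against genotype (on raw
percentages, no variance-stabilising transform) gives an F statistic and
p-value; p-values are Benjamini–Hochberg adjusted *across units* (each
analysis family — splicing units, GO terms — is adjusted separately, never
pooled). Degenerate inputs are handled explicitly: zero between-group
variance gives F = 0, p = 1; zero within-group variance with distinct
means gives F = ∞, p = 0.

# Expression summaries

* `ma_transform()`: M = log₂((cond + ε)/(ref + ε)), A = geometric mean of
  the pseudocounted values. ε defaults to 0.5 RPKM — large enough to tame
  zeros, small against typically expressed genes.
* `classify_de()`: DE iff adjusted p < α (default 0.05), direction by the
  sign of M, optional |M| cutoff; the total is up + down by construction.
* `fold_change_threshold(1.5)` = |log₂ 1.5| = 0.585, displayed as 0.6.
* `hypergeom_enrichment()`: upper-tail P[X ≥ x] including the observed
  overlap — the standard over-representation convention.

# Cytometry: KS distance with a replicate baseline

Each sample's ECDF is right-continuous (`F(x)` = fraction ≤ x); the KS
distance D is the supremum difference over pooled observed values. D is a
rank statistic — invariant under monotone transforms — which suits
non-Gaussian fluorescence distributions.

With ~10,000 cells per sample the KS *test* is significant for trivially
small shifts. The decision rule therefore uses the biological replicates as
an effect-size baseline: a genotype pair is flagged as a distribution shift
only when **every** between-genotype D exceeds the **maximum**
within-genotype D *and* every between-pair p < α (default 0.05). The exact
small-sample p is used when n·m ≤ 10⁴ and there are no ties; otherwise the
Kolmogorov asymptotic with effective size nm/(n+m). Gating is configurable
(`gate`, default 0 = no gating for non-negative data).

# Dual-luciferase calculators

All quantities are built from the firefly/renilla ratio of each well, which
cancels lysate amount and instrument gain:

* frameshifting efficiency = 100 × ratio(frameshift construct) /
  ratio(0-frame control);
* readthrough = 100 × ratio(stop-codon reporter) / ratio(sense reporter);
* IRES activity = 100 × ratio(strain) / ratio(reference strain).

Replicates are aggregated as the ratio of per-construct replicate means
(robust to single-well renilla noise); a paired per-replicate mode is
available, as the aggregation order is not dictated by the formulas.
Strain comparisons use a pooled-variance two-tailed Student t-test (Welch
available), report SEM, and withhold p below 3 replicates. All four
quantities are exactly invariant under a common plate-gain factor.

# Maximal specific growth rate

μ_max is the steepest slope of ln(OD) versus time over a sliding window of
consecutive points — the usual plate-reader definition; no parametric
growth model is fitted. Two numerical choices matter:

* **Weighting.** Plate-reader noise is approximately additive in OD, so
  after the log transform its variance scales as 1/OD². Window fits are
  therefore weighted least squares with weights OD² (`weighted = TRUE`).
* **Window size.** A calibration study on noiseless and noisy logistic
  curves (r = 0.6 h⁻¹, K = 1, N₀ = 0.02, 10-min sampling, additive
  σ = 0.005) showed that short (5-point) windows are noise-dominated at low
  OD — taking a maximum over many noisy slopes inflates μ_max severely —
  while very long windows under-estimate it through logistic curvature.
  15 points (2.3 h at 10-min sampling) balances the two: on noiseless
  logistic input the estimate stays within 5% of r, and under σ = 0.005
  noise it is within 10% of r in ≈93% of runs. `window_points = 15` is the
  default; the window and its weighted r² are reported with the estimate.

Blank handling: OD is used as supplied by default (`blank = 0`), because a
curve that is already background-subtracted — or an exact exponential —
must not be re-blanked; `blank = "first"` or a numeric blank is available.
Non-positive ODs after blanking exclude a window. μ_max is exactly
invariant under rescaling all ODs by a constant.

# The synthetic-data generators

`sim_config()` fixes one master seed; every generator call derives an
independent substream from the seed plus a stable stage key
(`"chip:WT:1"`, `"growth:scc2_4:2"`, …), so outputs are byte-identical
given `(seed, config)` and inserting one generator call never perturbs
another. Truth records are emitted beside the data; recovery tests read
truth only from these records.

What the generators emulate, and the default study conditions:

* **ChIP** (`gen_chip_reads`): uniform background reads over a 4 × 100 kb
  genome with 60 evenly spaced 1.5-kb genes; a 20-gene target group
  receives reads at `f` × background (f = 5 in the wild type, 2 in the
  mutant — a reduced but not abolished genic association), 2 replicates,
  200,000 single-block 50-bp reads per sample.
* **Spliced RNA-seq** (`gen_spliced_reads`): 20 two-exon transcripts with
  exon/intron lengths cycling through realistic yeast values (~150–310 bp
  exons, 80–140 bp introns). Each fragment is spliced with probability θ
  (θ = 0.9 wild type, 0.75 mutant — a modest splicing defect) and its
  start is uniform over the isoform positions that fit the 50-bp read.
  The truth table carries the analytic expected PSO from
  `expected_pso_enum()`, which enumerates every start position
  exhaustively — the oracle never touches the simulated reads. At
  practical depths the per-unit estimate carries visible counting noise
  (≈3 points at 10⁴ reads/unit), so calibration is assessed on the
  across-units mean splicing index, which the splicing module reports
  alongside per-unit values.
* **Cytometry** (`gen_cytometry`): log-normal intensities
  (meanlog = log 500, sdlog = 0.5), 10,000 cells, 2 replicates per
  genotype; the mutant distribution is scaled 1.5-fold.
* **Luciferase** (`gen_luciferase`): renilla around a plate mean with
  log-normal noise (CV 10%), firefly = renilla × construct ratio ×
  independent log-normal noise, 6 replicates. Construct ratios encode the
  configured truths: −1 frameshifting 1.1% (WT) vs 3.4% (mutant), +1
  frameshifting 8% in both, readthrough 0.3/0.6/1.0% (UAA/UAG/UGA) in
  both, IRES activity 60% of wild type in the mutant. At CV = 0 every
  estimator returns the truth exactly.
* **Growth** (`gen_growth`): logistic OD with additive Gaussian noise
  (σ = 0.005), sampled every 10 min for 12 h; r = 0.6 h⁻¹ (wild type)
  and 70% of that in the mutant, K = 1, N₀ = 0.02.

What they deliberately do **not** model: sequence content and sequencing
errors, fragment-length distributions, PCR duplicates, mappability,
strandedness of the RNA-seq protocol, cytometry instrument drift or
spectral spillover, plate position effects, and lag-phase physiology.
Passing recovery tests therefore demonstrates correctness of the
estimators under the stated statistical structure, not robustness to every
artefact of real data.

# Problem sizes in the shipped tests

The test and acceptance runs use the default generator conditions above
(200,000 ChIP reads/sample; 10⁴ reads/unit for PSO recovery; 200
simulations for the cytometry null/power and frameshift-recovery rates;
100 seeds for growth-rate recovery), which keep the whole suite at a few
minutes on one CPU while leaving Monte-Carlo margins that are wide
relative to the tested tolerances.

# Known limitations

* Feature counting is any-overlap with multi-assignment: a read spanning
  two features increments both. Union/strict modes are a planned flag.
* Paired-end mates are treated as independent reads.
* The metagene TSS anchor is applied to all gene groups; mid-gene
  re-anchoring for gene-body-bound classes can be achieved by passing
  custom anchors but is not automated.
* `extend_reads()` treats unstranded (`*`) reads as `+`.
* The pipeline driver runs the synthetic demonstration end-to-end;
  wiring arbitrary external BAM/annotation inputs through the YAML config
  is intentionally minimal, with the exported stage functions as the
  primary interface.

# A minimal end-to-end run

```{r pipeline, eval = FALSE}
cfg <- list(version = 1, seed = 11, outdir = "demo_run",
            sim = list(chip = list(depth = 20000L),
                       cytometry = list(n_cells = 2000L)))
run_pipeline(cfg)
```

The output directory then holds one TSV per stage (each headed by the tool
version and a parameter hash), `summary.json` with per-stage statuses, and
`run.log` with one provenance line per stage; a rerun with the same config
and seed reproduces the TSVs bit-for-bit.
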