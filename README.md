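# scc2xpress

Analytics for gene-expression and translational-fidelity phenotypes of
budding-yeast cohesin-loader (Scc2) mutants — and for any experiment with
the same data classes. The package covers the full downstream stack of such
a study:

* **Metagene ChIP profiling** — reads extended 5′→3′ to 150 bp, coverage in
  reads per million (RPM), averaged per base over a gene group in a
  ±600 bp strand-oriented window around the TSS.
* **Splicing efficiency (PSO, Percent Spliced Out)** — for each annotated
  intron with its flanking exons,
  `PSO = 100 · J / C̄`, where `J` is the count of split reads whose block
  gap matches the intron exactly and `C̄` the mean per-base read coverage
  over the two flanking exons; per-unit one-way ANOVA across genotypes with
  Benjamini–Hochberg correction across units.
* **Expression summaries** — MA quantities
  (`M = log2((cond+ε)/(ref+ε))`, `A =` geometric mean of RPKM), DE
  classification at adjusted p < 0.05 with an optional |log2 FC| cutoff,
  and upper-tail hypergeometric gene-set over-representation.
* **Cytometry** — two-sample Kolmogorov–Smirnov distance
  `D = sup|F_a − F_b|` between fluorescence ECDFs, with a
  replicate-baseline decision rule: a shift is called only when every
  between-genotype D exceeds the largest within-genotype D *and* all
  between-pair KS p-values clear α.
* **Dual-luciferase calculators** — programmed ribosomal frameshifting
  efficiency (100 × ratio(PRF construct)/ratio(0-frame control)),
  stop-codon readthrough (100 × ratio(stop)/ratio(sense)) and IRES
  activity (100 × ratio(strain)/ratio(reference)), all built on the
  firefly/renilla ratio and exactly plate-gain invariant.
* **Growth** — maximal specific growth rate μ_max as the steepest
  OD²-weighted sliding-window slope of ln(OD) versus time.
* **Seeded synthetic data** — generators for every input class with truth
  records, so the complete pipeline runs and is testable offline.

Differential-expression model fitting (negative-binomial testing) is out of
scope: DE tables are inputs, not outputs.

## Worked example

Synthetic dual-luciferase plates and growth curves with the default study
conditions (−1 frameshifting 1.1% in WT vs 3.4% in the mutant; growth
0.6 h⁻¹ vs 70% of that):

```r
library(scc2xpress)

cfg <- sim_config(seed = 42)
plate <- gen_luciferase(cfg)$plate
pick <- function(st, role)
  plate[plate$strain == st & plate$construct_role == role, ]

sapply(c("WT", "scc2_4"), function(st)
  frameshift_efficiency(pick(st, "minus1_PRF"),
                        pick(st, "zero_frame_control")))
#>     WT scc2_4
#>   1.00   3.21

g <- gen_growth(cfg)$curves
sapply(c("WT", "scc2_4"), function(st) {
  d <- g[g$strain == st & g$replicate == 1, ]
  max_growth_rate(d$time_min, d$od)$mu_max
})
#>     WT scc2_4
#>  0.556  0.467
```

The mutant plate reads ≈3.2% −1 frameshifting against ≈1.0% in the wild
type — a ≈3-fold loss of reading-frame maintenance recovered from noisy
wells (CV 10%, n = 6) — and the noisy logistic curves give μ_max within a
few percent of the generating rates (0.6 and 0.42 h⁻¹). An end-to-end run
over every stage:

```r
run_pipeline(list(version = 1, seed = 11, outdir = "demo_run"))
```

writes one TSV per stage, a JSON summary and a provenance log into
`demo_run/`.

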