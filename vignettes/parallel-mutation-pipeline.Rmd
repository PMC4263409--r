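---
title: "Detecting parallel adaptive mutations in evolve-and-resequence data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting parallel adaptive mutations in evolve-and-resequence data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evoreseq)
```

## The problem

Whole-population ("pooled") sequencing of experimentally evolved bacterial
populations yields, for every population, a table of variants with allele
frequencies rather than clonal genotypes. Under weak selection in rich
media, populations accumulate hundreds of segregating mutations, almost all
of them non-adaptive. Within one polymorphic population an adaptive
mutation is indistinguishable from a hitchhiker; across *independently*
evolved replicate populations, however, adaptive targets reveal themselves
by recurrence: mutations keep arising in the same gene. The probability
that independent populations all acquire mutations in one specific gene by
chance is

$$p \;=\; \prod_s \left(\frac{1}{G_s}\right)^{n_s},$$

where $G_s$ is the number of annotated genes in species $s$ and $n_s$ the
number of its populations carrying a hit. At the scale of two
enterobacterial genomes (4565 and 5068 genes) and 12 + 12 populations this
is $10^{-88}$ — recurrence at that level is selection, not luck
(`random_parallelism_probability()` evaluates this in log space).

The catch is that a low detection floor (frequency 0.05, an order of
magnitude above the sequencing error rate) lets *systematic* false
positives through: errors in the reference assembly, misresolved
duplications, repeats, and methylation-sensitive positions recur across
every sample at nearly the same frequency and perfectly mimic parallel
evolution. The pipeline's job is to remove them without touching the real
signal, then quantify parallelism at the gene, subsystem and proteome
levels.

## The filtering cascade

`run_pipeline()` applies the stages in a fixed order, logging counts at
each step:

1. **Frequency floor** (`apply_frequency_floor()`): calls below 0.05 are
   dropped. The floor is *inclusive* — "a minimum frequency of 0.05" is
   read literally, so a call at exactly 0.05 survives.
2. **Effect selection** (`select_nonsynonymous()`): analysis focuses on
   protein-consequential classes — amino-acid substitutions, stop gains,
   frameshifts and in-frame indels. SNP effects are classified under the
   bacterial genetic code (translation table 11).
3. **MA-control blacklist** (`build_ma_blacklist()`): mutation-accumulation
   lines pass through daily single-colony bottlenecks, so selection is
   minimal and independent lines cannot plausibly acquire the *same*
   mutation repeatedly. Any site called in ≥ 4 of the MA lines (aligned
   with the same polymorphism-aware pipeline as the populations) is
   blacklisted and removed everywhere. The blacklist is keyed by
   (contig, position), not by allele — removal is site-level. The
   threshold of four lines is where the removal count stabilizes in the
   original analysis; it is a parameter (`ma_min_lines`).
4. **Levene's-test artifact filter** (`levene_artifact_filter()`): for
   species without MA controls (or in addition to them), sites whose
   frequencies are suspiciously *uniform* across treatments are removed.
   Real mutations arise at different times in different genetic
   backgrounds, so their frequencies spread; systematic artifacts sit at
   the same frequency everywhere. For each site observed in at least 2
   populations of *each* medium, per-treatment frequency vectors are
   compared with Levene's test and the site is removed when the spreads do
   **not** differ (p ≥ α).

Three Levene-filter choices were genuinely open and are worth recording:

* **Absent populations contribute frequency 0.** The source procedure is
  silent on this. Zeros encode "mutation absent", which makes
  treatment-restricted variants high-variance (retained) and
  omnipresent artifacts low-variance (removed) — matching the filter's
  stated intent. `include_absent = FALSE` drops absentees instead.
* **α = 0.05** by default (not stated in the source procedure);
  configurable and logged. Note the operating characteristic is inverted
  relative to an ordinary test: the *null* (equal spread) triggers
  removal, so about 5% of true artifacts survive the filter by chance.
  The MA blacklist catches these for the species that has MA lines.
* **Center = mean** (Levene's original statistic) because the procedure
  names Levene's test; `center = "median"` (Brown–Forsythe) is available.

Untestable sites (too few observations) are always retained — the filter
is conservative with respect to discovery.

## Parallelism statistics

`gene_mutation_matrix()` counts calls per gene × population;
`parallelism_summary()` reports per gene the number of populations with a
hit (presence, the figure-panel quantity), total mutations, and unique
alleles (deduplicated by position/ref/alt), sorted with lexicographic
gene-id tie-breaking so output is reproducible. `parallelism_histogram()`
keeps true counts and applies display caps only to a separate column.
`cumulative_gene_frequency()` sums all allele frequencies of a gene per
population; sums above 1 (possible with noisy co-segregating alleles) are
flagged, never capped, because capping would hide data problems.
`flag_mutators()` operationalizes "visibly more mutations than replicate
populations" as a Tukey fence (count > Q3 + 1.5·IQR within
species × medium); the source analysis identifies mutators visually, so
the rule, its `k`, and a median-multiple alternative are all explicit
parameters. `unique_allele_spectrum()` profiles a gene's alleles,
localizes them to protein domains (e.g. receiver 1–123 vs DNA-binding
124–238 for an arcA-like regulator) and reports the effect-class
composition that separates fine-tuning spectra (substitutions only) from
knockout spectra (stop/frameshift-rich).

`subsystem_score()` computes, per functional subsystem,
$(m_s/g_s)/(M/G)$ — the subsystem's mutated-gene fraction relative to the
genome-wide fraction. When subsystems partition the genome the
gene-count-weighted mean score is exactly 1 (a unit-test identity). Genes
without an assignment are pooled into an explicit `"unassigned"`
pseudo-subsystem so the partition identity holds; they can be excluded
upstream. "Mutated" is presence-based within one species × medium panel.

## Population proteomics

`rollup_proteins()` converts peptide log2 abundances to protein profiles:
samples are median-aligned, each peptide is centered by its own
across-sample mean, centered peptides are averaged per sample (missing
values ignored), and the protein's grand mean is added back. This
centered-mean roll-up is deterministic and order-free; the reference
implementation in the DAnTE lineage does not pin down its variant, so a
median-based alternative is selectable. `differential_test()` runs a
classic one-way ANOVA (equal-variance F) of ancestor vs evolved samples
per protein — the pooled two-group design is the default because the
headline comparison is "ancestor vs evolved populations"; a per-population
multi-group design is available. `significance_filter()` applies the dual
threshold p ≤ 0.01 **and** |log2FC| > 0.7; the p boundary is inclusive,
the fold-change boundary exclusive, and no multiple-testing correction is
applied, faithfully to the procedure it reproduces (a correction option
exists). A protein must be observed in ≥ 2 ancestor replicates to be
testable; undetected protein × population cells stay missing in
`functional_heatmap_table()` — never imputed as zero.

## What the synthetic generator emulates

`simulate_experiment()` produces complete experiments with truth labels so
every filter can be scored against known ground truth:

* **Design**: two species-like genomes (desk scale 500/550 genes,
  study scale 4565/5068), 12 populations per species × medium (LB, BHI),
  12 MA lines (first species only, as in the design it mirrors), two
  mutator populations per medium with an 8× mutation load.
* **Neutral load**: Poisson(15) non-synonymous variants per population
  (×8 in mutators) at uniform coding positions, with synonymous variants
  at a 1:3 ratio purely to exercise the effect filter. Frequencies are
  Beta(1,9) draws resampled as Binomial(depth 200)/depth — pooled
  sequencing noise — and truncated at the 0.05 detection floor.
* **Drivers**: an arcA-like regulator hit with probability 1.0 (LB) /
  0.75 (BHI) carrying 1 + Poisson(2) co-segregating alleles whose
  frequencies partition a Beta(9,3) cumulative frequency (mean 0.75), and
  an rpoS-like regulator (hit probability 0.4) whose BHI alleles are
  loss-of-function with probability 0.8.
* **Artifacts**: 30 sites per species planted in *every* evolved
  population and MA line at 0.12 ± 0.005. They are deliberately **not**
  binomially resampled: they model systematic pipeline errors, not
  sampling noise, and their removal is what the Levene filter's power
  rests on.
* **MA lines**: Poisson(8) private variants per line at frequencies
  0.8–1.0 — near-fixed but polymorphic, as clonal samples grown to high
  density for DNA isolation can be.

All draws flow from one master seed through named substreams
(`genome:sp1`, `drivers:sp2`, …), so identical seeds give byte-identical
datasets and individual stages can be regenerated.

Free parameters not pinned by the design it emulates were fixed once for
realism: gene lengths are log-normal(meanlog log 300, sdlog 0.35) codons —
a typical enterobacterial coding-length distribution with moderate
dispersion — and the driver cumulative-frequency distribution is Beta(9,3)
to center on 0.75. Ref/alt alleles at a site are derived deterministically
from the position so that recurrent draws of one site represent the same
allele, as recurrent mutations do.

What the generator does **not** emulate: read-level data (no FASTQ, no
alignment), within-experiment temporal dynamics (no Wright–Fisher
trajectories — only final-timepoint frequency tables are analyzed),
linkage between variants, sequence-context mutation biases, and indel
realignment ambiguity. Passing tests therefore demonstrate that the
*statistical logic* of the cascade is sound under its stated assumptions,
not that any particular aligner's error profile is handled.

## Numerical and degenerate-case choices

* Levene's statistic: 0/0 (all deviations identical) returns W = 0,
  p = 1 — indistinguishable spreads; a zero denominator with non-zero
  numerator returns W = ∞, p = 0. Groups with < 2 observations make a
  site untestable (retained).
* The mutator fence needs ≥ 4 populations per group; smaller groups warn
  and flag nothing.
* `random_parallelism_probability()` works in log10 space; the linear
  value underflows to 0 below ~1e-308 and the log is the authoritative
  output.
* Generation arithmetic is exact: `log2(dilution_factor)` per transfer,
  so 100-fold daily transfers give 6.64 generations/day (~6.6; 498 ≈ 500
  over 75 days) and 40,000-fold give 15.29 (~15.2; 764 ≈ 765 over
  50 days). The single-colony bottleneck variant (29.4 generations per
  colony transfer) requires per-colony CFU counts, which are not part of
  any input here; the same log2 helper applies to
  `log2(cells per colony)` when counts exist.
* Problem sizes in the shipped tests: desk-scale genomes (120–550 genes),
  20-replicate recovery simulations, 1000-instance oracle comparisons,
  10,000-protein null matrices — sizes chosen so the full suite exercises
  every claim in minutes on one core.

## Known limitations

* The Levene filter retains ~5% of true artifacts at α = 0.05 by
  construction; pair it with MA controls where available.
* Gene-level parallelism counts inherit any surviving artifact site: a
  single uniform-frequency site places its gene at the top of the
  presence ranking. The audit table (`levene$results`) and the unique
  allele count (`n_unique_alleles` of 1 with maximal `n_populations` is
  the signature) are the diagnostic.
* The Tukey fence on small replicate groups (n = 12) has a non-trivial
  false-positive rate in groups with genuinely homogeneous counts;
  flagged populations are reported, not excluded, and exclusion decisions
  stay with the analyst via `pipeline_config(exclude_populations=)`.
* Effect classification assumes the supplied coding sequence and offset
  are consistent; it does not re-align indels or handle multi-codon
  substitutions.
* The proteomics module tests mean shifts between groups; it does not
  model peptide-level random effects or shared-peptide ambiguity
  (each peptide maps to exactly one protein).
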