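---
title: "Dual-assay methylome comparison: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-assay methylome comparison: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methdual)
library(dplyr)
```

## The problem

MeDIP-seq and MRE-seq interrogate DNA methylation from opposite sides:
immunoprecipitation read density rises with methylated-CpG density, while
methylation-sensitive restriction enzyme reads mark *un*methylated CpG sites
at fragment ends. Together they cover the whole genome — including intergenic
space, introns and transposable elements that methylation arrays never see —
at the cost of giving counts rather than per-CpG methylation fractions.
`methdual` implements the comparative pipeline built on this pairing:
tumor-vs-normal differential methylation at 500 bp resolution, recurrence and
type-preferred consensus across tumor samples of two cancer types, regulatory
annotation of the resulting differentially methylated regions (DMRs), and
validation in an independent beta-value cohort of the kind produced by
Infinium arrays.

Everything is exercised against a synthetic-data generator, so the package is
testable end to end without any external download. This vignette records the
models, the tunable parameters, and the design decisions that were genuinely
open.

## The window test

The genome is tiled with non-overlapping 500 bp windows (0-based half-open
coordinates throughout, the BED convention; windows are the unit of analysis
and of reporting). For one tumor-vs-normal comparison, each window with at
least one CpG is tested as follows.

For the MeDIP assay, conditioning on the pair total $T = x_n + x_t$ removes
the nuisance scale: under no methylation difference, the tumor count is
$x_t \mid T \sim \mathrm{Binomial}(T, p_0)$ with
$p_0 = s_t / (s_n + s_t)$, where each exposure $s$ is the library total times
the window's copy-number factor. The mid-p one-sided tail of this conditional
binomial is converted to a signed normal score $z_M$ (positive = tumor
enriched). The MRE assay gives $z_R$ the same way. Because MRE signal is
anti-correlated with methylation, the combined statistic flips its sign:

$$Z = \frac{z_M - z_R}{\sqrt{2}},$$

with a two-sided p-value from the standard normal, direction `hyper` for
$Z > 0$ and `hypo` for $Z < 0$. If one assay has no reads in the window pair,
$Z$ is the other assay's score alone; if neither has reads, $p = 1$.

Numerical choices:

* **Mid-p tails.** Using $P(X > x) + \tfrac12 P(X = x)$ rather than a closed
  tail makes the score zero (and $p = 1$) exactly at the symmetric null —
  equal counts under equal exposures — instead of inheriting a discreteness
  bias. It also makes the score exactly antisymmetric under swapping the
  normal and tumor labels; the implementation evaluates whichever tail is
  smaller so this antisymmetry holds in floating point too.
* **Tail floors.** One-sided tails are floored at $10^{-300}$ before the
  inverse-normal transform to avoid infinities.
* **Degenerate windows.** Windows with zero CpGs are excluded before testing
  *and* before multiple-testing correction: both assays are CpG-conditional,
  so such windows carry no information and would only dilute the
  Benjamini-Hochberg (BH) family.
* **CNV as exposure.** Copy-number factors enter multiplicatively in the
  exposures (an offset in the conditional null), not by rescaling observed
  counts; a window amplified twofold in the tumor needs twice the reads to
  provide the same evidence. When per-enzyme MRE counts are available,
  enzymes are rescaled to equal totals before pooling to absorb
  enzyme-efficiency differences.

BH correction is applied per pairwise comparison, over exactly the tested
windows, and calls are windows with $q < 10^{-5}$. This statistic is a
deliberately transparent integration of the two assays with the same decision
surface as published integrative callers for this data type (500 bp windows,
two count tracks in, one q-value and a direction out); it makes no claim to
reproduce any specific published likelihood, and every piece of it is
verifiable by enumeration or simulation.

## Consensus rules

With three tumors per cancer type, a window is a **type consensus DMR** when
at least 2 of the 3 comparisons call it with the same direction. A 2-vs-1
direction conflict resolves to the majority; an exact tie (possible for other
configuration sizes) yields no call. **Shared DMRs** are windows that are
consensus in both types with equal direction. **Type-preferred DMRs** are
called in all three comparisons of one type and in none (either direction) of
the other. DMRs are reported at window resolution; `merge_adjacent_dmrs()`
optionally collapses adjacent same-direction windows and is off by default.
These rules are tested by exhaustive enumeration of all $3^3 \times 3^3$
pairwise-call configurations against an independent oracle.

## Annotation

The feature catalog derives CpG-island **shores** as the flanking 1 kb on each
side of an island with island bodies subtracted (a shore never overlaps any
island), **introns** as gene bodies minus exons, and **intergenic** space as
the genome minus gene bodies and promoters. Core promoters are 1 kb around
the TSS (500 bp each side).

* **Exclusive context.** For context fractions each DMR gets one label with
  priority promoter > exon > intron > intergenic; island/shore/TE membership
  is reported as independent flags. The priority order is this package's
  choice — enrichment reporting uses overlapping membership, so nothing is
  lost by the exclusive label.
* **Enrichment score.** For a feature and a DMR set,
  $ES = (n_{hit}/n_{DMR}) / (N_{hit}/N_{all})$ on the window frame. The score
  itself carries no test, so a one-sided binomial test (success probability
  $N_{hit}/N_{all}$ over $n_{DMR}$ trials) is attached, BH-corrected across
  the feature batch, keeping the display convention of flagging features with
  $ES > 5$ and significant q. Effect size and significance stay separate.
* **Chromatin states.** Per cell line, a window's dominant state is the state
  covering strictly more than 50% of its bases (an exact 50/50 tie gives
  none). Merging across cell lines gives promoter precedence: a window is
  `promoter` if any cell line's dominant state maps to a promoter state,
  `enhancer` if any maps to enhancer and none to promoter, else `other`. The
  label-to-class map is an argument (`default_state_map()`), since chromatin
  vocabularies differ between segmentations.
* **Developmental patterns.** Three-letter words over (stem cells, normal
  tissue, cancer). The mapping is forced once one accepts that a cancer-hyper
  DMR implies the normal tissue is unmethylated there and vice versa: cancer
  hypo with stem cells matching normal is MMU; hypo where normal is more
  methylated than stem cells is UMU; hyper with no stem-cell difference is
  UUM; hyper where normal is less methylated than stem cells is MUM.
  Inconsistent combinations (e.g. hyper where normal exceeds stem cells) get
  `NA` rather than a forced word.
* **Profiles.** Chromosome-scale profiles use RPKM
  ($count / (\mathrm{bin\ kb} \times \mathrm{library\ millions})$) in 500 kb
  bins, averaging fold changes across same-type tumors before the log2
  transform; bins with zero reference RPKM are missing. The genome-wide
  density comparison uses 5 kb bins of library-normalized MeDIP density and
  labels bins beyond a fold threshold (default 2; the threshold is this
  package's convention, as is taking fractions over bins with nonzero normal
  signal).

## Cohort validation

Probe beta values are quantile-normalized across samples. For each DMR
carrying at least one probe, the average methylation level (aML) of a group
is the plain mean over the group x probe block (missing values excluded with
the denominator reduced), and the methylation change is
$DMC = aML_{cancer} - aML_{normal}$. Significance comes from a two-sided
Mann-Whitney U test on **per-sample probe-mean betas**, so $n$ equals the
number of biological samples; pooling probe-level values (available via
`unit = "probe"`) inflates $n$ with correlated observations and is not the
default. For pooled sizes up to 12 the p-value is computed by full
enumeration of group assignments (correct under ties); larger samples use the
tie-corrected normal approximation. BH runs across all testable DMRs of the
batch; untestable DMRs (no probes, or no non-missing values in a group) are
excluded from the family. A DMR is **validated** iff $q < 0.05$,
$|DMC| > 0.05$ (strictly), and the observed direction matches the prediction.

## What the generator emulates — and what it does not

`generate_genome()` builds a toy genome: 2 chromosomes of 2 Mb (the second
"X-like"), ~45,000 CpGs from a clustered background process (Poisson cluster
centers, geometric cluster sizes of mean 5, 60 bp Gaussian spread, mean rate
0.01/bp) with a 10-fold rate elevation inside ~40 CpG islands per chromosome,
~25% of CpGs flagged as MRE-assayable sites, 60 gene models per chromosome
with exons and 1 kb core promoters, generic miRNA-like and lncRNA-like TSS
lists, and a transposable-element catalog of 5 subfamilies (three flagged
enhancer-like for the chromatin-state simulator).

`plant_methylomes()` assigns the pooled-normal profile a low baseline (~0.1)
in island/promoter windows and a high one (~0.8) elsewhere, then plants 60
DMR windows per class (type-preferred for each type, and shared), half hyper
and half hypo, at latent effect size 0.6, plus a contiguous hypomethylated
block (latent drop 0.3) covering ~55% of the X-like chromosome in one type
only, emulating chromosome-scale demethylation. DMRs are planted only in
windows with at least 10 CpGs (~2x the genome mean): a window with a handful
of CpGs carries almost no count information in either assay, and real DMRs
concentrate at CpG-supported loci (islands, shores, CpG-bearing TEs). The
stem-cell profile departs from normal at half the planted windows per
direction so that all four developmental patterns arise by design. Two
copy-number blocks per tumor (factors 2 and 0.5, ~20 windows each) exercise
the CNV normalization.

`simulate_counts()` draws MeDIP counts as
$\mathrm{Poisson}(d \cdot cnv \cdot m \cdot c/\bar c)$ and MRE counts as
$\mathrm{Poisson}(d \cdot cnv \cdot (1-m) \cdot r/\bar r)$, with $c$, $r$ the
window's CpG and MRE-site counts and $\bar c$, $\bar r$ their genome means;
$d = 30$ expected reads per window per assay is the default sequencing depth.
The linear response of each assay to $m$ and $1-m$ is the simplest model
consistent with the assays' semantics. `simulate_probe_cohort()` places
probes at CpGs with a 3-fold weight inside islands/promoters (the array
design bias), strips probes from 30% of planted DMR windows (so
probe-coverage reporting is exercised), and draws beta values from a Beta
distribution with mean equal to the group latent level and precision 50,
for 20 samples per group by default.

Not modeled: read-level artifacts (fragment sizes, GC and CpG-coupling bias),
per-enzyme MRE site structure (MRE sites are a random CpG subset; the enzyme
rescaling path is still exercised through its own interface), inter-individual
variation within the pooled normal (the study design pools the normals, so
this is unidentifiable; a jitter parameter stands in), and realistic
chromatin-state transition structure. Passing tests therefore demonstrate
that the statistics, rules and bookkeeping are correct and well-calibrated
under a faithful count model — not that the caller's power on real libraries
matches the synthetic numbers.

## Problem sizes and determinism

Default scale — 8,000 windows, 8 methylomes (normal, 3 + 3 tumors, stem
cell), 7 pairwise comparisons, a 60-sample probe cohort — runs the full
pipeline in well under a minute on one CPU; the test suite's recovery and
null-calibration studies use the same scale with 20-seed replication where
calibration is asserted. Every generator and the pipeline are deterministic
given a seed: `run_pipeline()` derives one sub-seed per stage from the master
seed, so any stage can be re-run in isolation.

The no-effect control used for calibration sets planted classes, the X-like
block, copy-number blocks and the per-sample jitter all to zero, so that only
assay (Poisson) noise remains and any call is a false positive. With jitter
on, tumors differ from normal by real (if tiny) latent amounts, which is a
different null.

## Known limitations

* The window test's normal combination is slightly conservative at very low
  counts (mid-p tails under-reject); at the default depth this is negligible.
* Direction conflicts in consensus resolve by majority; for even numbers of
  comparisons, ties yield no call rather than a deterministic tie-break.
* `validate_dmrs()` treats the probe-mean per sample as one observation; DMRs
  whose probes straddle heterogeneous methylation are averaged, as in the
  aML definition.
* The enrichment test's binomial background treats windows as exchangeable;
  it does not model window-to-window correlation of features.
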