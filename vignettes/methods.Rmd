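---
title: "Models and methods behind sweepscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sweepscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`sweepscan` scans SNP-array genotypes for selective sweeps by contrasting
groups of populations with two statistics: a creeping-window
Weir–Cockerham F~ST~ and hapFLK. This vignette lays out the models, the
parameters that matter, the numerical choices, and what the synthetic-data
generator does and does not emulate. It states no empirical claim beyond
what the package's tests and acceptance script themselves compute.

## Study design the package targets

The intended design is a case/control contrast of prolificacy: several
related low-prolificacy populations versus a diverged high-prolificacy
population, all genotyped on a medium-density array (tens of thousands of
autosomal SNPs, here sheep autosomes 1–26). Groups are defined from total
prolificacy (TP, the lifetime lamb count): `TP <= 3` controls, `TP >= 7`
cases, anything between unassigned and excluded from the scans. The two
thresholds are arguments of `assign_groups()`.

## Quality control

`qc_filter()` applies three filters in a fixed order, each computed on the
set surviving the previous step: samples with missingness strictly above
5%, SNPs with call rate strictly below 95%, SNPs with pooled minor allele
frequency strictly below 5%. The order — sample filters before variant
filters — follows the convention of the standard PLINK workflow; it is
fixed and covered by a test because filter order changes the counts at the
margins. Removal is by strict inequality, so values exactly at a threshold
survive. Monomorphic SNPs that survive QC stay in the dataset but are
undefined for every differentiation statistic.

Relatedness is estimated with the KING-robust between-family estimator
$\hat\phi_{ij} = (N_{het,het} - 2N_{opp}) / (N_{het}(i)+N_{het}(j))$
counted over jointly non-missing SNPs. `prune_related()` removes greedily
(highest number of above-threshold partners first, ties by sample order)
until no retained pair exceeds the cutoff. The default cutoff 0.354 is the
conventional duplicate/monozygote boundary — the geometric midpoint between
the expected values for duplicates (0.5) and first-degree relatives (0.25);
the source workflow this package generalizes states the goal of pruning
but not its cutoff, so the value is a documented, configurable default.

## Weir–Cockerham F~ST~ and the creeping window

For r groups with per-group sample sizes $n_i$, allele frequencies $p_i$
and observed heterozygote proportions $h_i$ (all computed on non-missing
calls per SNP), the estimator's components are

$$a = \frac{\bar n}{n_c}\left[s^2 - \frac{1}{\bar n - 1}\left(\bar p(1-\bar p) - \frac{r-1}{r}s^2 - \frac{\bar h}{4}\right)\right],\quad
b = \frac{\bar n}{\bar n-1}\left[\bar p(1-\bar p) - \frac{r-1}{r}s^2 - \frac{2\bar n-1}{4\bar n}\bar h\right],\quad
c = \bar h/2,$$

and $\theta = a/(a+b+c)$, undefined when $a+b+c=0$. The scan defaults to
r = 2 (case pool versus control pool); `grouping = "population"` gives the
r = 4 per-breed variant.

Windows span 10 adjacent SNPs and advance one SNP at a time (the
"creeping" window). The window statistic is the arithmetic mean of the
defined per-SNP θ values; negative values are kept (clamping and the
conventional multi-locus ratio-of-sums $\sum a / \sum(a+b+c)$ are options).
Windows with fewer than half their SNPs defined are dropped. Significance
is an empirical percentile: the top fraction of windows (ties included),
default 0.001. The default is deliberately configurable because percentile
conventions in this literature are inconsistent ("top 0.01" may mean 1%,
0.1% or 0.01% depending on the source); 0.1% reproduces the typical count
of significant windows at array scale. SNP-count windows are the primary
mode; fixed 600-kb windows (`bp_windows()`) serve the common
results-presentation style.

## The haplotype-cluster model

hapFLK needs local haplotype frequencies without a fixed haplotype
definition. The fastPHASE-style model treats each haplotype as a mosaic of
K latent clusters: between SNP l and l+1 the chain jumps with probability
$\rho_l$ (shared across clusters) to a cluster drawn from the weights
$\alpha_{l+1,\cdot}$, else stays; cluster k emits allele 2 at SNP l with
probability $\theta_{lk}$. Unphased genotypes use the product chain over
ordered cluster pairs; because the pair transition factorizes, the forward,
backward and expected-jump recursions all stay O(K²) per SNP per sample
(implemented in C++, scaled to avoid underflow at any genome length).

Choices worth knowing:

* **Pooled fit.** One model is fitted on all populations jointly and
  per-population cluster frequencies are extracted afterwards from the
  posteriors. Fitting per population would break cluster identity across
  populations and invalidate the cross-population comparison.
* **Initialization.** $\alpha$ rows from a symmetric Dirichlet,
  $\theta$ from pooled frequencies plus N(0, 0.1) noise, $\rho$ from
  $1-e^{-\Delta d}$ on the genetic map when informative (a forced break at
  chromosome boundaries) else 0.02. Run i of `n_runs` is seeded with
  `seed + i - 1`; identical seeds are bit-reproducible.
* **Clamping.** Emission frequencies live in [1e-4, 1-1e-4] to keep EM
  away from degenerate fixed points; $\rho$ in [1e-6, 1-1e-6].
* **Convergence.** EM stops when the log-likelihood improves by less than
  `tol` (default 1e-4) or at `max_iter` (default 100). The trace is
  non-decreasing by the EM guarantee; a parameter block whose expected
  counts vanish keeps its previous value (a generalized-EM step, still
  monotone).
* **Identifiability.** With per-SNP free weights, cluster *labels* are
  only locally identifiable — two equally good fits can permute labels
  along the genome. Tests therefore score the recovered mosaic by
  label-invariant co-assignment agreement, not by global label matching.
  hapFLK itself is label-invariant.

## Kinship, FLK and hapFLK

Population structure is summarized by the drift covariance **F**:
`reynolds_distance()` computes the classic Reynolds coancestry distance
from allele frequencies, `build_kinship()` builds a neighbor-joining tree,
roots it at the midpoint (the design assumes no outgroup), clamps negative
NJ branch lengths to zero, and reads $F_{ij}$ as the shared root-to-MRCA
drift. One scale subtlety is handled explicitly: between two populations
that each accrued drift f since their split, the Reynolds distance
converges to the *average* (f, not 2f) of the branch drifts, so NJ path
lengths are doubled to put **F** on the additive scale where
$\mathrm{Var}(p_i) = F_{ii}\,p_0(1-p_0)$. Without that factor the FLK
statistic runs at twice its degrees of freedom; with it, the null
calibration test (mean ≈ npop−1, 1% above the χ² 99th percentile) passes
with the kinship *fitted from the same data*, because the fitted branch
lengths absorb finite-sample noise in the frequencies.

FLK whitens the frequency deviations:
$\hat p_0 = \frac{1^T F^{-1} p}{1^T F^{-1} 1}$, and
$\mathrm{FLK} = (p-\hat p_0 1)^T [\hat p_0(1-\hat p_0) F]^{-1} (p-\hat p_0 1)$,
χ² with npop−1 df under neutrality; SNPs with $\hat p_0 \in \{0,1\}$ are
undefined. hapFLK replaces p by the stacked per-population cluster
frequencies: with kinship-weighted ancestral cluster frequencies q, the
cluster covariance is $S = \mathrm{Diag}(q) - qq^T$ truncated to K−1
dimensions, the covariance of the stacked residuals is $S \otimes F$, and
the statistic is $\mathrm{tr}(F^{-1} R S^{-1} R^T)$, averaged over the EM
runs. A pseudo-inverse replaces $S^{-1}$ at rank-deficient SNPs, with a
reported count. K = 1 gives identically zero; a perfectly informative
2-cluster model reduces hapFLK exactly to FLK (both are tested).

Raw hapFLK is standardized genome-wide, $Z = (raw - \overline{raw})/SD$,
and p-values default to the upper-tail standard normal on Z. The
methodological literature describes both a χ² and a normal reading of
these p-values; the normal reading matches how scans of this design are
reported, so it is the default and `law = "chisq"` is the alternative.
SNPs in the top fraction (default 0.001) are flagged and consecutive
flagged SNPs merge into regions.

The kinship for hapFLK is estimated over the declared populations (4 in
the target design), not the 2 pooled scan groups — hapFLK's point is to
model hierarchical structure — while the F~ST~ scan pools; both choices
are arguments.

## Region annotation

Internal coordinates are 1-based inclusive; BED I/O converts to and from
0-based half-open (tested in both directions). Regions get ±200-kb flanks
clamped to [1, chromosome length]; annotation names are reported on ≥1-bp
overlap with the flanked region. Regions found by both statistics
(≥1-bp overlap across methods) are merged and labeled `both`. Gene and QTL
sources are user-supplied interval files; live database queries are out of
scope.

## The synthetic-data generator

The generator emulates the target design's structure: a population tree
with Balding–Nichols drift (child frequency Beta-distributed around the
parent with variance $c\,p(1-p)$; c is the expected F~ST~ of the branch),
founder-pool haplotype mosaics for LD, injectable sweeps, i.i.d.
missingness, and a uniform [0.05, 0.95] ancestral frequency law echoing
array ascertainment. Defaults: 4 populations (3 related + 1 diverged) with
group sizes 56/84/49/249 matching the target design, 26 chromosomes ×
1622 SNPs (~42k), 50-kb marker spacing, founder pool M = 50, switch rate
0.05 per interval. Branch drifts (0.02 shared, 0.015 tips, 0.03 diverged)
were set once so that the realized between-group windowed F~ST~ lands near
0.05 — the genome-wide level typical of this breed contrast — after
accounting for the ≈1/M extra drift a finite founder pool adds.

Two modes matter for validation. The finite-founder mosaic is the
realistic mode (LD, haplotype structure) and is what the sweep-power tests
use. For calibration properties stated under the island model (mean θ
equals the drift parameter; FLK null calibration), tests use
`n_founders = Inf`, which draws haplotypes site-wise Bernoulli from the
tip frequencies: that *is* the island model those properties describe,
with no founder bottleneck and no LD. A sweep is a haplotype-frequency
displacement — one founder driven to carrier frequency ≥ s (default 0.9)
over the span — not a selection-coefficient trajectory: the scan
statistics respond to frequency and haplotype differentiation, which is
the signal being validated.

What the generator does **not** emulate: array ascertainment bias beyond
the ancestral-frequency floor, variable marker density and recombination
hot spots, admixture and migration, genotyping error structure beyond
i.i.d. missingness, and real phenotypes. Passing tests therefore show the
estimators and the pipeline are correct and well calibrated under drift +
founder-LD conditions; they do not certify behavior under admixture or
strong ascertainment.

## Problem sizes used in tests

Unit tests run at small sizes (tens of samples, hundreds of SNPs). The
acceptance checks use the sizes their properties are stated at: 4
populations × 50 diploids × 5000 SNPs for calibration, and 20 sweep
replicates at the same scale for power, with the EM at K = 10, 3 restarts
and 25 iterations — restarts and iteration caps chosen as the point where
the power result stops changing, keeping the whole suite a few minutes on
one CPU. The pipeline's own defaults (K = 10, nfit = 20, max_iter = 100)
remain the analysis settings.

## Known limitations

* The unphased K² chain is exact but quadratic in K; K beyond ~20 on large
  cohorts becomes slow. Phased input scales linearly in K.
* The text PLINK dialect carries no allele-role designation; roles are
  inferred (minor allele first, ties lexicographic), so only the binary
  dialect preserves allele roles exactly.
* hapFLK p-values are reference-distribution approximations; for
  publication-grade inference on real data, empirical calibration against
  genome-wide permutations or null regions is advisable.
* The NJ/midpoint kinship assumes a tree-like history; admixed populations
  violate it and bias FLK.
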