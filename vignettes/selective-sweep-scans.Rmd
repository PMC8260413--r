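---
title: "Selective-sweep scans with sweepscan: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selective-sweep scans with sweepscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepscan)
```

## The problem

A recent, strong selective sweep leaves three correlated footprints in
population genomic data: elevated allele-frequency differentiation between
the selected population and its relatives, reduced nucleotide diversity, and
extended haplotype structure (slow linkage-disequilibrium decay). sweepscan
detects such sweeps in a fixed three-population design — **Target** (the
population hypothesized to carry the sweep), **Control** and **Background**
(two reference populations) — the design used in livestock studies that
contrast, say, thin-tailed dairy sheep breeds against two indigenous
fat-tailed breeds.

## Statistics

**Weir–Cockerham FST.** Per biallelic site, the two-population
variance-components estimator. With $r = 2$ populations of $n_1, n_2$ called
diploids, alternate-allele frequencies $p_1, p_2$ and observed heterozygote
proportions $h_1, h_2$:

$$\bar n = \tfrac{n_1+n_2}{2},\quad
  n_c = \frac{r\bar n - \sum n_i^2/(r\bar n)}{r-1},\quad
  \bar p = \frac{\sum n_i p_i}{r\bar n},\quad
  s^2 = \frac{\sum n_i (p_i-\bar p)^2}{(r-1)\bar n},\quad
  \bar h = \frac{\sum n_i h_i}{r\bar n}$$

$$a = \frac{\bar n}{n_c}\Big[s^2 - \frac{1}{\bar n - 1}\big(\bar p(1-\bar p)
      - \tfrac{r-1}{r}s^2 - \tfrac{\bar h}{4}\big)\Big],\qquad
  b = \frac{\bar n}{\bar n-1}\Big[\bar p(1-\bar p) - \tfrac{r-1}{r}s^2
      - \tfrac{2\bar n - 1}{4\bar n}\bar h\Big],\qquad
  c = \frac{\bar h}{2}.$$

The per-window estimate is the ratio of sums $\sum a / \sum (a+b+c)$ over
the SNPs of the window (the "weighted" estimator of standard VCF tooling).
Negative estimates are legitimate output of this estimator and are **not**
clamped by default; clamping before combining into LSBL would bias LSBL
upward. A `clamp_negative_fst` flag exists for sensitivity analysis.

**LSBL.** The locus-specific branch length isolates differentiation on the
Target branch of the three-population tree:

$$\mathrm{LSBL} = \tfrac{1}{2}\big(F_{ST}(T,C) + F_{ST}(T,B) - F_{ST}(C,B)\big).$$

Although the statistic is definable per site, sweepscan computes windowed
pairwise FST first (ratio of sums on an identical grid) and combines one
LSBL per window: the ratio-of-sums route is markedly stabler in sparse
windows. The per-site alternative (window mean of per-site LSBL) is
available behind `per_site_lsbl = TRUE`.

**Nucleotide diversity.** Per site, the mean pairwise difference among the
$n$ called alleles, $2j(n-j)/(n(n-1))$ with $j$ the alternate-allele count;
per window, the sum over SNPs divided by the *window size in bp* (not the
SNP count) — the convention of the common windowed-π tools.

**LD decay.** $r^2$ is the squared allelic correlation: counted over
haplotypes when phase is available (equal to $D^2/(p_A p_a p_B p_b)$),
otherwise the squared Pearson correlation of dosage vectors over jointly
called samples. Pairs are binned by distance; the **half-decay distance**
is the midpoint of the first bin (in increasing distance) whose mean falls
to half the maximum bin mean. That first-crossing rule is a stated
convention — the smoothing used by the original plotting tools before
reading off "half of maximum" is unpublished — and raw bin means from small
samples are noisy, so a pair-count-weighted monotone (isotonic) smoothing
option is provided and used wherever few sites survive the LD filter.

**Outliers and regions.** Thresholds are empirical top-percentile values
(default top 1%) with the R type-7 interpolation convention; windows
*strictly above* the threshold are outliers (ties excluded). Overlapping or
book-ended outlier windows merge into regions; a gene is assigned to a
region on ≥ 1 bp overlap. Because a published count of "regions with
FST and LSBL above their thresholds" can mean the union or the intersection
of the two window sets, the default combined set is the **union**, while
gene "sharing" is the **intersection** of the FST-derived and LSBL-derived
gene sets (matching the way such studies report "genes found by both
statistics"); a flag switches the window rule to intersection.

## Windows and coordinates

Windows span 50 kb with a 25 kb step, anchored at position 1 on every
chromosome (the grid origin is unstated in the source analyses; anchoring
at 1 is deterministic and makes grids from different runs comparable).
Windows are 1-based half-open `[start, start + size)` internally; merged
sweep regions are reported 1-based closed; exported BED is 0-based
half-open. Windows with fewer than `min_snps = 10` polymorphic sites carry
`NA` FST/LSBL (π is still reported; an empty window has π = 0). Sites
monomorphic in both populations of a pair contribute nothing to the window
sums.

## The SNP filter chain

The vcftools-style chain is reproduced as a `FilterSpec`: site QUAL ≥ 30,
biallelic only, mean depth in [4, 72], ≤ 10% missing genotypes (the
upstream flag "keep sites ≥ 90% called" inverts the number — stated
explicitly because the two conventions are easily confused), ≥ 2 non-
reference alleles, indels removed, optional MAF ≥ 0.05. A site failing
several criteria is counted once under the first failing criterion, in that
order. Multiallelic sites are dropped, not decomposed. Site QUAL (not
genotype GQ) feeds the quality rule, matching the upstream tool's
semantics. Mean depth comes from FORMAT/DP means or, failing that, INFO/DP
divided by the sample count; with neither, depth rules are skipped with a
warning.

## The synthetic data generators

Two simulators, deliberately: most statistical tests need controlled
*expectations*, not linkage, and a linked simulator is the slowest part of
any test suite.

**Balding–Nichols generator.** Each site draws an ancestral frequency
$p \sim U(0.05, 0.95)$ (the bounds avoid near-fixed sites that make the
variance components degenerate; configurable); each population draws its
frequency from a Beta with mean $p$ and variance $F p (1-p)$; genotypes are
binomial. Sites are unlinked, so windowed FST/LSBL/π expectations can be
computed by cheap Monte-Carlo integration of the same sampling model —
the oracle used by the acceptance tests. $F$ is per-population, so an
elevated Target branch ($F_T > F_C = F_B$) is the neutral-free analogue of
target-specific drift, and `inject_sweep_differentiation()` (Target
frequencies pushed toward fixation inside a region) is the cheap surrogate
for a completed sweep. Output is unphased.

**Forward Wright–Fisher simulator.** Discrete generations, diploid,
recombination (Poisson crossovers along the segment) and infinite-sites
mutation on an integer bp grid; burn-in of one ancestral population for
`10 * N_e` generations, a three-way split, then independent lineages with
an optional terminal bottleneck and an optional additive sweep (fitnesses
$1, 1+hs, 1+s$; the beneficial allele enters as a single copy at the split
and is resampled — by deterministic continuation of the seeded RNG
stream — up to 100 attempts if lost). Output is phased.

Defaults (the source study publishes no demographic parameters; these were
chosen once for testability and are not revisited): `N_e = 70` diploids,
`L = 300` kb, `mu = 2e-6` per bp per generation, `rho = 6e-7`,
`split_gens = 60`, bottleneck `(Target, N = 7, 30 generations)`. The
reasoning: θ = 4 N μ ≈ 5.6e-4 per bp gives realistic SNP density on a
segment simulable in ~2 s; the bottleneck size 7 mirrors both a 10× size
reduction and the 7-individuals-per-group subsampling used for LD in the
motivating study; and ρ is set so the binned r² of the non-bottleneck
lineage halves at ~30 kb — the half-maximum is crossed near
$C = 4 N_e \rho d \approx 5$ (Hill–Weir), not at $C = 1$, and the
small-sample r² floor (≈ 1/13 with 14 haplotypes) compresses the dynamic
range, which an earlier naive $1/(4N_e\rho)$ guess ignored.

**What the generators do not emulate:** real chromosome-scale
recombination maps and hotspots, gene conversion, mutation-rate
heterogeneity, realistic sheep demography (growth, migration, admixture),
background selection, and genotyping error. A green simulation test
therefore establishes that the estimators recover the parameters of *these*
models at the simulated scale — not that the pipeline's biological
conclusions on real data are correct.

## Numerical choices and degenerate inputs

* Window FST is `NA` when the component denominator sums to zero or fewer
  than `min_snps` SNPs are present; any `NA` pairwise FST propagates to
  LSBL.
* The exact Hardy–Weinberg test enumerates heterozygote counts conditional
  on allele counts and sums probabilities ≤ the observed one (two-sided);
  a `1e-12` slack on the comparison guards floating-point ties.
  Monomorphic sites give p = 1.
* `percentile_threshold()` requires ≥ 100 non-null values; thresholds use
  `quantile(type = 7)`.
* NJ ties in the Q-criterion break on the lowest current-index pair;
  negative branch lengths are clamped to zero with the deficit moved to the
  sister branch, preserving the joined pair's path length.
* All simulators restore the caller's RNG state; every stochastic function
  takes an explicit seed.
* TSV writers print doubles with `%.17g`, so write/read round-trips are
  exact.

## Known limitations

* One CDS chain per gene (the first transcript encountered); no splice,
  UTR or regulatory consequences; single-nucleotide substitutions only.
* No haplotype-based sweep statistics (iHS, XP-EHH), no inter-chromosomal
  LD, no enrichment analysis, no PCA/ADMIXTURE — deliberately out of scope.
* The Wright–Fisher simulator holds the per-generation crossover count at
  rate ρL along a uniform map; it is a test harness, not a demographic
  inference tool.
* Reproducing a specific published amino-acid label (e.g. a P107T call in
  a particular sheep gene) requires that genome's reference and annotation;
  the test suite proves the mechanism on constructed fixtures on both
  strands instead.
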