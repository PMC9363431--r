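---
title: "Scanning for repeated local adaptation across altitudinal transects"
author: "repadapt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning for repeated local adaptation across altitudinal transects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repadapt)
```

## The problem

When the same species independently colonises similar environments — here,
montane habitat at the upper end of an altitudinal range — selection can act
repeatedly on the same loci. Detecting that repetition requires replicated
sampling: three-population *transects* (a highland population, a nearby
lowland population, and a distant lowland population that controls for
isolation by distance), replicated both within and across sides of a
dispersal barrier. `repadapt` implements the full scan over such a design:
per-window differentiation statistics, data-driven candidate regions, formal
tests of whether candidate regions repeat across transects more often than
chance, whether independent selection signatures corroborate them, whether
the *same haplotypes* are involved, and whether the underlying variants came
from standing variation or introgression from an already-adapted relative.

## Differentiation statistics

Per site, Hudson's Fst is computed from Bhatia's unbiased components

$$\alpha = (p_1 - p_2)^2 - \frac{p_1(1-p_1)}{n_1 - 1} - \frac{p_2(1-p_2)}{n_2 - 1},
\qquad \beta = p_1(1-p_2) + p_2(1-p_1),$$

with $n$ counted in haplotypes, and windowed as the ratio of sums
$\sum\alpha / \sum\beta$ ("weighted" Fst) on a 5 kb / 1 kb sliding grid.
Pairwise Fst is clamped to $[0, 1)$ and transformed to a relative divergence
time $T = -\log(1 - F_{st})$; the population branch statistic for the
highland branch of a trio is

$$PBS_{high} = \tfrac{1}{2}\left(T_{high\text{-}low} + T_{high\text{-}dist} - T_{low\text{-}dist}\right),$$

which isolates allele-frequency change specific to the highland lineage.
Windows are z-normalised genome-wide per transect (population sd, ddof = 0)
so transects with different baseline drift are comparable; transects with
only two sampled populations fall back to a zFst scan.

Diversity statistics share the grid: nucleotide diversity uses the unbiased
per-site mean pairwise difference $2p(1-p)\,n/(n-1)$ divided by the full
window length (an accessibility mask can replace the denominator when one
exists); Tajima's D uses the standard Watterson constants for the
population's haplotype count; absolute divergence recovers the
between-population mean pairwise difference from pooled and within-group
diversities,

$$D_{xy} = \frac{\theta_{AB}\binom{n_{AB}}{2} - \theta_A \binom{n_A}{2} - \theta_B \binom{n_B}{2}}{n_A\, n_B},$$

with every $n$ a **haplotype** count — only then does the expression reduce
exactly to the mean between-population pair difference, which the test suite
verifies against exhaustive pair counting.

## Candidate regions and sharing

Windows with $z > 4$ (strict) become outliers; each contributes a
$\pm 50$ kb buffer around its centre, and overlapping or book-ended buffers
merge into High Differentiation Regions (HDRs). An HDR shared with the
same-side replicate transect is a SHDR; an allopatric SHDR additionally
overlaps at least one HDR in *each* opposite-side transect. Sharing
significance comes from re-placing each transect's intervals (same number,
same sizes, chromosome chosen proportional to length, uniform start) 10,000
times against the *observed* partner sets; placed intervals may collide and
are merged first, mirroring how observed HDRs arise from merged buffers.
Empirical $p = (1 + \#\{null \ge obs\})/(n_{perm}+1)$. A delete-one-block
jackknife (default 1 Mb blocks; HDRs assigned by midpoint) gives the 95% CI
of the observed proportion.

Because the sharing proportion over a handful of intervals is discrete, the
permutation p-value is stepped and conservative rather than exactly uniform
under the null; the suite checks calibration (rejection at $\alpha$ stays at
or below $\alpha$) rather than strict uniformity.

## Selection-signature enrichment

Each SHDR's minimum Tajima's D, minimum $\Delta\pi = \pi_{high} - \pi_{low}$
and maximum $D_{xy}$ are compared to extrema of 10,000 randomly placed
interval sets of the observed size profile (pooled across intervals; a
size-stratified option exists). The default tails follow the sweep
footprint — sweeps *depress* Tajima's D and $\Delta\pi$ (flag when the
observed minimum is below the null 10th percentile) and *elevate* $D_{xy}$
(flag when the observed maximum exceeds the null 90th percentile). The
one-sided 10% rule implies roughly 10% of null regions flag per statistic,
which the calibration suite confirms. A `tails = "literal"` switch applies
the alternative pairing (upper tail for Tajima's D, lower for the others)
for sensitivity analyses.

## Haplotype sharing: local PCA and the altitude model

A genome-wide ("global") PCA on non-outlier windows, thinned to 1 site per
10 kb, captures neutral structure; a local PCA over one SHDR's outlier
windows captures the haplotypes actually differentiated there. Dosages are
mean-imputed and column-centred; the decomposition is by SVD with the sign
fixed so the largest-magnitude loading is positive (reproducible under
sample reordering). The model

`local_PC1 ~ altitude_m + global_PC1`

asks whether altitude predicts clustering beyond neutral structure; variable
importance is LMG partial $R^2$ (the average of incremental $R^2$ over both
predictor orderings, exact for two predictors, so the two partials sum to
the model $R^2$). Altitude enters in metres; a class-coded variant is a
one-line change in the caller. Inversion-like regions are karyotyped by 1-D
k-means (k = 3, deterministically initialised at the minimum, median and
maximum of PC1); which homozygote cluster is "wild type" is metadata the
caller supplies, and a mean-silhouette diagnostic warns when PC1 is
unimodal and the three clusters are artefactual.

## Excess allele sharing

For a quartet ((P1 lowland, P2 highland), P3 donor), outgroup, derived
frequencies are polarized on the outgroup's major allele (sites with
outgroup minor-allele frequency above 0.2 are dropped, following common
ABBA-BABA practice). The windowed statistic is $f_{dM}$ — the ABBA−BABA
numerator over the symmetric dynamic-donor denominator, computed in 50 kb
non-overlapping windows with at least 20 informative sites — bounded in
$[-1, 1]$, positive for sharing between the donor and the highlands,
negative for sharing with the lowlands, and antisymmetric under P1/P2
exchange. SHDR-level inference uses three complementary rules: an outlier
flag (max $f_{dM}$ above the 90th percentile of $|$min $f_{dM}|$ across all
SHDRs — SHDRs whose minimum is positive still contribute their absolute
minimum, a literal reading kept for reproducibility), a one-sided two-sample
Kolmogorov-Smirnov enrichment test of the max distribution against the
$|$min$|$ distribution, and 1000 background block permutations of the
per-region mean maximum. A genome-wide Patterson's D is reported as a
single-number summary; multi-taxon f-branch statistics are out of scope.

## The synthetic-data generator

The generator's role is to produce data with the statistical structure the
scan consumes, under full seed control. It is a hierarchical
Balding-Nichols model: each site draws an ancestral derived-allele frequency
from Beta(0.8, 2.0) (skewed toward rare derived alleles), and every branch
of a user-specified drift tree perturbs its parent frequency $p$ by a
Beta$(p\frac{1-F}{F}, (1-p)\frac{1-F}{F})$ draw with branch-specific drift
$F \in [0,1)$ ($F = 0$ copies the parent; fixed frequencies stay fixed).
Genotypes are independent Binomial(2, p) draws per diploid.

The default design mirrors the sampling scheme the scan targets: two sides,
two replicate transects per side, each a trio at ~1235 m / ~364 m / ~95 m,
eight diploids per population, plus a highland-specialist donor lineage and
an outgroup simulated with derived frequency ≈ 0 (1% of sites carry low-level
recurrent variation so polarization filtering is exercised). Within-transect
branches use $F$ of 0.015–0.03 and side-level branches 0.04, which puts
replicate-transect Fst below ~0.1, the regime the scan assumes. The desk
genome is 3 chromosomes × 1 Mb with 12,000 uniformly spaced sites (4 sites
per kb, 20 per 5 kb window); these sizes keep a full pipeline run to tens of
seconds while leaving ~3000 windows per transect, enough for stable
z-normalisation and permutation nulls.

Planted features override drifted frequencies: sweeps shift target
frequencies toward fixation by `intensity`; standing variants set one
identical derived frequency in all targets; introgression mixes in the
donor's frequency; an inversion block draws a diverged haplotype and gives
each carrier-population sample a 0/1/2 karyotype dosage, so local PCA shows
the three-cluster pattern a real segregating inversion produces. Because
sweeps are planted on frequencies rather than genealogies, the
site-frequency-spectrum footprint of a sweep is induced directly: a
configurable fraction (default 0.5) of sites whose post-sweep target
frequency is intermediate ([0.25, 0.75]) is removed, leaving the rare-allele
excess (negative Tajima's D) the enrichment stage looks for.

What the generator does *not* emulate: linkage and recombination along the
chromosome (sites are exchangeable given the tree), sequencing error and
genotype uncertainty, gene flow after the split (beyond planted features),
and background selection. Passing tests therefore demonstrate that the
statistics, interval machinery and inference rules behave correctly on data
with known truth — not that the pipeline's power on real short-read data
matches these numbers.

## Numerical and design choices

- **Coordinates** are 0-based half-open internally; VCF positions are
  1-based on input/output, BED 0-based. Window centre = start + size/2.
- **Minimum sites**: 10 variant sites per 5 kb window (windows below are
  null and excluded from z-scores); 20 informative sites per 50 kb
  f_dM window. The window minimum is a declared default, not inferred from
  any reference analysis.
- **Negative Fst** is reported as computed in pairwise matrices but clamped
  to 0 before the $-\log(1-F_{st})$ transform, since divergence times must
  be non-negative.
- **Missing genotypes**: per-site sample sizes are recomputed from called
  genotypes; a site with fewer than 2 called haplotypes in an involved
  population is skipped for that statistic (with a counted warning).
- **Tajima's D** uses the population's full haplotype count for its
  constants; with missing data the per-site contributions still use per-site
  counts.
- **PCA** uses called dosages with mean imputation rather than genotype
  likelihoods; in the high-confidence/synthetic regime the two coincide, and
  the substitution is stated openly.
- **Determinism**: one master seed expands into per-stage seeds through a
  fixed affine map below $2^{31}$; every stochastic operation takes an
  explicit seed and restores the caller's RNG state, so identical
  configurations give byte-identical artifact directories.
- **Ties**: a site with $p_2 = p_1$ contributes through the "$p_2 \ge p_1$"
  branch of the $f_{dM}$ denominator (its numerator is zero either way; the
  convention is fixed for reproducibility).

## Known limitations

Sites are simulated without linkage, so interval-level permutation nulls on
synthetic data are, if anything, better behaved than on real genomes where
differentiation autocorrelates; the jackknife partially addresses this for
the sharing estimate. The permutation framework treats all genomic positions
as exchangeable and does not model regions intrinsically prone to
involvement in adaptation. Cross-species comparisons require both interval
sets on one coordinate system; coordinate liftover is out of scope, as are
read mapping, genotype-likelihood machinery, composite-likelihood sweep
scans and phylogenetic network inference.
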