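---
title: "Methods: deciding breed-level divergence from dense SNP genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deciding breed-level divergence from dense SNP genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breedline)
```

## The question the package answers

Livestock breeds are managed, reproductively semi-isolated populations.
When a breed contains named lines that have been kept apart for a long
time, a practical question arises: are the lines now divergent enough to
be called separate breeds? `breedline` operationalises one way of
answering it from dense SNP-array genotypes: measure the pairwise
divergence of the candidate lines as F<sub>ST</sub>, and place that value on a
calibration ladder of F<sub>ST</sub> values computed between population pairs
whose relationship is already known — selection lines within one breed at
the bottom, then recognised breeds developed in the same region, breeds
from different regions, and intercontinental pairs at the top. If the
candidate pair's divergence reaches the recognised-breed rungs, the
genetic evidence supports calling them separate breeds.

Around that headline inference the package implements the supporting
analyses such a study needs: allele-sharing substructure detection,
low-dimensional embedding, outlier-SNP ranking with chromosomal
enrichment, haplotype-frequency comparison at a candidate selected locus,
and within-population diversity indices.

## Data model

Genotypes are diploid biallelic SNP calls coded 0/1/2 as counts of a
designated B allele, with an explicit missing sentinel (`NA`) kept
distinct from 0 copies. The marker map stores chromosome labels as
strings (`"1"`–`"26"`, `"X"`) and 1-based physical positions. The X
chromosome is treated as autosomal diploid throughout — no
male-hemizygote handling is attempted, a simplification that slightly
inflates apparent X heterozygosity in males and is acceptable because no
statistic here is sex-stratified.

Text PED/MAP files are the interchange format. Alleles at each SNP are
assigned A/B in order of first appearance in the file (lexicographic
tie-break when both first appear in one heterozygote), which makes
reading a fixed point: read–write–read is the identity on codes and map.
Generic QC (SNP call rate, MAF, then sample call rate, in that fixed
order) stands in for array-specific cleaning; the SNP-then-sample order
is a documented convention chosen for determinism, since different orders
give slightly different panels.

## The drift model behind simulation and estimation

The generator and the F<sub>ST</sub> estimator share one model. Each population
*j* descends from a common ancestor; at SNP *l* with ancestral frequency
*p<sub>l</sub>*, the population's current frequency is

p<sub>jl</sub> ~ Beta( p<sub>l</sub>(1−c<sub>j</sub>)/c<sub>j</sub>,
(1−p<sub>l</sub>)(1−c<sub>j</sub>)/c<sub>j</sub> ),

the Balding–Nichols parameterisation, so E[p<sub>jl</sub>] = p<sub>l</sub> and
Var(p<sub>jl</sub>) = c<sub>j</sub> p<sub>l</sub>(1−p<sub>l</sub>). The drift parameter
c<sub>j</sub> is the fraction of ancestral heterozygosity lost to drift, and for
two populations with drift c₁, c₂ the expected pairwise F<sub>ST</sub> is
(c₁+c₂)/2.

Generator defaults emulate the SNP50-array setting of the motivating
data: ancestral frequencies uniform on (0.05, 0.5) (array ascertainment
excludes rare variants; the spectrum is otherwise unspecified, so a flat
one is the neutral choice), SNPs spread over 26 autosomes plus X on a
regular position grid (only chromosome membership feeds any statistic),
independent SNPs with no background LD (every target statistic is
frequency-based; LD matters only in the injected haplotype block, which
is explicit), genotypes Binomial(2, p<sub>jl</sub>), and i.i.d. missingness.
What the simulator does **not** emulate — LD structure, related
individuals, ascertainment toward particular breeds, genotyping batch
error — means passing recovery tests demonstrate correctness of the
estimators under the model, not robustness to every artefact of real
array data.

## F_ST estimation

Per SNP, with sample frequencies p̂₁, p̂₂ from n₁, n₂ called
chromosomes, the Hudson-form moment components are

N<sub>l</sub> = (p̂₁−p̂₂)² − p̂₁(1−p̂₁)/(n₁−1) − p̂₂(1−p̂₂)/(n₂−1),
D<sub>l</sub> = p̂₁(1−p̂₂) + p̂₂(1−p̂₁),

and the global estimate is the ratio of sums Σ N<sub>l</sub> / Σ D<sub>l</sub> —
never the mean of per-SNP ratios, which is biased and unstable at
low-information loci. The estimator is unbiased for the drift parameter
above and robust to unequal sample sizes. A full Bayesian per-population
drift fit (MCMC) would estimate each c<sub>j</sub> separately; the moment
estimator was chosen because it is deterministic, fast at 50k SNPs, and
its expectation under the generator is known exactly, which makes
recovery testable. Per-SNP values are left unclamped (they can be
slightly negative) so outlier ranking is undistorted in the lower tail;
clamping is display-only. Uncertainty is a bootstrap over loci (default
1000 resamples, seeded): the SD definition of the reference table is
unstated, and resampling loci is the standard, testable choice.

Ranking takes the smallest count covering at least the requested
fraction (ceiling rule — 1% of 49,034 SNPs is 491; the alternative floor
convention would give 490). Chromosomal enrichment of a top set is
expected-vs-observed share with a hypergeometric upper-tail p-value;
with ~27 chromosomes, readers should treat the p-values as descriptive
unless multiplicity-corrected.

## Allele sharing and embedding

A<sub>s</sub>(i,j) = (IBS2 + 0.5·IBS1)/N over the N jointly-called SNPs —
pairwise-complete, matching the per-pair N in the definition. (The
formula is sometimes written ambiguously as IBS2+0.5·IBS1/N; only the
normalised reading is bounded in [0,1], and that is what is
implemented.) The ordered heatmap uses average-linkage agglomerative
clustering on 1−A<sub>s</sub>; linkage is a convention (none is canonical for
heatmaps) and the leaf order is made deterministic by putting the
subtree containing the lower original index first at every merge.

The embedding is classical scaling (principal coordinates) of
D = 1−A<sub>s</sub>: eigen-decomposition of −½JD²J, coordinates scaled by the
root eigenvalues, negative eigenvalues excluded and counted, axis signs
fixed by making each axis's largest-magnitude loading positive. PCA "of
allele sharing" admits two readings — Gram-matrix scaling of A<sub>s</sub>, or
PCA of normalised genotypes; both are provided (`pcoa_from_sharing()`,
`genotype_pca()` with Patterson scaling) and agree on cluster topology
for drifted-population data, so the choice does not affect any
conclusion the package draws. Separation of labelled groups is scored as
the mean silhouette width in the leading coordinates: 1 for tight
distinct clusters, ~0 for labels unrelated to position.

## Haplotype frequencies by EM

For a window of m ≤ 8 SNPs, haplotype frequencies are estimated from
unphased genotypes by expectation–maximisation over the 2^m haplotypes.
An individual with H heterozygous window sites is compatible with
2^(H−1) unordered haplotype pairs; the E-step weights pair (a,b) by
f<sub>a</sub>f<sub>b</sub> (doubled when a ≠ b — the standard random-union-of-gametes
likelihood), and the M-step divides expected gamete counts by 2n. The
log-likelihood is asserted non-decreasing at every iteration. Defaults
(tol 1e-8 on the log-likelihood increment, 1000 iterations, 10 starts:
one from the product of single-SNP frequencies plus 9 seeded Dirichlet
starts, best likelihood kept) were chosen so the estimate matches an
exhaustive-search oracle deterministically on small instances; the
likelihood surface for 4-SNP windows at realistic n is benign, and one
informed start almost always suffices, but restarts are cheap insurance.
Individuals with any missing window call are excluded and counted rather
than wildcard-summed: exclusion is the simpler auditable rule, and the
reference analyses visibly used fewer animals in the window than in the
panel-wide tables, consistent with the same choice.

## Diversity indices

Gene diversity uses the Nei small-sample correction
2p̂(1−p̂)·n/(n−1) — several reference populations have only 22–24
animals, where the correction matters. The inbreeding coefficient is
(O<sub>hom</sub>−E<sub>hom</sub>)/(L−E<sub>hom</sub>) with expectations from the sample's own
population, since inbreeding is defined relative to one's population.
Allelic richness uses closed-form rarefaction: the probability that an
allele with N<sub>i</sub> of N copies appears in a drawn subsample of g copies is
1 − C(N−N<sub>i</sub>, g)/C(N, g); private richness multiplies presence in the
focal population by absence from every other population's rarefied
sample. The default g is twice the smallest population's sample size
(standard practice; configurable), and SNPs that cannot supply g called
chromosomes in every population are excluded and counted.

## Calibration ladder and verdict

The packaged reference matrix (14 sheep populations, 921 animals,
F<sub>ST</sub>% above the diagonal, SD×1000 below) is stored verbatim as
printed and never re-derived — the underlying genotypes are not
distributed, so the arithmetic on the printed values is the reproducible
surface. Category averages are unweighted means of pairwise cells,
displayed half-up at 1 decimal (matching the reference precision;
whether the original averages were taken over rounded or unrounded cells
is unstated — rounded cells reproduce the printed averages at 1 decimal,
which is the check used). The verdict rule is: breed-level divergence
iff the candidate F<sub>ST</sub> is at least the recognised-breed-category
average, with the boundary classified inclusively — ties are practically
impossible and an inclusive rule keeps the decision deterministic.

```{r calibration}
fix <- read_fst_fixture()
calib <- calibration_table(fix$fst)
calib
breed_verdict(fix$fst["FLN", "LUN"], calib)$narrative
```

## Numerical and degenerate-input conventions

* Monomorphic-across-both-populations SNPs have D<sub>l</sub> = 0 and are
  flagged uninformative, excluded from the global ratio.
* Zero drift (c = 0) short-circuits the Beta draw to the ancestral
  frequency exactly; c = 1 is rejected (the Beta is undefined).
* A sample pair with no jointly-called SNPs is a data error naming the
  pair, not a silent NA.
* Sample-size guards: F<sub>ST</sub> needs ≥ 2 samples per population per SNP
  (chromosome count ≥ 2); populations below that are skipped with a
  warning in the all-pairs table.
* All randomness (simulation, bootstrap, random SNP subsets, EM
  restarts) is seeded; the pipeline fans one global seed out to fixed
  per-stage offsets so stages are individually reproducible.

## Problem sizes

The test suite exercises the estimators at panel sizes of a few hundred
to 10,000 SNPs and 20–100 diploids — large enough that the stochastic
recovery checks (drift-parameter recovery within 3 bootstrap SDs,
haplotype-vector recovery within 3 binomial SEs, ARI = 1 block recovery
at c = 0.06) have the power to fail informatively, and small enough to
run routinely. The same estimators scale unchanged to 50k-SNP panels.

## Known limitations

* The verdict is a calibration against named reference categories, not
  a universal F<sub>ST</sub> threshold for breedhood; non-genetic criteria are
  out of scope.
* No LD-aware statistics (iHS, XP-EHH) and no Weir–Cockerham θ;
  the Hudson/Balding–Nichols pairing is the single estimator family.
* No sex-aware X handling, no pedigree checks, no kinship/IBD.
* The EM reports frequency point estimates without standard errors.
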