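---
title: "Mapping triallelic loci: methods and design choices"
author: "triallele package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping triallelic loci: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

# Background

Threespine stickleback (*Gasterosteus aculeatus*) repeatedly colonise
freshwater, and most adaptive loci segregate as two ancient haplotype
classes: a marine allele and a freshwater allele. A smaller set of loci is
*triallelic*: populations fall into three distinct haplotype clusters — a
marine class plus two different freshwater classes with opposite
phenotypic effects (for spine length, a Long and a Short freshwater
allele). This package implements the computational pipeline for finding
and characterising such loci from desk-scale inputs: population
allele-frequency tables, allele-specific read-count tables from F1
crosses, phenotype tables, allele sequences, and genetic maps. Read
alignment and variant calling are upstream of this package; it starts
from genotype and count tables.

Every analysis stage has a matching seeded generator of synthetic data
with known planted structure (`generateGenotypeLandscape()`,
`generateAseCounts()`, `generatePhenotypes()`), so the package validates
itself by parameter recovery rather than by fixtures.

```{r load}
suppressPackageStartupMessages({
  library(triallele)
  library(GenomicRanges)
})
```

# The triallelic genome scan

The scan slides 2,500-bp windows with a 500-bp step across a matrix of
alternate-allele frequencies (rows: SNPs, columns: populations; a
per-individual genotype-dosage matrix works identically). Each window is
judged by two independent filters, and the final call set is the
intersection of the two merged candidate tracks.

**PCA filter.** A two-cluster (plain marine/freshwater) window puts
essentially all between-population variance on one principal axis; a
three-cluster window needs two. `windowPca()` computes the percent
variance explained (PVE) spectrum with populations as observations and
centred SNP frequencies as variables, and `pcaFilter()` passes windows
with PC2 ≥ 20 PVE and PC1 + PC2 ≥ 75 PVE (inclusive thresholds). Windows
whose candidate flags survive are merged within 10 kb.

**Cluster-gain filter.** `clusterGain()` clusters the populations at
k = 2 and k = 3 and computes, for each k, the sum *s* over clusters of
the average intracluster genetic distance (singleton clusters contribute
0; *s*~1~ is the all-in-one-cluster baseline — the only baseline that
makes "reduction in *s* for k = 3" well defined from a single
clustering). `kmeansFilter()` passes windows with a > 65% reduction of
*s* at k = 3 relative to *s*~1~ *and* a > 20% further reduction from
k = 2 to k = 3 (strict thresholds). Candidates are merged within 5 kb.

```{r scan-demo}
w3 <- GRanges("chrI", IRanges(40001, 42500), nClusters = 3L, divergence = 0.9)
w2 <- GRanges("chrI", IRanges(70001, 72500), nClusters = 2L, divergence = 0.9)
spec <- LandscapeSpec(nMarine = 4L, nFreshwater = 8L,
                      chromLengths = c(chrI = 1e5),
                      windows = c(w3, w2), noiseSd = 0.05, seed = 2)
sim <- generateGenotypeLandscape(spec)
res <- scanTriallelic(sim$genotypes, seed = 2)
triallelicCalls(res)
scanRecovery(res, sim$truth, sim$genotypes)
```

## Choice of the genetic distance

The distance behind *s* is a genuinely open design point, and the default
here is the **mean squared per-site frequency difference** between two
populations' frequency vectors (`metric = "squared"`), with the per-site
RMS difference (`"euclidean"`) and the per-site mean absolute difference
(`"manhattan"`) as options. The squared scale is the one the k-means
objective itself minimises, and it is the only one of the three under
which the 65%/20% thresholds behave sensibly on bounded allele
frequencies: because *s* sums the three clusters' average distances, a
linear (RMS) metric has a within-cluster noise floor of about
3·√2·noiseSd, while the average between-cluster distance of three
mutually separated clusters of scalar frequencies in [0, 1] cannot exceed
roughly divergence/√2 — at realistic noise (SD 0.05) the k = 3 reduction
is then capped near 0.60 for *any* cluster geometry and the 0.65
threshold can never fire. On the squared scale the noise floor drops to
2·noiseSd² ≈ 0.005 and cleanly separated windows show reductions around
0.95.

## Numerical and degeneracy choices

* Windows with fewer than 3 SNPs, or with no variance after imputation,
  are skipped (recorded in `windowStats()` with a reason), not failed.
* Missing frequencies are mean-imputed per site within the window; PCA
  and k-means need complete matrices.
* For nine or fewer samples the best partition at each k is found by
  exhaustive enumeration over all set partitions (cheap: 3,025 partitions
  at n = 9, k = 3). For larger windows the search takes the lowest-*s*
  partition over 20 seeded k-means restarts, two deterministic
  hierarchical starts (average and complete linkage cuts), and all
  single-sample "donation" splits of the chosen (k−1)-partition. The
  donation candidates guarantee *s*~1~ ≥ *s*~2~ ≥ *s*~3~: averaging over
  which member is removed, the remaining cluster's mean pairwise distance
  equals the cluster's own mean, so some donation never increases *s*.
* Distinct sample profiles are put in a canonical order before centers
  are drawn, so scan output is invariant to sample order; the
  `GenotypeTable` constructor sorts chromosomes alphabetically, so it is
  invariant to input row order too. Per-window RNG streams are derived
  from the scan seed and the window index.

## What the landscape generator does and does not emulate

`generateGenotypeLandscape()` plants windows of 1, 2 or 3 clusters on a
background of shared frequencies plus Gaussian jitter. Within a planted
window each cluster's per-SNP mean sits at 0.5 ± divergence/2 with the
side drawn independently per cluster and SNP, which makes the clusters
mutually roughly equidistant and in general position — the geometry the
PCA filter expects of a genuine triallelic region. It does *not* emulate
linkage disequilibrium decay, allele-frequency spectra, population
phylogenetic structure, or heterozygous intermediates; recovery results
on it demonstrate the scan's statistical behaviour under its own model,
not performance on real population data.

# Reciprocal allele-specific expression

Two F1 crosses share a marine parent: Marine × Long and Marine × Short.
At a cis-regulated gene with reciprocal freshwater evolution, the
freshwater allele is up in one cross and down in the other, in the same
tissue. Four tissues are profiled: dorsal spine (DS) and pelvic spine
(PS) — where the phenotype lives — and pectoral fin (PF) and heart (H) as
controls.

Per SNP and tissue, `snpAseTest()` runs two tests between the crosses:

* **Pooled Fisher:** reference/alternate reads are summed within each
  cross and the 2 × 2 table is tested two-sidedly. Libraries above their
  (cross, tissue) median total are first downsampled to exactly that
  median by drawing reads without replacement
  (`downsampleToMedian()`), so deeply sequenced libraries cannot
  dominate the pool. Subsampling (rather than a binomial re-draw with
  the observed ratio) preserves the count distribution exactly; a
  re-draw adds two-stage variance and makes the pooled test
  anti-conservative.
* **Mann–Whitney on log ratios:** each library contributes
  log2(ref/alt) (`aseLogRatio()`; a Haldane–Anscombe pseudocount of 0.5
  is added to both counts only when a zero is present, and
  double-zero libraries are excluded), and the per-library ratios of the
  two crosses are compared (exact when the pooled sample size is ≤ 20
  without ties; tie-corrected normal approximation otherwise).

The per-SNP effect size `diffAse` is the difference of cross-mean log2
ratios (Long cross minus Short cross). The ±1 bound used for control
tissues needs an explicit definition of "differential ASE" and this is
the only per-SNP effect the methods compute, so it is the one bounded.

`filterEligibleSnps()` reproduces the eligibility rule (with the default
fraction 20/24: at least 20 of 24 fish with ≥ 3 reads per allele and
each allele ≥ 5% of that fish's total), aggregating counts per
*individual* across its libraries; the library→individual mapping is an
explicit column, defaulting in the generator to the study design of 12
fish per cross.

`spineCandidateFilter()` keeps exonic, non-outlier (< 5,000 reads) SNPs
with significant same-direction differential ASE in both spine tissues
(unadjusted p < 0.05) and no differential ASE in either control (p >
0.05 and |diffAse| < 1). `reciprocalGeneFilter()` calls reciprocal
expression when, in at least one tissue, both freshwater alleles differ
from marine (pooled per-cross binomial tests, p < 0.05 each — pooling
matches the Fisher convention), differ from each other (both tests
p < 0.05), and differ at least twofold (|diffAse| ≥ 1); genes are
reported at 1-SNP and ≥ 2-SNP support. No multiple-testing correction is
applied anywhere — the filters are deliberately specified on unadjusted
p-values — and the statistics are polarity-symmetric, with the
freshwater-allele column used only for interpretation.

```{r ase-demo}
simA <- generateAseCounts(AseEffectSpec(nGenes = 12L, fracReciprocal = 0.25,
                                        seed = 31))
resA <- snpAseTest(simA$counts, seed = 31)
reciprocalGeneFilter(resA)
simA$truth[simA$truth$reciprocal, ]
```

`proximityEnrichment()` counts called genes within 50 kb of the scan's
regions against 10,000 equal-size random gene draws, with
p = (1 + #{null ≥ observed})/(10,000 + 1).

The count generator draws per-library depth from a negative binomial
(default mean 60, size 8) and the freshwater-allele count binomially
given depth; planted reciprocal genes use freshwater-allele fractions
0.73 in the Short cross and 0.36 in the Long cross in the spine tissues
(the 2.7-fold-up / 1.8-fold-down pattern), controls and null genes sit at
0.5. An optional `pJitterSd` adds ratio overdispersion (default 0). It
does not emulate mapping bias toward the reference allele, shared
residual variation between tissues of one fish, or gene-level expression
differences.

# Spine-length association

Spine lengths scale with body size and differ between sexes, so all
association statistics operate on OLS residuals of each trait on standard
length and sex (`residualizeTrait()`). Sex is always included unless
collinear; conditioning its inclusion on per-population significance
would make the model selection data-dependent and unstable. "Combined
major spine" residuals are the per-fish sum of separately residualized
DS1, DS2 and PS (`combinedSpineResiduals()`).

* `quintileScan()` ranks fish by residual, takes the first and last
  quintiles (⌊n/5⌋ fish each) and compares allele counts
  (2·hom + het) per site with a Fisher exact test. The original
  screen's test statistic is unnamed; an allele-count Fisher test is the
  natural exact choice at these sample sizes.
* `markerFtest()` is a one-way ANOVA F-test across genotype classes
  treated as an unordered factor (not an additive dosage), with
  pairwise-complete records.
* `conditionalFtest()` first removes the control marker's class means
  from the residuals and then retests every other marker.
* `pveGenotype()` is the ANOVA R² × 100 — the percent of residual
  variance explained by genotype class. Computing PVE on residuals
  (rather than raw lengths with covariates refit per marker) matches the
  residualize-then-test structure of the rest of the analysis.
* `selectExtremes()` picks the lowest/highest residual fish for
  resequencing designs, ties broken by fish id within one shared
  ordering so the two sets never overlap.

The phenotype generator draws genotypes under Hardy–Weinberg and builds
`trait = intercept + β~SL~·SL + β~sex~·sex + γ(genotype) + ε`;
`spineEffectForPve()` inverts the variance decomposition
PVE = 2p(1−p)d² / (2p(1−p)d² + σ²) to plant a target PVE with an
additive γ = (0, d, 2d).

```{r assoc-demo}
d <- spineEffectForPve(30, 0.5, 0.5)
simP <- generatePhenotypes(PhenotypeSpec(nFish = 700L,
                                         gamma = c(SS = 0, SL = d, LL = 2 * d),
                                         residSd = 0.5, seed = 11))
r <- residualizeTrait(simP$phenotypes, "DS1")
pveGenotype(r, simP$genotypes)
markerFtest(r, simP$genotypes)$p
```

# Three-allele phylogeny and clock dating

`substitutionRate()` globally aligns two allele sequences (affine gaps:
match 1, mismatch −1, open 5, extend 1) and reports the raw p-distance
over aligned, unambiguous bases; gap columns are excluded from numerator
and denominator because cloned alleles carry structural variants that
must not count as substitutions. No multiple-hit correction is applied —
at distances of ~0.02 the correction is far below the alignment-choice
uncertainty (±0.001 on reproduced rates, since alignment parameters for
the original rates are unstated).

`threeTaxonTree()` takes the three pairwise rates, declares the closest
pair sisters (ties broken lexicographically), and assigns terminal
branches by the three-point formula b~X~ = (d~XY~ + d~XZ~ − d~YZ~)/2,
which reconstructs the input distances exactly; a negative implied
branch is clamped to zero with a warning. `clockDates()` converts
distances to times as t = d/(2·rate) under a user-supplied per-lineage
substitution rate — the calibration (e.g. from the Japanese
marine/Japan Sea divergence) is an input, not something this package
derives. The sister-split time uses the sister distance; the deeper split
uses the mean of the two crossing distances.

```{r clock-demo}
tr <- threeTaxonTree(DistanceTriple(dLS = 0.0148, dSM = 0.0211, dLM = 0.0171))
tr
deeperD <- mean(c(0.0211, 0.0171))
clockDates(tr, ratePerLineage = deeperD / (2 * 2.75))[1:2]
```

# Recombination-rate contrasts

`windowedRates()` tiles each chromosome with non-overlapping 100-kb
windows, linearly interpolates the genetic map at the window edges, and
reports (ΔcM)/(Mb); windows not fully inside the map span are dropped,
and map validity (strictly increasing bp, non-decreasing cM) is enforced
at construction. `recombGroupCompare()` contrasts windows overlapping
triallelic regions against the rest with a two-sided Mann–Whitney test
(the original figure's test is unnamed; Mann–Whitney is robust to the
heavy right tail of rate distributions) and reports group means with
standard errors. `crossSpeciesRatio()` pairs windows across species via a
user-supplied synteny table (no liftover is attempted), forms per-pair
rate ratios (zero-denominator pairs dropped and counted), and applies the
same contrast; with all ratios tied, or only one pair, the result is
descriptive (p = 1 resp. NA).

# Problem sizes and reproducibility

All generators are deterministic given their spec (including its seed),
and every stochastic routine takes an explicit seed. The validation suite
and `scripts/acceptance.R` use these problem sizes, chosen to estimate
each quantity stably while keeping a full run in minutes on one CPU:
exhaustive Fisher checks over all 2×2 tables with total ≤ 40; exhaustive
Mann–Whitney permutation checks at group sizes ≤ 6; exhaustive partition
checks at ≤ 8 samples; null calibrations with 1,000 p-values per test
family (one-sided Kolmogorov–Smirnov at α = 0.01, super-uniformity of the
discrete tests allowed); scan recovery on a 520-kb, 69-population
landscape with ten planted triallelic windows and eight two-cluster
decoys; ASE recovery with 150 genes at 20% planted; and PVE recovery as
the median over 100 seeds at n = 700.

# Known limitations

* The scan reports where three clusters exist, not which allele is
  marine or freshwater; ecotype labels are carried for interpretation
  only.
* The eligibility filter assumes the library→individual mapping is
  correct; with one library per individual the "fraction of fish" rule
  degrades to a fraction of libraries.
* Exact Mann–Whitney p-values switch to the tie-corrected normal
  approximation in the presence of ties at any pooled size.
* The distance tree is a three-taxon impute, not a phylogenetic
  inference; there is no bootstrap support and no rate heterogeneity.
* Windowed recombination rates inherit all error in the input genetic
  map; markers are assumed error-free and interpolation is linear.
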