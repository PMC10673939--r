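---
title: "Methods: landscape genotype-environment association with landgea"
author: "landgea authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: landscape genotype-environment association with landgea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(landgea)
```

# The problem

Landrace crops sampled across a heterogeneous landscape carry two
superimposed signals in their genomes: neutral population structure shaped
by shared ancestry and geography, and localized allele-frequency clines at
loci under environmental selection. `landgea` implements the full inference
chain used to separate the two in diploid SNP panels of geo-referenced
accessions: genotype QC and LD pruning, population structure estimation,
partial redundancy analysis (pRDA) with variance partitioning, three
genotype-environment association (GEA) scans, sliding-window diversity
statistics, LD decay, and candidate-interval/gene mapping. A synthetic
landscape generator with known adaptive loci makes every stage testable
without external data.

# The synthetic landscape generator

`landscapeConfig()` / `simulateLandscape()` emulate a diversity panel of a
predominantly selfing cereal sampled across a plateau: by default 200
individuals from 20 sites in 4 genetic groups, 5,000 biallelic SNPs on 7
chromosomes of 0.5 Mb each, and 30 monthly climate variables (five series -
`tmax`, `prec`, `srad`, `tavg`, `tmin` - over the April-September growing
season).

**Structure.** Neutral loci follow the Balding-Nichols model: ancestral
frequency $p_0 \sim U(0.1, 0.9)$ and group frequencies
$p_g \sim \mathrm{Beta}\!\big(p_0 \tfrac{1-F}{F},\, (1-p_0)\tfrac{1-F}{F}\big)$
with $F$ = `fst_groups` (default 0.2). Groups are blocks of sites contiguous
in latitude, deliberately confounding structure with geography and climate
the way real landscapes do; `group_assignment = "random"` removes that
confounding for calibration studies.

**Selfing.** Genotypes are drawn selfing-aware: with probability `f_is`
(default 0.9) an individual's two alleles are identical by descent, else
Hardy-Weinberg. This matters: under random mating, heterozygosity is
$2p(1-p)$, and the standard GBS het-rate filter at 0.2 would discard ~85% of
loci - inconsistent with the panels this pipeline targets, where selfing
keeps observed heterozygosity near a few percent. `f_is = 0` restores
random mating.

**Adaptive loci.** A known subset (default 2%) takes site-level frequencies
$p(\mathrm{site}) = \mathrm{logit}^{-1}(\mathrm{logit}(p_0) + \beta z)$,
where $z$ is the standardized driver climate variable and $\beta$ =
`cline_effect` (default 1.5, random sign). Clines act on site-level
frequency - the model class the GEA methods assume - not on individual
residuals. The truth table records each locus's driver and slope.

**Climate.** Variables are linear or Gaussian-bump functions of the site
coordinates plus site-level noise; two variable pairs are post-adjusted so
their realized correlation equals `env_collinearity` exactly (default 0.8),
so forward selection always faces real collinearity. Missing genotype calls
are MCAR at `missing_rate` (default 5%).

**What the generator does not emulate.** Loci are exchangeable given
structure: there is no recombination map, so background LD between
neighbouring loci is absent, and the fitted LD-decay distance on synthetic
panels collapses to the first distance bin. Passing tests therefore
demonstrate the estimators' correctness, not coalescent realism; on real
data the LD-decay stage is the one whose output depends on features the
generator omits. There is also no admixture, no sequencing-error model, and
missingness is not informative.

# QC, filtering, pruning

Two filter sets mirror the dual filtering of a GBS panel: the *structure*
set keeps loci with missingness $\le 0.2$, het rate $\le 0.2$ and MAF
$\ge 0.1$ (used for PCA, clustering, pRDA after LD pruning); the *outlier*
set keeps MAF $> 0.05$, het $< 0.2$, missingness $< 0.2$ (used by the
association scans). The boundary conventions differ on purpose: one set is
phrased as keeps, the other as removals, and a locus at MAF exactly 0.05 is
removed under both.

LD pruning follows PLINK `--indep-pairwise 150 5 0.5` semantics: windows of
150 SNPs advancing by 5, removing the lower-MAF member of any pair with
$r^2 > 0.5$ (tie: the later position), repeated until no window contains a
violating pair. Windows are indexed on the original locus order and pairs
visited in index order, making the procedure deterministic. $r^2$ uses
pairwise-complete observations. Missing calls elsewhere are replaced by
modal imputation (ties toward the locus mean, then the lower dosage).

# Population structure

`genotypePCA()` centers each locus at $2\hat p$ and scales by
$\sqrt{\hat p(1-\hat p)}$ (Patterson scaling, default) or the sample SD.
`inferClusters()` runs k-means (20 restarts) on the retained PCs for
$k = 1..k_{max}$ and selects $k$ by
$\mathrm{BIC}(k) = n\ln(\mathrm{WSS}_k/n) + k\ln n$ (ties to the smaller
$k$). A caveat worth knowing: with many samples in few informative
dimensions the WSS keeps shrinking fast enough that argmin-BIC over-splits
Gaussian clusters; the criterion is reliable when clustering on a healthy
number of retained axes relative to $n$, and the elbow of the BIC vector
(returned in full) is the robust manual check.

`wcFst()`/`pairwiseFst()` implement the Weir-Cockerham (1984) variance
components $a$, $b$, $c$ with the ratio-of-sums multi-locus estimator
$\hat\theta = \sum_l a_l / \sum_l (a_l + b_l + c_l)$. On Balding-Nichols
simulations the estimator recovers the generating $F$ (e.g. 0.30 recovered
as 0.300 at 2,000 loci, 2 x 100 individuals).

`amova()` is a two-level analysis of molecular variance on squared
Euclidean distances. By default each diploid is expanded into its two
allele rows (dosage 1 becomes one 0 and one 1), the convention of
haplotype-based AMOVA for genotypic data; this makes $\Phi_{ST}$ estimate
the same allelic differentiation as Weir-Cockerham Fst. Computing AMOVA
directly on dosage vectors (`level = "dosage"`) is also available, but its
$\Phi_{ST}$ measures genotypic differentiation, $\approx 2F/(1+F)$ under
Balding-Nichols - a deliberate, documented distinction, since only the
allele-level version is cross-consistent with Fst. Negative components are
truncated to zero and flagged; the permutation p-value shuffles whole
individuals.

# Climate variables and forward selection

`standardizeEnv()` z-scores climate variables (geography stays unscaled);
`envPCA()` summarizes the climate space. `forwardSelect()` is an
`ordiR2step`-style stepwise selection for the RDA of genotypes on climate:
at each step the best candidate by adjusted $R^2$ (Ezekiel) is admitted
only if its marginal permutation p-value is $\le \alpha$ (default 0.05, 999
permutations of the residualized candidate) and the running adjusted $R^2$
does not exceed the global all-variable model's. The global ceiling has a
consequence users should expect: with many site-level variables and few
sites the global model is pure overfit, its adjusted $R^2$ is near zero,
and selection correctly refuses to add anything. Selection over the 30
monthly variables is therefore most informative when the panel has many
distinct sampling locations.

# Partial RDA and variance partitioning

`fitRDA()` fits $\hat Y = X(X^+Y)$ by least squares on the column-centred
genotype matrix, after residualizing $Y$ and $X$ on the condition block for
partial models; axes come from the SVD of $\hat Y$. $R^2$ is constrained
inertia over the total inertia of the *unconditioned* centred matrix, so
the four partitioning models are on a common denominator:

* Model 1 (full): climate + geography + structure (first 3 genotype PCs);
* Model 2: structure | climate + geography (pure structure);
* Model 3: geography | climate + structure (pure geography);
* Model 4: climate | geography + structure (pure climate);

with confounded = full − (sum of pure) and unexplained = 1 − full. The
identities hold to 1e-9 by construction and are asserted on every simulated
dataset; the fits agree with vegan's `rda()` to 1e-8 in the test suite.

# RDA outlier scan

`rdaOutlierScan()` is the Mahalanobis-distance construction on the SNP
loadings of the first $K = 4$ axes of the climate-given-structure pRDA:
distances to the across-SNP centroid, a genomic inflation factor
$\lambda = \mathrm{median}(D^2)/\chi^2_{df,0.5}$, p-values from the upper
$\chi^2_{df}$ tail of $D^2/\lambda$, Storey q-values, and a Bonferroni flag
at a nominal $\alpha$ of 0.1.

Two numerical choices matter and are exposed:

* **Locus scaling.** The scan's pRDA standardizes loci
  (`fitRDA(scale_loci = TRUE)`): raw 0/1/2 loadings mix each locus's
  frequency variance into $D^2$ and the $\chi^2$ tail calibration visibly
  breaks (null KS p ~ 1e-4 unscaled vs ~0.25 scaled). Variance
  partitioning stays on unscaled dosages, the conventional inertia scale.
* **Covariance.** The robust minimum-covariance-determinant estimator
  (`robust = TRUE`, used by the pipeline) prevents the planted outliers
  from inflating their own reference covariance; the classical estimator
  remains the deterministic default of the bare function.
* **Degrees of freedom.** `df_mode = "axes"` uses $df = K$; `"df2"`
  pairs four axes with two degrees of freedom, a combination that appears
  in the applied literature. Both are first-class modes; they rank loci
  identically and differ only in calibration.

On the standard recovery fixture (200 x 5,000, $F = 0.3$, $\beta = 1.5$,
2% adaptive) the robust scaled scan attains 60-80% recovery at
$q < 0.05$ with observed FDR at or below ~10%; on the matched null fixture
$\lambda \approx 1.05$ and calibrated p-values pass a KS uniformity check.

# LFMM

`fitLFMMRidge()` fits $Y = X B^\top + U V^\top + E$ per climate variable.
The default `"pc-factors"` mode fixes the latent factors to the first
$K = 2$ genotype-PC score axes and estimates per-locus effects by OLS on
$(1, X, U)$ - deterministic, so the five replicate runs of `lfmmScan()`
are identical and the intersection consensus equals a single run (the run
machinery exists for the stochastic `"alternate"` mode, which alternates a
ridge update of $B$ with a rank-$K$ SVD of $Y - XB^\top$). z-scores are
calibrated by $\lambda = \mathrm{median}(z^2)/0.4549$ (the $\chi^2_1$
median, hard-coded to 4 decimals) and converted to q-values by
`storeyQvalues()` (Storey-Tibshirani smoother over
$\lambda_{grid} = 0.05..0.95$, natural cubic spline with df 3; below 100
tests $\pi_0$ falls back to 1, the Benjamini-Hochberg equivalence).

$K = 2$ factors span the structure axes of at most 3 groups. With 4
latitude-blocked groups one structure axis is unabsorbed, and any climate
variable correlated with it inflates $\lambda$ (to ~2.5 on the default
landscape) - that is confounding, which GIF calibration then absorbs
(calibrated p-values remain near-uniform), not a defect of the estimator.
The calibration checks in the test suite therefore use a 3-group landscape
with randomly placed groups, where the model is correctly specified and
$\lambda$ sits in [0.95, 1.07] across all 30 variables.

A unit note on effect sizes: the generator's $\beta$ is a logistic slope on
site-level allele frequency, while the fitted effect is a dosage-per-SD
regression coefficient further attenuated by the latent factors; the two
are proportional only locally, so recovery tests assert sign and
order-of-magnitude agreement, not unit slope.

# EnvGWAS

`envAssocScan()` treats each climate variable as the trait: OLS of
`env ~ dosage + PC1..PCn` per SNP, over a grid of 2-4 genetic PCs, keeping
per variable the PC count whose genomic inflation factor is closest to 1 -
an automated stand-in for choosing by QQ-plot. Dual significance:
Bonferroni at $\alpha = 0.05$ over the tested loci and Storey q < 0.05.
Per-SNP variance explained is the nested-model partial $R^2$
$(RSS_{cov} - RSS_{full})/RSS_{cov}$, which the vectorized scan obtains as
the squared partial correlation. This is a deliberate single-locus
substitute for multi-locus iterative mixed-model scans (FarmCPU-class
methods): per-SNP tests, dual thresholds and variance explained are
preserved; pseudo-QTN iteration and the kinship random effect are not, and
that limitation is stated here rather than hidden.

# Diversity windows and Tajima's D

`makeWindows()` tiles 20 kb windows advancing 10 kb; one truncated window
is appended when the last full window does not reach the chromosome end.
Per site, with $n_c$ callable chromosomes, nucleotide diversity is the
unbiased pairwise estimator $2\hat p(1-\hat p) n_c/(n_c-1)$. Per window
over its $S$ segregating sites: $\pi$ = mean per-site diversity, Watterson
$\theta_W = 1/a_1(\bar n)$, and Tajima's
$D = (\pi_{sum} - S/a_1)/\sqrt{e_1 S + e_2 S(S-1)}$ with the standard
constants at the rounded window-average chromosome count.

$\pi$ and $\theta_W$ are normalized **per segregating site**, not per bp:
for reduced-representation SNP panels, invariant sites are unobserved and
per-bp diversity is undefined; with ~300 chromosomes this convention puts
$\theta_W = 1/a_1 \approx 0.16$-0.18 and MAF-filtered $\pi$ around 0.3,
the magnitudes such panels report. `per_bp = TRUE` switches the
denominator to window width. A directional property worth knowing: MAF
filtering removes rare variants, lowering $S/a_1$ faster than $\pi_{sum}$,
so genome-wide window $D$ shifts positive relative to the unfiltered panel
- asserted as a test.

# LD decay and candidate mapping

`ldDecay()` bins within-chromosome pairwise $r^2$ up to 300 kb (1-5 kb
bins) and fits the Hill-Weir expected-$r^2$ curve in the recombination
parameter $C = \rho d$, with the sample-size adjustment at $n$
chromosomes, by Levenberg-Marquardt least squares on the bin means. The
decay distance is where the fitted curve falls halfway between its value
at $d = 0$ and its asymptote ($\approx 1/n$); a fixed-cutoff crossing
(default $r^2 < 0.1$) is reported alongside. Chromosomes with under 10
populated bins, failed fits, or no crossing in range are flagged.

`candidateIntervals()` flanks each significant SNP by its chromosome's
decay distance (clipped at the ends: a 145 kb decay distance yields a
290 kb interval); `mapGenes()` lists genes overlapping each interval plus
the nearest outside gene, resolving upstream/downstream on the gene's
strand (a SNP 5' of the gene start on that strand is upstream).
`consensusPleiotropy()` unifies the three methods' significant
(SNP, variable) pairs; a locus associated with two or more distinct
variables is pleiotropic - the "two or more" convention is adopted
deliberately where usage in the field oscillates between "two or more"
and "more than two".

# Pipeline, problem sizes, determinism

`runPipeline()` chains every stage from a config list or YAML file, logs
each stage's parameters and row counts, writes all result TSVs and a
manifest with MD5 checksums. Under `"pc-factors"` LFMM, the classical or
seeded-robust Mahalanobis scan, and fixed seeds everywhere, two runs of
the same config are byte-identical - asserted in the tests.

The test suite and the acceptance script run desk-scale problem sizes
chosen to keep each statistical check informative: the standard fixtures
are 200 individuals x 5,000 SNPs for calibration and recovery, 100 x 400
for the 100-replicate forward-selection power study, and smaller
deterministic toys for the exact-arithmetic oracles. The forward-selection
replicates use 6 climate variables and a strong single driver because,
with 30 site-level variables on 20 sites, the global-adjusted-$R^2$
ceiling correctly refuses all selection - the property under test is
driver identification where selection is statistically meaningful.

# Known limitations

* No kinship random effect in the EnvGWAS stand-in; no pseudo-QTN
  iteration.
* The generator's loci are unlinked, so LD-decay estimates on synthetic
  data reflect only structure-induced background correlation.
* Argmin-BIC cluster counts over-split large panels in few dimensions;
  inspect the returned BIC vector.
* Mixed-ancestry individuals are not detected internally; downstream
  stages accept an explicit sample-exclusion list instead.
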