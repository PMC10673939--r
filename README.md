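# landgea

Landscape genomics for diploid SNP panels of geo-referenced plant
accessions: separate neutral population structure from environment-driven
allele-frequency clines and nominate candidate adaptive loci and genes.

`landgea` is aimed at researchers analysing genotyping-by-sequencing panels
of landraces or wild populations sampled across climatic gradients. It
implements the complete inference chain as composable, tested functions:

* **QC and pruning** — per-locus MAF / heterozygosity / missingness
  statistics, the dual filter sets used for structure vs outlier analyses,
  modal imputation, and PLINK-style `indep-pairwise` LD pruning
  (150-SNP window, step 5, r² 0.5).
* **Population structure** — genotype PCA (Patterson scaling), k-means +
  BIC cluster inference, Weir–Cockerham Fst (ratio-of-sums θ̂ from the
  a/b/c variance components), and two-level AMOVA with permutation tests.
* **Partial redundancy analysis** — `ordiR2step`-style forward selection of
  non-collinear climate variables, the four-model pRDA variance
  partitioning (full; structure | climate+geography; geography |
  climate+structure; climate | geography+structure), and a Mahalanobis
  outlier scan on the first four constrained axes with genomic-inflation
  calibration (p from the upper χ² tail of D²/λ, λ = median(D²)/χ²₀.₅).
* **GEA scans** — a latent factor mixed model (Y = XBᵀ + UVᵀ + E, K = 2
  factors, five-run consensus, GIF calibration, Storey q-values) and a
  PC-corrected per-SNP scan of environment-as-trait with dual Bonferroni /
  FDR thresholds and per-SNP partial R².
* **Diversity and LD** — 20 kb / 10 kb sliding windows of SNP density, π,
  Watterson's θ and Tajima's D (per-segregating-site normalization);
  Hill–Weir LD-decay curve fits with per-chromosome decay distances.
* **Candidate mapping** — decay-distance flanking intervals around
  significant SNPs, strand-aware gene mapping from GFF3/BED, cross-method
  consensus and pleiotropy bookkeeping.
* **Synthetic landscapes** — a Balding–Nichols generator with selfing,
  spatially structured collinear climate variables, and planted logistic
  clines with a truth table, so every stage is testable end to end.

## Worked example

```r
library(landgea)

cfg <- landscapeConfig(n_individuals = 120, n_loci = 1500, n_adaptive = 30,
                       fst_groups = 0.2, cline_effect = 1.5, seed = 101)
sim <- simulateLandscape(cfg)
sim$genotypes
#> GenotypeData: 120 samples x 1500 loci
#>   chromosomes: 1H (209), 2H (206), 3H (233), 4H (223), 5H (195), 6H (210), 7H (224)
#>   missing calls: 4.97%

g <- imputeModal(ldPrune(filterLoci(sim$genotypes, "structure")))
nLoci(g)
#> [1] 1352

pca  <- genotypePCA(g)
envz <- standardizeEnv(sim$env)
six  <- c("tmax6", "prec4", "srad4", "srad5", "srad6", "srad7")

variancePartition(g, envVars(envz)[, six],
                  as.matrix(envCoords(sim$env)[, c("lat", "lon")]),
                  pca$scores[, 1:3])
#> VariancePartition (fractions of total genotype inertia):
#>     full_model pure_structure pure_geography   pure_climate     confounded
#>         0.2361         0.0990         0.0160         0.0445         0.0766
#>    unexplained
#>         0.7639

fit <- fitRDA(g, envVars(envz)[, six], Z = pca$scores[, 1:3],
              scale_loci = TRUE)
set.seed(2)
sc <- rdaOutlierScan(fit, K = 4, robust = TRUE)
sum(sc$q < 0.05)
#> [1] 13        # all 13 are planted adaptive loci (lambda = 1.09)

bonferroniThreshold(0.05, 37636)$neg_log10
#> [1] 5.877
```

Reading the numbers: the four-model partition says the full model explains
23.6% of genotype inertia, of which population structure uniquely explains
9.9 points, climate 4.5, geography 1.6, and 7.7 points are confounded
among the three. The outlier scan flags 13 loci at q < 0.05 — here all of
them planted clines, with an inflation factor near 1 indicating a
calibrated null. The Bonferroni line at −log10(p) = 5.877 is the
genome-wide threshold for a 37,636-SNP panel at α = 0.05.

`runPipeline(list(simulate = list(), seed = 1), "out/")` chains every stage
(structure → selection → pRDA → LFMM → EnvGWAS → windows → LD decay →
candidate mapping) and writes each result table as TSV plus a checksummed
manifest; `inst/scripts/run_pipeline.R` is a thin command-line wrapper.

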