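# Shared fixtures, built once per test run.

# small landscape with planted clines (used by several files)
fx_small <- local({
  cfg <- landscapeConfig(n_sites = 12, n_individuals = 120, n_groups = 3,
                         n_loci = 600, n_adaptive = 20, fst_groups = 0.2,
                         cline_effect = 1.5, n_env_vars = 6,
                         env_collinearity = 0.8, missing_rate = 0.05,
                         seed = 11)
  c(simulateLandscape(cfg), list(cfg = cfg))
})

# null landscape (no adaptive loci), moderate structure
fx_null <- local({
  cfg <- landscapeConfig(n_sites = 12, n_individuals = 120, n_groups = 3,
                         n_loci = 600, n_adaptive = 0, fst_groups = 0.2,
                         n_env_vars = 6, missing_rate = 0.05, seed = 21)
  c(simulateLandscape(cfg), list(cfg = cfg))
})

# deterministic toy genotype matrix (no simulation)
fx_toy_geno <- function(dos, chrom = NULL, pos = NULL) {
  dos <- as.matrix(dos)
  if (is.null(rownames(dos)))
    rownames(dos) <- sprintf("s%02d", seq_len(nrow(dos)))
  if (is.null(chrom)) chrom <- rep("1H", ncol(dos))
  if (is.null(pos)) pos <- seq_len(ncol(dos)) * 100L
  genotypeData(dos, chrom, pos)
}

# independent brute-force r^2 (covariance/variance arithmetic from scratch)
oracle_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  sxy <- sum((x - sum(x) / n) * (y - sum(y) / n)) / (n - 1)
  sxx <- sum((x - sum(x) / n)^2) / (n - 1)
  syy <- sum((y - sum(y) / n)^2) / (n - 1)
  (sxy * sxy) / (sxx * syy)
}
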