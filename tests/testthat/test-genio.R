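test_that("GT strings map to dosages and unsorted VCFs come back sorted", {
  tmp <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "a", "b", "c"), collapse = "\t"),
    "2H\t500\t.\tA\tT\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1H\t900\t.\tG\tC\t.\tPASS\t.\tGT\t./.\t1/0\t0|1",
    "1H\t100\t.\tA\tG\t.\tPASS\t.\tGT\t1/1\t0/0\t./."), tmp)
  g <- readGenotypes(tmp)
  expect_equal(lociTable(g)$chrom, c("1H", "1H", "2H"))
  expect_equal(lociTable(g)$pos, c(100L, 900L, 500L))
  expect_equal(unname(dosage(g)[, 1]), c(2L, 0L, NA))
  expect_equal(unname(dosage(g)[, 2]), c(NA, 1L, 1L))
  expect_equal(unname(dosage(g)[, 3]), c(0L, 1L, 2L))
  expect_equal(sampleIds(g), c("a", "b", "c"))
})

test_that("multiallelic and non-SNP records are skipped or rejected", {
  tmp <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "a", "b"), collapse = "\t"),
    "1H\t100\t.\tA\tT,G\t.\tPASS\t.\tGT\t0/0\t0/1",
    "1H\t200\t.\tAT\tA\t.\tPASS\t.\tGT\t0/0\t1/1",
    "1H\t300\t.\tA\tT\t.\tPASS\t.\tGT\t0/1\t1/1"), tmp)
  expect_message(g <- readGenotypes(tmp), "skipping 2")
  expect_equal(nLoci(g), 1L)
  expect_error(readGenotypes(tmp, multiallelic = "error"), "multiallelic")
})

test_that("locus QC statistics follow their definitions", {
  g <- fx_toy_geno(cbind(c(0, 1, 2, 2, 2),
                         c(0, 1, 1, 2, NA),
                         c(0, 0, 0, 0, 0)))
  qc <- locusQC(g)
  expect_equal(qc$maf[1], 0.3)                 # phat = 0.7
  expect_equal(qc$het_rate[2], 0.5)
  expect_equal(qc$missing_rate[2], 0.2)
  expect_equal(qc$maf[3], 0)                   # monomorphic
  expect_equal(qc$het_rate[3], 0)
})

test_that("filter sets match a brute-force rule check and are idempotent", {
  # 6 loci engineered so each rule removes one (20 samples)
  n <- 20
  mk <- function(n0, n1, n2, nmiss = 0)
    sample(c(rep(0, n0), rep(1, n1), rep(2, n2), rep(NA, nmiss)))
  set.seed(42)
  d <- cbind(mk(14, 2, 4),        # maf 0.25, het 0.1     -> keep both
             mk(18, 1, 1),        # maf 0.075             -> structure fails
             mk(19, 1, 0),        # maf 0.025             -> both fail
             mk(10, 6, 4),        # het 0.3               -> both fail
             mk(12, 2, 2, 4),     # miss 0.2: outlier fails (strict <)
             mk(8, 4, 2, 6))      # miss 0.3              -> both fail
  g <- fx_toy_geno(d)
  qc <- locusQC(g)

  brute_structure <- which(qc$missing_rate <= 0.2 & qc$het_rate <= 0.2 &
                             qc$maf >= 0.1)
  brute_outlier <- which(qc$maf > 0.05 & qc$het_rate < 0.2 &
                           qc$missing_rate < 0.2)
  gs <- filterLoci(g, "structure")
  go <- filterLoci(g, "outlier")
  expect_equal(lociTable(gs)$locus, lociTable(g)$locus[brute_structure])
  expect_equal(lociTable(go)$locus, lociTable(g)$locus[brute_outlier])

  # boundary: maf exactly 0.05 is removed under both sets
  gb <- fx_toy_geno(cbind(mk(18, 2, 0), mk(12, 2, 6)))
  expect_equal(locusQC(gb)$maf[1], 0.05)
  expect_false("1H_100" %in% lociTable(filterLoci(gb, "outlier"))$locus)
  expect_false("1H_100" %in% lociTable(filterLoci(gb, "structure"))$locus)
  expect_true("1H_200" %in% lociTable(filterLoci(gb, "outlier"))$locus)

  # idempotence and genotype preservation
  expect_identical(dosage(filterLoci(gs, "structure")), dosage(gs))
  expect_identical(dosage(gs), dosage(g)[, brute_structure])
})

test_that("modal imputation follows the documented tie rules", {
  g1 <- fx_toy_geno(cbind(c(0, 0, 2, NA)))
  expect_equal(unname(dosage(imputeModal(g1))[4, 1]), 0L)

  # tie {0,2}, mean dosage 1, equidistant -> lower dosage wins
  g2 <- fx_toy_geno(cbind(c(0, 0, 2, 2, NA)))
  expect_equal(unname(dosage(imputeModal(g2))[5, 1]), 0L)

  # tie {1,2} with mean 1.2 pulled toward 1 -> 1 wins
  g3 <- fx_toy_geno(cbind(c(0, 1, 1, 2, 2, NA)))
  expect_equal(unname(dosage(imputeModal(g3))[6, 1]), 1L)

  # no missing -> unchanged object
  g4 <- fx_toy_geno(cbind(c(0, 1, 2), c(2, 2, 0)))
  expect_identical(dosage(imputeModal(g4)), dosage(g4))

  g5 <- fx_toy_geno(cbind(c(NA, NA, NA)))
  expect_error(imputeModal(g5), "all-missing")
})

test_that("pairwise r2 equals the from-scratch oracle", {
  expect_equal(pairwiseR2(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1.0)
  expect_equal(pairwiseR2(c(0, 2, 0, 2), c(0, 0, 2, 2)), 0.0)
  expect_true(is.na(pairwiseR2(c(0, 0, 0, 0), c(0, 1, 2, 1))))
  expect_true(is.na(pairwiseR2(c(0, NA, NA, 1), c(0, 1, NA, NA))))
  set.seed(31)
  for (i in 1:5) {
    x <- rbinom(50, 2, 0.4); y <- rbinom(50, 2, 0.6)
    x[sample(50, 5)] <- NA
    expect_equal(pairwiseR2(x, y), oracle_r2(x, y), tolerance = 1e-12)
  }
})

test_that("LD pruning removes the lower-MAF member and clears all violations", {
  # two perfectly correlated loci, MAF 0.3 vs 0.2 -> 0.2 removed
  x <- c(rep(0, 14), rep(1, 2), rep(2, 4))       # maf 0.25... build explicit
  a <- c(rep(2, 6), rep(0, 14))                  # maf 0.3
  b <- c(rep(2, 4), rep(1, 4), rep(0, 12))       # maf 0.3? recompute below
  a <- c(rep(2, 6), rep(0, 14))                  # p = 0.3
  b <- a; b[1:2] <- 0                            # p = 0.2, still r2 high?
  g <- fx_toy_geno(cbind(a, a_dup = ifelse(a == 2, 2, 0)))
  # direct construction: duplicate locus with lower maf by flipping two carriers
  d <- cbind(L1 = a, L2 = b)
  g <- fx_toy_geno(d)
  qc <- locusQC(g)
  r2 <- pairwiseR2(d[, 1], d[, 2])
  if (r2 > 0.5) {
    pruned <- ldPrune(g, window_snps = 10, step_snps = 1, r2_max = 0.5)
    kept <- lociTable(pruned)$locus
    expect_equal(kept, lociTable(g)$locus[which.max(qc$maf)])
  }

  # brute-force greedy oracle on a 30-locus chromosome
  set.seed(77)
  base <- rbinom(40, 2, 0.5)
  d <- sapply(1:30, function(i) {
    x <- base
    flip <- sample(40, sample(0:25, 1))
    x[flip] <- rbinom(length(flip), 2, 0.5)
    x
  })
  g <- fx_toy_geno(d)
  w <- 12; s <- 3; thr <- 0.5
  qc <- locusQC(g)
  pos <- lociTable(g)$pos
  keep <- rep(TRUE, 30)
  repeat {
    removed <- FALSE
    for (st in seq(1, 30, by = s)) {
      win <- st:min(st + w - 1, 30)
      win <- win[keep[win]]
      if (length(win) < 2) next
      for (ai in seq_len(length(win) - 1)) {
        aa <- win[ai]
        if (!keep[aa]) next
        for (bi in (ai + 1):length(win)) {
          bb <- win[bi]
          if (!keep[bb]) next
          r2 <- oracle_r2(d[, aa], d[, bb])
          if (!is.na(r2) && r2 > thr) {
            victim <- if (qc$maf[aa] < qc$maf[bb]) aa
                      else if (qc$maf[bb] < qc$maf[aa]) bb
                      else if (pos[aa] > pos[bb]) aa else bb
            keep[victim] <- FALSE
            removed <- TRUE
            if (victim == aa) break
          }
        }
        if (!keep[aa]) next
      }
    }
    if (!removed) break
  }
  pruned <- ldPrune(g, window_snps = w, step_snps = s, r2_max = thr)
  expect_equal(lociTable(pruned)$locus, lociTable(g)$locus[keep])

  # post-condition: no surviving within-window pair violates the threshold
  surv <- which(keep)
  worst <- 0
  for (st in seq(1, 30, by = s)) {
    win <- intersect(st:min(st + w - 1, 30), surv)
    if (length(win) < 2) next
    r2w <- cor(d[, win, drop = FALSE])^2
    worst <- max(worst, max(r2w[upper.tri(r2w)]))
  }
  expect_lte(worst, thr + 1e-12)
})

test_that("pruning is invariant to step size when the window spans the chromosome", {
  g <- fx_small$genotypes[, 1:80]
  p1 <- ldPrune(g, window_snps = 200, step_snps = 1)
  p2 <- ldPrune(g, window_snps = 200, step_snps = 50)
  expect_identical(lociTable(p1)$locus, lociTable(p2)$locus)
  expect_error(ldPrune(g, window_snps = 1), "window_snps")
})
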