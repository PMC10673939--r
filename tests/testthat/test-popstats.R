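test_that("window tiling follows the documented enumeration", {
  w <- makeWindows(c(A = 50000))
  expect_equal(nrow(w), 4)
  expect_equal(w$start, c(1, 10001, 20001, 30001))
  expect_equal(w$end, c(20000, 30000, 40000, 50000))
  expect_false(any(w$partial))

  w1 <- makeWindows(c(A = 20000))
  expect_equal(nrow(w1), 1)
  expect_false(w1$partial)

  w2 <- makeWindows(c(A = 25000))
  expect_equal(nrow(w2), 2)
  expect_equal(w2$end[2], 25000)
  expect_true(w2$partial[2])

  expect_warning(makeWindows(c(A = 50000), size = 100, step = 500), "gaps")
})

test_that("per-site pi and Watterson arithmetic are exact", {
  # 2 alt among 8 chromosomes: pi = 2 * 0.25 * 0.75 * 8/7
  d <- cbind(c(2, 0, 0, 0))  # 4 diploids -> 8 chromosomes, 2 alt
  g <- fx_toy_geno(d)
  ws <- windowStats(g, makeWindows(c(`1H` = 1000), size = 1000, step = 1000))
  expect_equal(ws$pi[1], 2 * 0.25 * 0.75 * 8 / 7, tolerance = 1e-12)

  # n = 4 chromosomes: a1 = 1 + 1/2 + 1/3, theta_w = 1/a1
  d2 <- cbind(c(1, 1), c(0, 2))
  g2 <- fx_toy_geno(d2)
  ws2 <- windowStats(g2, makeWindows(c(`1H` = 1000), size = 1000, step = 1000))
  expect_equal(ws2$theta_w[1], 1 / (1 + 1/2 + 1/3), tolerance = 1e-12)
})

test_that("4-haplotype 16-site window matches a first-principles oracle", {
  set.seed(404)
  # 4 haplotypes x 16 segregating sites
  H <- matrix(0L, 4, 16)
  for (j in 1:16) {
    k <- sample(1:3, 1)                 # 1..3 alt copies keeps the site segregating
    H[sample(4, k), j] <- 1L
  }
  d <- rbind(H[1, ] + H[2, ], H[3, ] + H[4, ])   # 2 diploid individuals
  g <- fx_toy_geno(d, pos = seq(10, 160, by = 10))
  ws <- windowStats(g, makeWindows(c(`1H` = 200), size = 200, step = 200))

  # oracle: exhaustive pairwise differences and constants from scratch
  n <- 4
  pair_diff <- 0
  for (a in 1:3) for (b in (a + 1):4) pair_diff <- pair_diff + sum(H[a, ] != H[b, ])
  pi_sum <- pair_diff / choose(n, 2)
  S <- 16
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  D <- (pi_sum - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))

  expect_equal(ws$snp_count[1], S)
  expect_equal(ws$pi[1], pi_sum / S, tolerance = 1e-12)
  expect_equal(ws$theta_w[1], 1 / a1, tolerance = 1e-12)
  expect_equal(ws$tajima_d[1], D, tolerance = 1e-12)
})

test_that("window statistics are invariant to sample and locus order", {
  g <- fx_small$genotypes
  win <- makeWindows(setNames(fx_small$cfg$chrom_lengths, paste0(1:7, "H")))
  ws <- windowStats(g, win)
  gp <- g[sample(nSamples(g)), ]
  wsp <- windowStats(gp, win)
  expect_equal(ws$pi, wsp$pi, tolerance = 1e-12)
  expect_equal(ws$tajima_d, wsp$tajima_d, tolerance = 1e-12)

  # non-overlapping tiling conserves the segregating-site count
  win2 <- makeWindows(setNames(fx_small$cfg$chrom_lengths, paste0(1:7, "H")),
                      size = 20000, step = 20000)
  ws2 <- windowStats(g, win2)
  d <- dosage(g)
  p <- colSums(d, na.rm = TRUE) / (2 * colSums(!is.na(d)))
  expect_equal(sum(ws2$snp_count), sum(p > 0 & p < 1))
})

test_that("MAF filtering shifts mean window Tajima's D positive", {
  cfg <- landscapeConfig(n_individuals = 150, n_loci = 3000, n_adaptive = 0,
                         fst_groups = 0.1, missing_rate = 0, seed = 77)
  sim <- simulateLandscape(cfg)
  win <- makeWindows(setNames(cfg$chrom_lengths, paste0(1:7, "H")))
  d_all <- windowStats(sim$genotypes, win)$tajima_d
  g_maf <- filterLoci(sim$genotypes, "outlier", maf_min = 0.05,
                      het_max = 1.01, miss_max = 1.01)
  d_maf <- windowStats(g_maf, win)$tajima_d
  expect_gt(mean(d_maf, na.rm = TRUE), mean(d_all, na.rm = TRUE))
})

test_that("candidate-window comparison partitions all windows", {
  win <- makeWindows(c(`1H` = 100000))
  g <- fx_toy_geno(matrix(rbinom(20 * 40, 2, 0.4), 20, 40),
                   pos = sort(sample(1:100000, 40)))
  ws <- windowStats(g, win)

  # no intervals -> candidate class empty and flagged
  cw0 <- compareCandidateWindows(ws, NULL)
  expect_true(cw0$empty_class)
  sm0 <- cw0$summary
  expect_equal(sm0$n[sm0$class == "candidate" & sm0$statistic == "pi"], 0)

  # one interval -> the two classes partition the windows
  iv <- data.frame(chrom = "1H", start = 30001, end = 50000)
  cw <- compareCandidateWindows(ws, iv)
  expect_equal(sum(cw$candidate_flag) +
                 sum(!cw$candidate_flag), nrow(ws))
  # candidate = overlap by >= 1 bp
  expect_true(all(which(cw$candidate_flag) ==
                    which(ws$start <= 50000 & ws$end >= 30001)))

  # recount oracle: per-class mean pi recomputed by hand
  sm <- cw$summary
  for (cls in c(TRUE, FALSE)) {
    x <- ws$pi[cw$candidate_flag == cls]
    x <- x[!is.na(x)]
    got <- sm$mean[sm$class == ifelse(cls, "candidate", "noncandidate") &
                     sm$statistic == "pi"]
    expect_equal(got, mean(x), tolerance = 1e-12)
  }
})

test_that("LD decay behaves on degenerate, independent and structured data", {
  # perfect LD everywhere -> flat curve at 1, flagged
  base <- rbinom(30, 2, 0.5)
  d <- matrix(base, 30, 40)
  g <- fx_toy_geno(d, pos = sort(sample(1:200000, 40)))
  ld <- ldDecay(g, max_dist = 200000, bin = 10000)
  expect_true(all(abs(ld$bins$mean_r2 - 1) < 1e-12))
  expect_true(ld$decay$flagged[1])

  # independent loci -> background near 1/n, decay at the first distances
  set.seed(55)
  d2 <- matrix(rbinom(60 * 200, 2, 0.5), 60, 200)
  g2 <- fx_toy_geno(d2, pos = sort(sample(1:300000, 200)))
  ld2 <- ldDecay(g2, max_dist = 300000, bin = 5000)
  expect_lt(mean(ld2$bins$mean_r2), 0.05)
  if (!ld2$decay$flagged[1]) expect_lt(ld2$decay$decay_distance[1], 20000)

  # too few bins -> flagged, NA decay distance
  ld3 <- ldDecay(g2, max_dist = 20000, bin = 5000)
  expect_true(ld3$decay$flagged[1])
})

test_that("monotone-decay fixture yields a reproducible, stable decay distance", {
  mk <- function(seed) {
    set.seed(seed)
    n <- 80; L <- 150
    pos <- sort(sample(1:400000, L))
    # copy-with-distance-dependent-mutation haplotypes: adjacent loci correlate
    h1 <- matrix(0L, n, L); h2 <- matrix(0L, n, L)
    for (h in list(quote(h1), quote(h2))) {
      m <- matrix(0L, n, L)
      m[, 1] <- rbinom(n, 1, 0.5)
      for (j in 2:L) {
        swap <- rbinom(n, 1, pmin(1, (pos[j] - pos[j - 1]) / 60000)) == 1
        m[, j] <- ifelse(swap, rbinom(n, 1, 0.5), m[, j - 1])
      }
      assign(as.character(h), m)
    }
    fx_toy_geno(h1 + h2, pos = pos)
  }
  g <- mk(9001)
  d1 <- ldDecay(g, max_dist = 300000, bin = 5000)$decay$decay_distance[1]
  d1b <- ldDecay(g, max_dist = 300000, bin = 5000)$decay$decay_distance[1]
  expect_identical(d1, d1b)  # run-to-run exact

  dd <- vapply(9002:9006, function(s)
    ldDecay(mk(s), max_dist = 300000, bin = 5000)$decay$decay_distance[1],
    numeric(1))
  expect_true(all(abs(dd - d1) / d1 < 0.5))  # across seeds, same order
})
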