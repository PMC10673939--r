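test_that("RDA fit matches an explicit normal-equations oracle", {
  set.seed(12)
  n <- 20; L <- 50
  Y <- matrix(rbinom(n * L, 2, 0.5), n, L)
  rownames(Y) <- sprintf("s%02d", 1:n)
  colnames(Y) <- sprintf("l%02d", 1:L)
  X <- cbind(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  fit <- fitRDA(Y, X)

  Yc <- scale(Y, scale = FALSE)
  Xc <- scale(X, scale = FALSE)
  B <- solve(crossprod(Xc), crossprod(Xc, Yc))
  Yhat <- Xc %*% B
  expect_equal(fit$fitted, Yhat, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(fit$r2, sum(Yhat^2) / sum(Yc^2), tolerance = 1e-10)
  expect_equal(fit$adj_r2, 1 - (1 - fit$r2) * (n - 1) / (n - 3 - 1),
               tolerance = 1e-12)
  # axes: eigenvalues of Yhat' Yhat
  ev <- eigen(crossprod(Yhat), symmetric = TRUE)$values
  expect_equal(fit$eig, ev[seq_along(fit$eig)], tolerance = 1e-8)

  # partial model oracle
  Z <- cbind(rnorm(n), rnorm(n))
  pfit <- fitRDA(Y, X, Z = Z)
  H <- cbind(1, Z)
  P <- diag(n) - H %*% solve(crossprod(H), t(H))
  Yr <- P %*% Yc; Xr <- P %*% X
  B2 <- solve(crossprod(Xr), crossprod(Xr, Yr))
  expect_equal(pfit$fitted, Xr %*% B2, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(pfit$r2, sum((Xr %*% B2)^2) / sum(Yc^2), tolerance = 1e-10)
})

test_that("RDA handles perfect fit, orthogonal predictors, and collinearity", {
  n <- 30
  set.seed(2)
  x <- rnorm(n)
  cl <- runif(40, -1, 1)
  Y <- outer(x, cl)                      # y_l = c_l * x exactly
  rownames(Y) <- sprintf("s%02d", 1:n)
  fit <- fitRDA(Y, cbind(x = x))
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  expect_equal(length(fit$eig), 1)

  # orthogonal construction -> R2 = 0
  x2 <- c(rep(1, n / 2), rep(-1, n / 2))
  Yo <- matrix(rep(rnorm(n / 2), each = 2), n, 10)  # constant within +/- pairs
  Yo <- Yo - rowMeans(Yo) * 0                       # keep as is
  xo <- rep(c(1, -1), n / 2)                        # orthogonal to pair-constant Y
  fo <- fitRDA(Yo, cbind(xo))
  expect_lt(fo$r2, 1e-20)

  expect_error(fitRDA(Y, cbind(a = x, b = 2 * x)), "collinear")
})

test_that("variance partitioning identities hold and orthogonal blocks do not confound", {
  # identities on a simulated landscape
  gi <- imputeModal(fx_small$genotypes)
  envz <- standardizeEnv(fx_small$env)
  pca <- suppressWarnings(genotypePCA(gi))
  vp <- variancePartition(gi, envVars(envz),
                          as.matrix(envCoords(fx_small$env)[, c("lat", "lon")]),
                          pca$scores[, 1:3])
  expect_equal(vp$pure_structure + vp$pure_geography + vp$pure_climate +
                 vp$confounded, vp$full_model, tolerance = 1e-9)
  expect_equal(vp$full_model + vp$unexplained, 1, tolerance = 1e-9)

  # exactly orthogonal predictor blocks -> confounded = 0
  n <- 24
  A <- matrix(rnorm(n * 2), n)
  qa <- qr.Q(qr(cbind(1, matrix(rnorm(n * 7), n))))  # orthonormal basis
  blocks <- qa[, 2:7]
  clim <- blocks[, 1:2]; geo <- blocks[, 3:4]; str3 <- blocks[, 5:6]
  set.seed(4)
  Y <- matrix(rbinom(n * 60, 2, 0.5), n)
  rownames(Y) <- sprintf("s%02d", 1:n)
  vo <- variancePartition(Y, clim, geo, str3)
  expect_equal(vo$pure_structure + vo$pure_geography + vo$pure_climate,
               vo$full_model, tolerance = 1e-9)
  expect_lt(abs(vo$confounded), 1e-9)

  # duplicated climate/geography -> collinear, rejected by fitRDA
  expect_error(variancePartition(Y, clim, clim, str3), "collinear")
})

test_that("structure-only signal loads on pure_structure, not climate", {
  # beta = 0 with groups unlinked to the environment: the unique structure
  # fraction dominates and the unique climate fraction is noise-level
  cfg <- landscapeConfig(n_sites = 12, n_individuals = 120, n_groups = 3,
                         n_loci = 600, n_adaptive = 0, fst_groups = 0.3,
                         n_env_vars = 6, group_assignment = "random",
                         missing_rate = 0, seed = 41)
  sim <- simulateLandscape(cfg)
  gi <- sim$genotypes
  envz <- standardizeEnv(sim$env)
  pca <- suppressWarnings(genotypePCA(gi))
  vp <- variancePartition(gi, envVars(envz),
                          as.matrix(envCoords(sim$env)[, c("lat", "lon")]),
                          pca$scores[, 1:3])
  expect_gt(vp$pure_structure, vp$pure_climate)
  expect_lt(vp$pure_climate, 0.05)
})

test_that("outlier scan is calibrated on null data and flags planted clines", {
  # null: no adaptive loci
  gi <- imputeModal(filterLoci(fx_null$genotypes, "structure"))
  envz <- standardizeEnv(fx_null$env)
  pca <- genotypePCA(gi)
  fit <- fitRDA(gi, envVars(envz), Z = pca$scores[, 1:3])
  sc <- rdaOutlierScan(fit, K = 4)
  expect_gt(attr(sc, "lambda"), 0.5)
  expect_lt(attr(sc, "lambda"), 2)
  expect_gte(min(sc$p), 0)
  expect_lte(max(sc$p), 1)

  # SNP at the loading centroid gets D2 ~ 0, p ~ 1: inject a zero-loading SNP
  # by checking the minimum-D2 SNP has p close to the top of the scale
  expect_gt(sc$p[which.min(sc$D2)], 0.9)

  # sign-flip invariance: flipping an axis leaves p untouched
  fit2 <- fit
  fit2$loadings[, 2] <- -fit2$loadings[, 2]
  fit2$scores[, 2] <- -fit2$scores[, 2]
  sc2 <- rdaOutlierScan(fit2, K = 4)
  expect_equal(sc$p, sc2$p, tolerance = 1e-12)

  # df modes differ but rank loci identically
  scp <- rdaOutlierScan(fit, K = 4, df_mode = "df2")
  expect_equal(order(sc$D2), order(scp$D2))
  expect_equal(attr(scp, "df"), 2)

  expect_error(rdaOutlierScan(fit, K = 50), "fewer than")
})

test_that("planted clines are recovered with bounded FDR", {
  cfg <- landscapeConfig(n_sites = 16, n_individuals = 160, n_groups = 3,
                         n_loci = 1500, n_adaptive = 30, fst_groups = 0.15,
                         cline_effect = 2.5, n_env_vars = 4,
                         env_collinearity = 0.5, missing_rate = 0, seed = 91)
  sim <- simulateLandscape(cfg)
  gi <- sim$genotypes
  envz <- standardizeEnv(sim$env)
  pca <- suppressWarnings(genotypePCA(gi))
  fit <- fitRDA(gi, envVars(envz), Z = pca$scores[, 1:3], scale_loci = TRUE)
  set.seed(1)
  sc <- rdaOutlierScan(fit, K = 4, robust = TRUE)
  hits <- sc$snp[sc$q < 0.05]
  truth_ad <- sim$truth$locus[sim$truth$is_adaptive]
  power <- mean(truth_ad %in% hits)
  fdr_obs <- if (length(hits)) mean(!hits %in% truth_ad) else 0
  expect_gt(power, 0.5)
  expect_lte(fdr_obs, 0.15)
})

test_that("Bonferroni threshold arithmetic is exact", {
  expect_equal(bonferroniThreshold(0.05, 37636)$neg_log10, 5.877)
  expect_equal(bonferroniThreshold(0.05, 1)$p_cut, 0.05)
  bt <- bonferroniThreshold(0.1, 3123)
  expect_equal(bt$p_cut, 0.1 / 3123, tolerance = 1e-15)
  expect_equal(bt$neg_log10, round(-log10(3.202049952e-5), 3))
})

test_that("RDA agrees with the vegan reference implementation", {
  set.seed(33)
  n <- 25
  Y <- matrix(rbinom(n * 40, 2, 0.5), n, 40)
  rownames(Y) <- sprintf("s%02d", 1:n)
  X <- data.frame(a = rnorm(n), b = rnorm(n))
  Z <- data.frame(z1 = rnorm(n))

  v <- vegan::rda(Y ~ a + b, data = X)
  fit <- fitRDA(Y, as.matrix(X))
  expect_equal(fit$r2, unname(summary(v)$constr.chi / summary(v)$tot.chi),
               tolerance = 1e-8)
  expect_equal(fit$adj_r2, vegan::RsquareAdj(v)$adj.r.squared,
               tolerance = 1e-8)

  vp <- vegan::rda(Y ~ a + b + Condition(z1), data = cbind(X, Z))
  pfit <- fitRDA(Y, as.matrix(X), Z = as.matrix(Z))
  expect_equal(pfit$r2, unname(summary(vp)$constr.chi / summary(vp)$tot.chi),
               tolerance = 1e-8)
})
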