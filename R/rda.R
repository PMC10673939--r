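#' Fit a (partial) redundancy analysis by least squares
#'
#' Regresses the column-centred genotype matrix on an explanatory block,
#' optionally after residualizing both response and predictors on a condition
#' block (partial RDA). Constrained axes come from the singular value
#' decomposition of the fitted values. R-squared is constrained inertia over
#' the total inertia of the *unconditioned* centred genotype matrix (the
#' vegan total-inertia convention), so fractions from different partial models
#' are comparable; the adjusted R-squared uses Ezekiel's formula with m = the
#' rank of the (conditioned) explanatory block.
#'
#' @param Y genotype matrix (samples x loci, 0/1/2, imputed) or a
#'   [GenotypeData-class].
#' @param X explanatory matrix (samples x predictors).
#' @param Z optional condition (covariate) matrix.
#' @param n_axes number of constrained axes to keep (default: all).
#' @param scale_loci standardize each locus to unit variance before fitting
#'   (default `FALSE`, the plain 0/1/2 convention used for variance
#'   partitioning). The Mahalanobis outlier scan uses `TRUE` so that SNP
#'   loadings are on a common correlation scale - with raw dosages the
#'   loading magnitude carries each locus's allele-frequency variance and the
#'   chi-squared tail calibration breaks down.
#' @return list of class `RDAFit`: `scores` (sample scores, U d), `loadings`
#'   (SNP loadings V), `eig` (squared singular values, non-increasing),
#'   `r2`, `adj_r2`, `rank`, `conditioned` (names of Z columns or NULL),
#'   `fitted` (the fitted response).
#' @export
fitRDA <- function(Y, X, Z = NULL, n_axes = NULL, scale_loci = FALSE) {
  Y <- if (is(Y, "GenotypeData")) dosage(Y) else as.matrix(Y)
  storage.mode(Y) <- "double"
  X <- as.matrix(X)
  if (nrow(Y) != nrow(X)) stop("Y and X row mismatch")
  if (scale_loci) {
    sdv <- apply(Y, 2, stats::sd)
    keep <- sdv > 0
    if (!all(keep)) Y <- Y[, keep, drop = FALSE]
    Y <- scale(Y)
  }
  Yc <- scale(Y, scale = FALSE)
  tot <- sum(Yc^2)
  n <- nrow(Yc)
  if (!is.null(Z)) {
    Z <- as.matrix(Z)
    if (nrow(Z) != n) stop("Y and Z row mismatch")
    qz <- qr(cbind(1, Z))
    Yr <- qr.resid(qz, Yc)
    Xr <- qr.resid(qz, X)
  } else {
    Yr <- Yc
    Xr <- scale(X, scale = FALSE)
  }
  qx <- qr(Xr)
  if (qx$rank < ncol(Xr)) {
    culprit <- colnames(Xr)[qx$pivot[-seq_len(qx$rank)]]
    stop("explanatory block rank-deficient after conditioning; ",
         "collinear column(s): ",
         paste(culprit %||% "(unnamed)", collapse = ", "))
  }
  fit <- qr.fitted(qx, Yr)
  sv <- svd(fit)
  pos <- sv$d > max(sv$d[1], 1e-300) * 1e-10
  k <- sum(pos)
  if (!is.null(n_axes)) k <- min(k, n_axes)
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  rownames(scores) <- rownames(Y)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  rownames(loadings) <- colnames(Y)
  colnames(scores) <- colnames(loadings) <- paste0("RDA", seq_len(k))
  r2 <- sum(fit^2) / tot
  m <- qx$rank
  structure(list(scores = scores, loadings = loadings,
                 eig = sv$d[seq_len(k)]^2, r2 = r2,
                 adj_r2 = 1 - (1 - r2) * (n - 1) / (n - m - 1),
                 rank = m, conditioned = colnames(Z), fitted = fit,
                 total_inertia = tot),
            class = "RDAFit")
}

#' @export
print.RDAFit <- function(x, ...) {
  cat(sprintf("RDAFit: R2 = %.4f (adj %.4f), %d constrained axes\n",
              x$r2, x$adj_r2, length(x$eig)))
  if (!is.null(x$conditioned))
    cat("  conditioned on:", paste(x$conditioned, collapse = ", "), "\n")
  invisible(x)
}

#' Four-model partial RDA variance partitioning
#'
#' Partitions the total genotype inertia into the unique (pure) contributions
#' of population structure, geography and climate, their confounded overlap,
#' and the unexplained remainder:
#' * Model 1 (full): climate + geography + structure;
#' * Model 2: structure | climate + geography;
#' * Model 3: geography | climate + structure;
#' * Model 4: climate | geography + structure.
#' `confounded = full - (pure_structure + pure_geography + pure_climate)` and
#' `unexplained = 1 - full`. Each pure fraction is also reported as a
#' percentage of the explainable (full-model) variance.
#'
#' @param Y genotype matrix or [GenotypeData-class] (imputed 0/1/2).
#' @param climate matrix of selected climate variables.
#' @param geography matrix of lat/lon.
#' @param structure3pc matrix of the first genotype-PCA axes (typically 3).
#' @return list of class `VariancePartition` with the fractions, the
#'   `pct_of_explained` vector, and the four `RDAFit`s.
#' @export
variancePartition <- function(Y, climate, geography, structure3pc) {
  climate <- as.matrix(climate); geography <- as.matrix(geography)
  structure3pc <- as.matrix(structure3pc)
  colnames(climate) <- colnames(climate) %||% paste0("clim", seq_len(ncol(climate)))
  colnames(geography) <- colnames(geography) %||% c("lat", "lon")[seq_len(ncol(geography))]
  colnames(structure3pc) <- colnames(structure3pc) %||%
    paste0("PC", seq_len(ncol(structure3pc)))
  full <- fitRDA(Y, cbind(climate, geography, structure3pc))
  m2 <- fitRDA(Y, structure3pc, Z = cbind(climate, geography))
  m3 <- fitRDA(Y, geography, Z = cbind(climate, structure3pc))
  m4 <- fitRDA(Y, climate, Z = cbind(geography, structure3pc))
  pure <- c(structure = m2$r2, geography = m3$r2, climate = m4$r2)
  confounded <- full$r2 - sum(pure)
  structure(list(full_model = full$r2,
                 pure_structure = pure[["structure"]],
                 pure_geography = pure[["geography"]],
                 pure_climate = pure[["climate"]],
                 confounded = confounded,
                 unexplained = 1 - full$r2,
                 pct_of_explained = 100 * c(pure, confounded = confounded) / full$r2,
                 fits = list(full = full, structure = m2, geography = m3,
                             climate = m4)),
            class = "VariancePartition")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.VariancePartition <- function(x, ...) {
  cat("VariancePartition (fractions of total genotype inertia):\n")
  v <- unlist(x[c("full_model", "pure_structure", "pure_geography",
                  "pure_climate", "confounded", "unexplained")])
  print(round(v, 4))
  invisible(x)
}

#' Mahalanobis-distance outlier scan on RDA axes
#'
#' The rdadapt-style construction: each SNP's loadings on the first K
#' constrained axes (each axis standardized across SNPs) give a Mahalanobis
#' distance D2 to the across-SNP centroid; the genomic inflation factor
#' lambda = median(D2) / qchisq(0.5, df) rescales D2, and p-values come from
#' the upper tail of a chi-squared distribution. `df_mode = "axes"` uses
#' df = K (default); `"df2"` uses df = 2, a published variant that pairs
#' four axes with two degrees of freedom. q-values via [storeyQvalues()];
#' the Bonferroni flag uses a nominal alpha of 0.1 by default.
#'
#' @param fit an `RDAFit` (typically climate | structure).
#' @param K number of leading axes (default 4).
#' @param df_mode `"axes"` (df = K) or `"df2"` (df = 2).
#' @param bonferroni_alpha nominal alpha for the Bonferroni flag (default 0.1).
#' @param robust use a robust (MCD) covariance for the Mahalanobis distance
#'   instead of the classical one (default `FALSE`, deterministic).
#' @return data.frame of class `OutlierResult`: snp, D2, p, q,
#'   bonferroni_flag; attributes `lambda`, `df`, `K`.
#' @export
rdaOutlierScan <- function(fit, K = 4, df_mode = c("axes", "df2"),
                           bonferroni_alpha = 0.1, robust = FALSE) {
  df_mode <- match.arg(df_mode)
  if (ncol(fit$loadings) < K)
    stop("fit has fewer than K = ", K, " axes")
  L <- scale(fit$loadings[, seq_len(K), drop = FALSE])
  if (robust) {
    cv <- MASS::cov.rob(L, method = "mcd")
    ctr <- cv$center; S <- cv$cov
  } else {
    ctr <- colMeans(L); S <- stats::cov(L)
  }
  if (!all(is.finite(S)) || rcond(S) < 1e-12)
    stop("singular loading covariance; try fewer axes")
  D2 <- stats::mahalanobis(L, ctr, S)
  df <- if (df_mode == "axes") K else 2
  lambda <- stats::median(D2) / stats::qchisq(0.5, df)
  p <- stats::pchisq(D2 / lambda, df, lower.tail = FALSE)
  q <- storeyQvalues(p)
  res <- data.frame(snp = rownames(fit$loadings), D2 = D2, p = p, q = q,
                    bonferroni_flag = p < bonferroni_alpha / length(p),
                    stringsAsFactors = FALSE)
  attr(res, "lambda") <- lambda
  attr(res, "df") <- df
  attr(res, "K") <- K
  class(res) <- c("OutlierResult", "data.frame")
  res
}

#' Bonferroni threshold
#'
#' @param alpha family-wise alpha in (0, 1).
#' @param n_tests number of tests (>= 1).
#' @return list: `p_cut = alpha / n_tests` and `neg_log10` (reported to 3
#'   decimals).
#' @examples
#' bonferroniThreshold(0.05, 37636)$neg_log10  # 5.877
#' @export
bonferroniThreshold <- function(alpha, n_tests) {
  stopifnot(alpha > 0, alpha < 1, n_tests >= 1)
  p_cut <- alpha / n_tests
  list(p_cut = p_cut, neg_log10 = round(-log10(p_cut), 3))
}
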