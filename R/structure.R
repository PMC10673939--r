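#' Genotype principal component analysis
#'
#' Centers each locus at twice its allele frequency and scales either by
#' `sqrt(p(1-p))` (`"patterson"`, the EIGENSOFT convention; default) or by the
#' sample standard deviation (`"unit"`). Axes come from the singular value
#' decomposition of the standardized matrix; explained fractions are squared
#' singular values over their total. Zero-variance loci are dropped with a
#' warning.
#'
#' @param g a [GenotypeData-class] with no missing calls (run [imputeModal()]
#'   first), or a plain numeric matrix.
#' @param scaling `"patterson"` or `"unit"`.
#' @param n_axes number of axes to retain (default: all).
#' @return list of class `PCAResult`: `scores` (samples x axes), `loadings`
#'   (loci x axes, orthonormal columns), `explained` (fraction per axis),
#'   `center`, `scaling`.
#' @export
genotypePCA <- function(g, scaling = c("patterson", "unit"), n_axes = NULL) {
  scaling <- match.arg(scaling)
  d <- if (is(g, "GenotypeData")) dosage(g) else as.matrix(g)
  if (anyNA(d)) stop("missing calls present; impute first")
  storage.mode(d) <- "double"
  p <- colMeans(d) / 2
  sc <- switch(scaling,
               patterson = sqrt(p * (1 - p)),
               unit = apply(d, 2, stats::sd))
  zero <- sc == 0 | !is.finite(sc) | apply(d, 2, stats::sd) == 0
  if (any(zero)) {
    warning(sum(zero), " zero-variance loci dropped from PCA")
    d <- d[, !zero, drop = FALSE]; p <- p[!zero]; sc <- sc[!zero]
  }
  Z <- sweep(sweep(d, 2, 2 * p, "-"), 2, sc, "/")
  sv <- svd(Z)
  expl <- sv$d^2 / sum(sv$d^2)
  k <- if (is.null(n_axes)) length(sv$d) else min(n_axes, length(sv$d))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  rownames(scores) <- rownames(d)
  colnames(scores) <- paste0("PC", seq_len(k))
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  rownames(loadings) <- colnames(d)
  colnames(loadings) <- paste0("PC", seq_len(k))
  structure(list(scores = scores, loadings = loadings,
                 explained = expl[seq_len(k)], explained_all = expl,
                 center = 2 * p, scaling = scaling),
            class = "PCAResult")
}

#' @export
print.PCAResult <- function(x, ...) {
  cat("PCAResult:", nrow(x$scores), "samples,", ncol(x$scores), "axes\n")
  cat("  explained:", paste0(sprintf("%.1f%%", 100 * utils::head(x$explained, 5)),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Infer genetic clusters by k-means + BIC
#'
#' The cluster-inference stage used ahead of discriminant analysis: k-means
#' (20 restarts) on the retained PC scores for k = 1..`k_max`, scored by
#' `BIC(k) = n * ln(WSS_k / n) + k * ln(n)`; the selected k minimises BIC
#' (ties go to the smaller k).
#'
#' @param pca a `PCAResult` from [genotypePCA()].
#' @param k_max largest k to scan (must be < n samples).
#' @param n_axes number of PC axes to cluster on.
#' @param seed RNG seed for the restarts.
#' @param nstart k-means restarts per k (default 20).
#' @return list of class `ClusterAssignment`: `k`, `labels`, `bic` (named
#'   vector over the scanned range).
#' @export
inferClusters <- function(pca, k_max = 8, n_axes = 10, seed = 1L, nstart = 20) {
  X <- pca$scores[, seq_len(min(n_axes, ncol(pca$scores))), drop = FALSE]
  n <- nrow(X)
  if (k_max >= n) stop("k_max must be smaller than the number of samples")
  set.seed(seed)
  bic <- numeric(k_max)
  fits <- vector("list", k_max)
  for (k in seq_len(k_max)) {
    if (k == 1) {
      wss <- sum(scale(X, scale = FALSE)^2)
      fits[[k]] <- list(cluster = rep(1L, n))
    } else {
      km <- stats::kmeans(X, centers = k, nstart = nstart, iter.max = 50)
      wss <- km$tot.withinss
      fits[[k]] <- km
    }
    bic[k] <- n * log(wss / n) + k * log(n)
  }
  kbest <- which.min(bic)  # which.min returns the first (smallest k) on ties
  structure(list(k = kbest, labels = fits[[kbest]]$cluster,
                 bic = stats::setNames(bic, paste0("k", seq_len(k_max)))),
            class = "ClusterAssignment")
}

#' @export
print.ClusterAssignment <- function(x, ...) {
  cat("ClusterAssignment: k =", x$k, "\n")
  print(table(x$labels))
  invisible(x)
}

# Weir & Cockerham (1984) per-locus variance components a, b, c for the
# populations named in `labels`; rows of `d` are samples. Returns a 3 x L
# matrix. Loci where fewer than 2 populations have >= 1 call are NA.
.wcComponents <- function(d, labels) {
  pops <- unique(labels)
  r <- length(pops)
  L <- ncol(d)
  nmat <- vapply(pops, function(g)
    colSums(!is.na(d[labels == g, , drop = FALSE])), numeric(L))
  pmat <- vapply(pops, function(g) {
    sub <- d[labels == g, , drop = FALSE]
    colSums(sub, na.rm = TRUE) / (2 * colSums(!is.na(sub)))
  }, numeric(L))
  hmat <- vapply(pops, function(g) {
    sub <- d[labels == g, , drop = FALSE]
    colSums(sub == 1L, na.rm = TRUE) / colSums(!is.na(sub))
  }, numeric(L))
  nmat <- matrix(nmat, nrow = L); pmat <- matrix(pmat, nrow = L)
  hmat <- matrix(hmat, nrow = L)
  nbar <- rowMeans(nmat)
  sumn <- rowSums(nmat)
  nc <- (sumn - rowSums(nmat^2) / sumn) / (r - 1)
  pbar <- rowSums(nmat * pmat) / sumn
  s2 <- rowSums(nmat * (pmat - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(nmat * hmat) / sumn
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  rbind(a = a, b = b, c = cc)
}

#' Multi-locus Weir-Cockerham Fst between two groups of samples
#'
#' Ratio-of-sums ("weighted") estimator: per-locus variance components a
#' (among populations), b (among individuals within populations) and c
#' (within individuals) are summed over loci and Fst = sum(a) / sum(a+b+c).
#' Loci with an undefined denominator are skipped.
#'
#' @param d dosage matrix (samples x loci, NA allowed).
#' @param labels group label per sample; exactly the two groups compared.
#' @return scalar Fst estimate.
#' @export
wcFst <- function(d, labels) {
  comp <- .wcComponents(d, labels)
  denom <- colSums(comp)
  ok <- is.finite(denom) & denom > 0
  sum(comp["a", ok]) / sum(denom[ok])
}

#' Pairwise Weir-Cockerham Fst matrix
#'
#' @param g a [GenotypeData-class] or dosage matrix.
#' @param labels group label per sample; every group needs >= 2 samples.
#' @return symmetric matrix of multi-locus Fst estimates, zero diagonal.
#' @export
pairwiseFst <- function(g, labels) {
  d <- if (is(g, "GenotypeData")) dosage(g) else as.matrix(g)
  labels <- as.character(labels)
  tab <- table(labels)
  if (length(tab) < 2) stop("need >= 2 groups")
  if (any(tab < 2)) stop("every group needs >= 2 samples: ",
                         paste(names(tab)[tab < 2], collapse = ", "))
  gs <- names(tab)
  m <- matrix(0, length(gs), length(gs), dimnames = list(gs, gs))
  for (i in seq_len(length(gs) - 1)) for (j in (i + 1):length(gs)) {
    sel <- labels %in% c(gs[i], gs[j])
    m[i, j] <- m[j, i] <- wcFst(d[sel, , drop = FALSE], labels[sel])
  }
  m
}

#' Two-level analysis of molecular variance (AMOVA)
#'
#' Partitions squared Euclidean distances between units into among- and
#' within-group variance components from the mean squares, with
#' Phi_ST = sigma2_among / (sigma2_among + sigma2_within) and a permutation
#' p-value from `n_perm` label permutations of Phi_ST.
#'
#' At the default `level = "allele"` each diploid individual is expanded to
#' its two allele rows (dosage 1 becomes one reference and one alternate
#' allele), the convention of haplotype-based AMOVA for genotypic data; the
#' resulting Phi_ST estimates the same allele-frequency differentiation as
#' Weir-Cockerham Fst. `level = "dosage"` works directly on the genotype
#' vectors (its Phi_ST then measures genotypic rather than allelic
#' differentiation, roughly 2F/(1+F) under a Balding-Nichols model with
#' differentiation F). Missing calls are mean-imputed per locus before the
#' expansion. Negative components are truncated to 0 and flagged.
#' Permutations always shuffle whole individuals.
#'
#' @param g a [GenotypeData-class] or dosage matrix.
#' @param labels group label per sample (>= 2 groups).
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @param level `"allele"` (default) or `"dosage"`.
#' @return list of class `AMOVA`: `sigma_among`, `sigma_within`, `pct_among`,
#'   `pct_within`, `phi_st`, `p_perm`, `truncated`.
#' @export
amova <- function(g, labels, n_perm = 999, seed = 1L,
                  level = c("allele", "dosage")) {
  level <- match.arg(level)
  d <- if (is(g, "GenotypeData")) dosage(g) else as.matrix(g)
  storage.mode(d) <- "double"
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) stop("need >= 2 groups")
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 2]]
  }
  n_ind <- nrow(d)
  labels_ind <- labels
  if (level == "allele") {
    # expand to two allele rows per individual: dosage 0 -> (0,0),
    # 1 -> (0,1), 2 -> (1,1); imputed fractional dosages split evenly
    d <- rbind(pmax(d - 1, 0), pmin(d, 1))
    labels <- c(labels, labels)
  }
  D2 <- as.matrix(stats::dist(d))^2
  N <- nrow(d)

  ss_from <- function(lab) {
    sswithin <- 0
    for (gr in unique(lab)) {
      sel <- which(lab == gr)
      if (length(sel) > 1)
        sswithin <- sswithin + sum(D2[sel, sel]) / (2 * length(sel))
    }
    sswithin
  }
  ss_total <- sum(D2) / (2 * N)
  ss_within <- ss_from(labels)
  ss_among <- ss_total - ss_within

  k <- length(unique(labels))
  ngs <- table(labels)
  n0 <- (N - sum(ngs^2) / N) / (k - 1)
  ms_among <- ss_among / (k - 1)
  ms_within <- ss_within / (N - k)
  sigma_within <- ms_within
  sigma_among <- (ms_among - ms_within) / n0
  truncated <- FALSE
  if (sigma_among < 0) { sigma_among <- 0; truncated <- TRUE }
  tot <- sigma_among + sigma_within
  phi <- sigma_among / tot

  set.seed(seed)
  phi_perm <- function(lab) {
    ssw <- ss_from(lab)
    sa <- ((ss_total - ssw) / (k - 1) - ssw / (N - k)) / n0
    sw <- ssw / (N - k)
    max(sa, 0) / (max(sa, 0) + sw)
  }
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    pl <- sample(labels_ind)
    if (level == "allele") pl <- c(pl, pl)
    if (phi_perm(pl) >= phi) exceed <- exceed + 1L
  }
  p <- (exceed + 1) / (n_perm + 1)

  structure(list(sigma_among = sigma_among, sigma_within = sigma_within,
                 pct_among = 100 * sigma_among / tot,
                 pct_within = 100 * sigma_within / tot,
                 phi_st = phi, p_perm = p, truncated = truncated,
                 n_perm = n_perm),
            class = "AMOVA")
}

#' @export
print.AMOVA <- function(x, ...) {
  cat(sprintf("AMOVA: among %.2f%%, within %.2f%% (Phi_ST = %.4f, p = %.4g)\n",
              x$pct_among, x$pct_within, x$phi_st, x$p_perm))
  if (x$truncated) cat("  note: negative among-group component truncated to 0\n")
  invisible(x)
}
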