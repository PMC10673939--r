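#' PC-corrected per-SNP environmental association scan (EnvGWAS)
#'
#' Treats each environmental variable as the trait and tests every SNP with
#' ordinary least squares `env ~ dosage + PC1..PCn`, scanning a small grid of
#' genetic-PC counts; for each variable the PC count whose genomic inflation
#' factor is closest to 1 is retained (an automated stand-in for QQ-plot
#' inspection). This is a deliberate single-locus substitute for multi-locus
#' iterative mixed-model scans such as FarmCPU: downstream consumers need only
#' per-SNP tests, dual thresholds, and per-SNP variance explained, all of
#' which are preserved. No kinship random effect is used.
#'
#' Internally the scan is vectorized: env and all dosages are residualized on
#' the PC block, the squared partial correlation gives both the t-statistic
#' (`t = r sqrt(df) / sqrt(1 - r^2)`, df = n - n_pcs - 2) and the partial
#' R-squared.
#'
#' @param g [GenotypeData-class] or dosage matrix (imputed; typically the
#'   "outlier" filter set).
#' @param env [EnvData-class] (raw variables are used, as association traits).
#' @param pcs genotype PC score matrix (from the LD-pruned set).
#' @param pc_grid candidate PC counts (default `2:4`).
#' @param alpha Bonferroni family-wise alpha (default 0.05).
#' @param fdr Storey q-value threshold (default 0.05).
#' @return list of class `EnvGWASResult`: `results` (snp, variable, beta, t,
#'   p, q, partial_r2, bonferroni_flag, fdr_flag), `chosen_pcs` and `lambda`
#'   per variable, `skipped` monomorphic-SNP count, `p_cut`.
#' @export
envAssocScan <- function(g, env, pcs, pc_grid = 2:4, alpha = 0.05, fdr = 0.05) {
  d <- if (is(g, "GenotypeData")) dosage(g) else as.matrix(g)
  storage.mode(d) <- "double"
  if (anyNA(d)) stop("missing genotype calls; impute first")
  V <- envVars(env)
  pcs <- as.matrix(pcs)
  n <- nrow(d)
  mono <- apply(d, 2, stats::sd) == 0
  skipped <- sum(mono)
  d <- d[, !mono, drop = FALSE]
  Ln <- ncol(d)
  p_cut <- alpha / Ln

  # residualize the dosage matrix once per candidate PC count
  blocks <- lapply(pc_grid, function(np) {
    qb <- qr(cbind(1, pcs[, seq_len(np), drop = FALSE]))
    Gr <- qr.resid(qb, d)
    list(np = np, qb = qb, Gr = Gr, gss = colSums(Gr^2))
  })
  out <- list()
  chosen <- stats::setNames(integer(ncol(V)), colnames(V))
  lam_chosen <- stats::setNames(numeric(ncol(V)), colnames(V))
  for (v in colnames(V)) {
    best <- NULL
    for (bl in blocks) {
      np <- bl$np
      er <- qr.resid(bl$qb, V[, v])
      gss <- bl$gss
      ok <- gss > 1e-12
      r <- rep(NA_real_, Ln)
      r[ok] <- as.numeric(crossprod(bl$Gr[, ok, drop = FALSE], er)) /
        sqrt(gss[ok] * sum(er^2))
      dfree <- n - np - 2
      tstat <- r * sqrt(dfree) / sqrt(pmax(1 - r^2, 1e-300))
      p <- 2 * stats::pt(-abs(tstat), dfree)
      lam <- stats::median(stats::qchisq(p, 1, lower.tail = FALSE),
                           na.rm = TRUE) / .CHI1_MEDIAN
      if (is.null(best) || abs(lam - 1) < abs(best$lam - 1))
        best <- list(np = np, lam = lam, r = r, t = tstat, p = p,
                     beta = as.numeric(crossprod(bl$Gr, er)) / gss)
    }
    chosen[v] <- best$np
    lam_chosen[v] <- best$lam
    pv <- best$p
    pv_ok <- !is.na(pv)
    q <- rep(NA_real_, Ln)
    q[pv_ok] <- storeyQvalues(pv[pv_ok])
    out[[v]] <- data.frame(snp = colnames(d), variable = v,
                           beta = best$beta, t = best$t, p = pv, q = q,
                           partial_r2 = best$r^2,
                           bonferroni_flag = !is.na(pv) & pv < p_cut,
                           fdr_flag = !is.na(q) & q < fdr,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(list(results = res, chosen_pcs = chosen, lambda = lam_chosen,
                 skipped = skipped, p_cut = p_cut, alpha = alpha, fdr = fdr),
            class = "EnvGWASResult")
}

#' @export
print.EnvGWASResult <- function(x, ...) {
  cat("EnvGWASResult:", length(unique(x$results$variable)), "variables,",
      length(unique(x$results$snp)), "SNPs\n")
  cat("  Bonferroni hits:", sum(x$results$bonferroni_flag),
      " FDR hits:", sum(x$results$fdr_flag), "\n")
  if (x$skipped) cat("  monomorphic SNPs skipped:", x$skipped, "\n")
  invisible(x)
}

#' Partial R-squared of one SNP for one environmental variable
#'
#' Nested-model definition: `(RSS_cov - RSS_full) / RSS_cov`, where the
#' covariate model regresses the variable on the PCs only and the full model
#' adds the SNP dosage.
#'
#' @param g [GenotypeData-class] or dosage matrix.
#' @param env_variable numeric vector (the trait).
#' @param snp locus id or column index.
#' @param pcs PC score matrix, or `NULL` for no covariates.
#' @return fraction in [0, 1]; `NA` (with a warning) when the covariate model
#'   already fits perfectly.
#' @export
partialR2 <- function(g, env_variable, snp, pcs = NULL) {
  d <- if (is(g, "GenotypeData")) dosage(g) else as.matrix(g)
  x <- d[, snp]
  B <- if (is.null(pcs)) matrix(1, length(x), 1) else cbind(1, as.matrix(pcs))
  rss_cov <- sum(qr.resid(qr(B), env_variable)^2)
  if (rss_cov < 1e-300) {
    warning("covariate model fits perfectly; partial R2 undefined")
    return(NA_real_)
  }
  rss_full <- sum(qr.resid(qr(cbind(B, x)), env_variable)^2)
  (rss_cov - rss_full) / rss_cov
}
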