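# chi-squared(1) median, hard-coded to 4 decimals for the GIF denominator
.CHI1_MEDIAN <- 0.4549

#' Fit a latent factor mixed model for one environmental variable
#'
#' Model: `Y = X B' + U V' + E`, with Y the imputed dosage matrix, X a single
#' standardized environmental variable, and K latent factors U absorbing
#' unobserved structure.
#'
#' Two estimation modes:
#' * `"pc-factors"` (default, deterministic): U is fixed to the first K
#'   genotype-PCA score axes; per-locus effect and z-score come from ordinary
#'   least squares of each locus on (1, X, U).
#' * `"alternate"`: alternate (i) a ridge update of B given U and (ii) a
#'   rank-K singular decomposition of `Y - X B'` for U, V, until the relative
#'   change in the fitted low-rank term drops below 1e-6 (or 200 iterations,
#'   with a warning); z-scores then come from the per-locus regression
#'   including the estimated U.
#'
#' `K = 0` reduces to plain per-locus regression on X.
#'
#' @param Y [GenotypeData-class] or imputed dosage matrix.
#' @param x one environmental variable (numeric vector; standardized
#'   internally).
#' @param K number of latent factors (default 2).
#' @param mode `"pc-factors"` or `"alternate"`.
#' @param ridge_lambda ridge penalty for the alternate mode (default 1e-5).
#' @param seed RNG seed (alternate mode initialisation only).
#' @param max_iter,tol alternate-mode controls.
#' @return data.frame of class `LFMMResult`: snp, beta, z, p_raw; attributes
#'   `K`, `mode`, `iterations`.
#' @export
fitLFMMRidge <- function(Y, x, K = 2, mode = c("pc-factors", "alternate"),
                         ridge_lambda = 1e-5, seed = 1L,
                         max_iter = 200, tol = 1e-6) {
  mode <- match.arg(mode)
  Y <- if (is(Y, "GenotypeData")) dosage(Y) else as.matrix(Y)
  storage.mode(Y) <- "double"
  if (anyNA(Y)) stop("missing genotype calls; impute first")
  n <- nrow(Y)
  x <- as.numeric(scale(x))
  iterations <- 0L
  if (K > 0 && mode == "pc-factors") {
    U <- genotypePCA(Y, scaling = "patterson")$scores[, seq_len(K), drop = FALSE]
  } else if (K > 0) {
    set.seed(seed)
    Yc <- scale(Y, scale = FALSE)
    sv <- svd(Yc, nu = K, nv = K)
    U <- sv$u %*% diag(sv$d[seq_len(K)], K)
    V <- sv$v
    B <- rep(0, ncol(Y))
    prev <- U %*% t(V)
    for (it in seq_len(max_iter)) {
      iterations <- it
      # ridge update of B given the latent term
      R <- Yc - U %*% t(V)
      B <- as.numeric(crossprod(R, x)) / (sum(x^2) + ridge_lambda)
      # rank-K refit of the residual
      sv <- svd(Yc - outer(x, B), nu = K, nv = K)
      U <- sv$u %*% diag(sv$d[seq_len(K)], K)
      V <- sv$v
      cur <- U %*% t(V)
      delta <- sqrt(sum((cur - prev)^2)) / max(sqrt(sum(prev^2)), 1e-12)
      prev <- cur
      if (delta < tol) break
    }
    if (iterations == max_iter && delta >= tol)
      warning("alternate mode did not converge in ", max_iter, " iterations")
  }
  D <- if (K > 0) cbind(`(Intercept)` = 1, x = x, U) else
    cbind(`(Intercept)` = 1, x = x)
  if (K > 0) {
    cn <- stats::cor(x, D[, -(1:2), drop = FALSE])
    if (any(abs(cn) > 0.999))
      warning("environmental variable nearly collinear with a latent factor")
  }
  DtD <- crossprod(D)
  DtDi <- solve(DtD)
  Bhat <- DtDi %*% crossprod(D, Y)          # p x L coefficients
  resid <- Y - D %*% Bhat
  dfree <- n - ncol(D)
  s2 <- colSums(resid^2) / dfree
  se <- sqrt(s2 * DtDi["x", "x"])
  beta <- Bhat["x", ]
  z <- beta / se
  z[!is.finite(z)] <- 0  # zero-variance loci carry no evidence
  res <- data.frame(snp = colnames(Y) %||% paste0("L", seq_len(ncol(Y))),
                    beta = beta, z = z,
                    p_raw = 2 * stats::pnorm(-abs(z)),
                    stringsAsFactors = FALSE)
  attr(res, "K") <- K
  attr(res, "mode") <- mode
  attr(res, "iterations") <- iterations
  class(res) <- c("LFMMResult", "data.frame")
  res
}

#' Genomic-inflation-factor calibration of z-scores
#'
#' `lambda = median(z^2) / 0.4549` (the chi-squared(1) median); calibrated
#' p-values are the upper chi-squared(1) tail at `z^2 / lambda`. Scaling all
#' z by a constant leaves the calibrated p unchanged.
#'
#' @param z numeric vector of z-scores (warns below 100 tests).
#' @return list: `lambda`, `p` (calibrated).
#' @export
gifCalibrate <- function(z) {
  if (all(z == 0)) stop("all z-scores are zero; lambda undefined")
  if (length(z) < 100) warning("fewer than 100 tests; lambda estimate unstable")
  lambda <- stats::median(z^2) / .CHI1_MEDIAN
  list(lambda = lambda,
       p = stats::pchisq(z^2 / lambda, df = 1, lower.tail = FALSE))
}

#' Storey q-values
#'
#' Estimates the null proportion pi0 with the Storey-Tibshirani smoother:
#' `pi0(lambda) = #\{p > lambda\} / (m (1 - lambda))` over the grid
#' lambda = 0.05, 0.10, ..., 0.95, smoothed by a natural cubic spline (df = 3)
#' and evaluated at the largest lambda, clamped to (0, 1]. Then
#' `q_i = min over t >= p_i of pi0 m t / #\{p <= t\}`, enforced monotone.
#' With fewer than 100 p-values, pi0 falls back to 1 (the Benjamini-Hochberg
#' equivalence).
#'
#' @param p vector of p-values in [0, 1].
#' @param pi0 optionally force pi0 (e.g. 1 for plain BH).
#' @return q-value vector, same order as `p`; attribute `pi0`.
#' @export
storeyQvalues <- function(p, pi0 = NULL) {
  if (any(p < 0 | p > 1, na.rm = TRUE) || anyNA(p))
    stop("p-values must lie in [0, 1] with no NA")
  m <- length(p)
  if (is.null(pi0)) {
    if (m < 100) {
      pi0 <- 1
    } else {
      lam <- seq(0.05, 0.95, by = 0.05)
      pi0l <- vapply(lam, function(l) mean(p > l) / (1 - l), numeric(1))
      fit <- stats::smooth.spline(lam, pi0l, df = 3)
      pi0 <- stats::predict(fit, x = max(lam))$y
      pi0 <- min(max(pi0, 1 / m), 1)
    }
  }
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pi0 * m * p[o] / rank(p, ties.method = "max")[o]
  q <- pmin(cummin(q), 1)
  res <- q[ro]
  attr(res, "pi0") <- pi0
  res
}

#' Multi-run LFMM scan over all environmental variables
#'
#' Runs [fitLFMMRidge()] for every climate variable `n_runs` times with
#' distinct seeds, calibrates each run's z-scores by the genomic inflation
#' factor, computes Storey q-values, and declares a (SNP, variable) pair
#' significant only if `q < fdr` in **all** runs (intersection consensus).
#' In `"pc-factors"` mode the runs are deterministic and identical, which is
#' recorded in the result.
#'
#' @param Y [GenotypeData-class] or imputed dosage matrix.
#' @param env [EnvData-class] (standardized or raw; variables are standardized
#'   per fit).
#' @param K latent factors (default 2).
#' @param n_runs replicate runs (default 5).
#' @param fdr q-value threshold (default 0.05).
#' @param mode passed to [fitLFMMRidge()].
#' @param seeds integer vector of length `n_runs` (default `seed + 0:4`).
#' @param seed base seed when `seeds` is not given.
#' @return list of class `LFMMScan`: `results` (per-run long data.frame:
#'   snp, variable, run, beta, z, p_raw, p_cal, q, significant), `consensus`
#'   (snp, variable pairs significant in all runs), `lambda` (per variable x
#'   run), `deterministic` flag.
#' @export
lfmmScan <- function(Y, env, K = 2, n_runs = 5, fdr = 0.05,
                     mode = c("pc-factors", "alternate"), seeds = NULL,
                     seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(seeds)) seeds <- seed + seq_len(n_runs) - 1L
  stopifnot(length(seeds) == n_runs)
  V <- envVars(env)
  deterministic <- mode == "pc-factors"
  runs <- list()
  lambda <- matrix(NA_real_, ncol(V), n_runs,
                   dimnames = list(colnames(V), paste0("run", seq_len(n_runs))))
  for (v in colnames(V)) {
    base_fit <- NULL
    for (r in seq_len(n_runs)) {
      if (deterministic && !is.null(base_fit)) {
        fit <- base_fit
      } else {
        fit <- fitLFMMRidge(Y, V[, v], K = K, mode = mode, seed = seeds[r])
        if (deterministic) base_fit <- fit
      }
      cal <- gifCalibrate(fit$z)
      lambda[v, r] <- cal$lambda
      q <- storeyQvalues(cal$p)
      runs[[length(runs) + 1L]] <-
        data.frame(snp = fit$snp, variable = v, run = r, beta = fit$beta,
                   z = fit$z, p_raw = fit$p_raw, p_cal = cal$p,
                   q = as.numeric(q), significant = q < fdr,
                   stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, runs)
  byrun <- stats::aggregate(significant ~ snp + variable, data = results,
                            FUN = all)
  consensus <- byrun[byrun$significant, c("snp", "variable")]
  rownames(consensus) <- NULL
  structure(list(results = results, consensus = consensus, lambda = lambda,
                 deterministic = deterministic, fdr = fdr, K = K,
                 n_runs = n_runs),
            class = "LFMMScan")
}

#' @export
print.LFMMScan <- function(x, ...) {
  cat("LFMMScan: K =", x$K, ",", x$n_runs, "runs",
      if (x$deterministic) "(deterministic: runs identical)" else "", "\n")
  cat("  consensus hits:", nrow(x$consensus), "(q <", x$fdr, "in all runs)\n")
  invisible(x)
}
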