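#' Standardize climate variables
#'
#' Z-scores every climate variable; geography (lat/lon/alt) stays unscaled in
#' its own slot. Constant variables are dropped with a warning naming them.
#' Idempotent.
#'
#' @param env an [EnvData-class].
#' @return an [EnvData-class] with `standardized = TRUE`.
#' @export
standardizeEnv <- function(env) {
  v <- envVars(env)
  if (anyNA(v)) stop("missing values in environment table")
  sdv <- apply(v, 2, stats::sd)
  const <- sdv == 0
  if (any(const)) {
    warning("constant variable(s) dropped: ",
            paste(colnames(v)[const], collapse = ", "))
    v <- v[, !const, drop = FALSE]
  }
  z <- scale(v)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  envData(sampleIds(env), envCoords(env), z, site = envSites(env),
          standardized = TRUE)
}

#' PCA of the climate variables
#'
#' Unit-scaled principal component analysis of the (standardized) climate
#' matrix; loadings expose the sign and magnitude of each variable on each
#' axis, and explained fractions sum to 1 over all axes. When there are fewer
#' samples than variables the axis count is capped at the matrix rank.
#'
#' @param env an [EnvData-class]; standardized (a raw table is standardized on
#'   the fly with a message).
#' @return a `PCAResult` (see [genotypePCA()]).
#' @export
envPCA <- function(env) {
  if (!isStandardized(env)) {
    message("standardizing climate variables for PCA")
    env <- standardizeEnv(env)
  }
  v <- envVars(env)
  sv <- svd(scale(v))  # already z-scored; scale() re-centers defensively
  expl <- sv$d^2 / sum(sv$d^2)
  k <- sum(sv$d > sv$d[1] * 1e-12)
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  rownames(scores) <- sampleIds(env)
  colnames(scores) <- paste0("PC", seq_len(k))
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  rownames(loadings) <- colnames(v)
  colnames(loadings) <- paste0("PC", seq_len(k))
  structure(list(scores = scores, loadings = loadings,
                 explained = expl[seq_len(k)], explained_all = expl,
                 scaling = "unit"),
            class = "PCAResult")
}

# R^2 of the RDA of (column-centred) Y on predictor matrix X, via QR
.rdaR2 <- function(Yc, X, tot) {
  qx <- qr(cbind(1, as.matrix(X)))
  fit <- qr.fitted(qx, Yc)
  sum(fit^2) / tot
}

#' Forward selection of climate variables against the genotype matrix
#'
#' Stepwise forward selection for the redundancy analysis of genotypes on
#' climate (an `ordiR2step`-style procedure). Starting from an empty model,
#' each step evaluates every unselected variable's gain in adjusted R-squared
#' (Ezekiel: `1 - (1 - R2) (n - 1)/(n - m - 1)`, m = number of selected
#' variables); the best candidate is admitted only if (i) its marginal
#' permutation p-value is at most `alpha` (the candidate's contribution,
#' residualized on the selected set, is row-permuted `n_perm` times) and
#' (ii) the running adjusted R-squared does not exceed that of the global
#' (all-variable) model. Selection stops when either rule fails.
#'
#' @param g a [GenotypeData-class] (imputed, typically the LD-pruned set) or
#'   dosage matrix.
#' @param env a standardized [EnvData-class].
#' @param alpha per-step permutation significance threshold (default 0.05).
#' @param n_perm number of row permutations (default 999; < 99 warns).
#' @param seed RNG seed.
#' @param max_steps optional cap on the number of selection steps.
#' @return list of class `SelectionTrace`: `selected` (ordered names),
#'   `adj_r2` (running value after each step), `p_perm` (per admitted step),
#'   `stop_reason`, `global_adj_r2`, plus the trace data.frame.
#' @export
forwardSelect <- function(g, env, alpha = 0.05, n_perm = 999, seed = 1L,
                          max_steps = Inf) {
  if (n_perm < 99) warning("n_perm < 99: permutation p-values unstable")
  if (!isStandardized(env)) env <- standardizeEnv(env)
  Y <- if (is(g, "GenotypeData")) dosage(g) else as.matrix(g)
  if (anyNA(Y)) stop("missing genotype calls; impute first")
  storage.mode(Y) <- "double"
  Yc <- scale(Y, scale = FALSE)
  tot <- sum(Yc^2)
  V <- envVars(env)
  n <- nrow(Yc)
  adj <- function(r2, m) 1 - (1 - r2) * (n - 1) / (n - m - 1)
  global_adj <- adj(.rdaR2(Yc, V, tot), ncol(V))

  set.seed(seed)
  selected <- character()
  trace <- data.frame(variable = character(), r2 = numeric(),
                      adj_r2 = numeric(), p_perm = numeric(),
                      stringsAsFactors = FALSE)
  r2_cur <- 0
  stop_reason <- "all variables selected"
  while (length(selected) < ncol(V) && length(selected) < max_steps) {
    cand <- setdiff(colnames(V), selected)
    r2_new <- vapply(cand, function(v)
      .rdaR2(Yc, V[, c(selected, v), drop = FALSE], tot), numeric(1))
    best <- cand[which.max(r2_new)]
    r2_best <- max(r2_new)
    adj_best <- adj(r2_best, length(selected) + 1)
    if (adj_best > global_adj + 1e-12) {
      stop_reason <- "adjusted R2 would exceed the global model"
      break
    }
    # marginal permutation test of the best candidate
    base <- if (length(selected))
      cbind(1, V[, selected, drop = FALSE]) else matrix(1, n, 1)
    qb <- qr(base)
    vres <- qr.resid(qb, V[, best])
    gain_obs <- r2_best - r2_cur
    P <- vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))
    U <- qr.resid(qb, matrix(vres[P], n, n_perm))  # re-residualize permuted copies
    norms <- sqrt(colSums(U^2))
    ok <- norms > 1e-12
    gains <- rep(0, n_perm)
    if (any(ok)) {
      Un <- sweep(U[, ok, drop = FALSE], 2, norms[ok], "/")
      gains[ok] <- colSums(crossprod(Yc, Un)^2) / tot
    }
    p <- (1 + sum(gains >= gain_obs - 1e-15)) / (n_perm + 1)
    if (p > alpha) {
      stop_reason <- sprintf("best candidate '%s' not significant (p = %.4g)",
                             best, p)
      break
    }
    selected <- c(selected, best)
    r2_cur <- r2_best
    trace <- rbind(trace, data.frame(variable = best, r2 = r2_best,
                                     adj_r2 = adj_best, p_perm = p))
  }
  if (length(selected) == ncol(V)) stop_reason <- "all variables selected"
  else if (length(selected) >= max_steps &&
           !startsWith(stop_reason, "best") &&
           !startsWith(stop_reason, "adjusted"))
    stop_reason <- "max_steps reached"
  structure(list(selected = selected, adj_r2 = trace$adj_r2,
                 p_perm = trace$p_perm, trace = trace,
                 global_adj_r2 = global_adj, stop_reason = stop_reason),
            class = "SelectionTrace")
}

#' @export
print.SelectionTrace <- function(x, ...) {
  cat("SelectionTrace:", length(x$selected), "variable(s) selected\n")
  if (nrow(x$trace)) print(x$trace, row.names = FALSE)
  cat("  stop:", x$stop_reason, "\n")
  invisible(x)
}
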