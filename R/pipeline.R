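#' Default pipeline parameters
#'
#' The canonical parameter set of the full inference chain: structure-set
#' filter (missing <= 0.2, het <= 0.2, MAF >= 0.1); outlier-set filter
#' (MAF > 0.05, het < 0.2, missing < 0.2); LD pruning (window 150 SNPs,
#' step 5, r2 0.5); 3 structure PCs in the partial RDA; outlier scan on
#' K = 4 axes with Bonferroni alpha 0.1; LFMM with K = 2 latent factors,
#' 5 runs, FDR 0.05; EnvGWAS over 2-4 PCs with alpha 0.05 and FDR 0.05;
#' 20 kb / 10 kb diversity windows; 300 kb maximum LD-decay distance.
#'
#' @return nested list of defaults; override entries via [runPipeline()]'s
#'   `config`.
#' @export
pipelineDefaults <- function() {
  list(
    filter = list(structure = list(maf_min = 0.1, het_max = 0.2, miss_max = 0.2),
                  outlier = list(maf_min = 0.05, het_max = 0.2, miss_max = 0.2)),
    prune = list(window_snps = 150, step_snps = 5, r2_max = 0.5),
    structure_pcs = 3,
    cluster = list(k_max = 8, n_axes = 10),
    forward = list(alpha = 0.05, n_perm = 199),
    rdadapt = list(K = 4, df_mode = "axes", bonferroni_alpha = 0.1,
                   robust = TRUE, scale_loci = TRUE),
    lfmm = list(K = 2, n_runs = 5, fdr = 0.05, mode = "pc-factors"),
    envgwas = list(pc_grid = 2:4, alpha = 0.05, fdr = 0.05),
    windows = list(size = 20000, step = 10000),
    ld = list(max_dist = 300000, bin = 5000),
    amova = list(n_perm = 999)
  )
}

.mergeConfig <- function(defaults, over) {
  for (nm in names(over)) {
    if (is.list(defaults[[nm]]) && is.list(over[[nm]]))
      defaults[[nm]] <- .mergeConfig(defaults[[nm]], over[[nm]])
    else defaults[[nm]] <- over[[nm]]
  }
  defaults
}

.logmsg <- function(...) message(format(Sys.time(), "[%H:%M:%S] "), ...)

#' Run the full landscape-genomics pipeline
#'
#' Executes, in order: data simulation (or loading), genotype QC and the two
#' filter sets, LD pruning, genotype PCA and cluster inference, pairwise Fst
#' and AMOVA, climate standardization and forward selection, the four-model
#' partial-RDA variance partitioning and the RDA outlier scan, the LFMM and
#' EnvGWAS association scans, sliding-window diversity statistics and LD
#' decay, and candidate-interval/gene mapping with cross-method consensus.
#' Every stage's parameters and row counts are logged via `message()`; all
#' result tables are written as TSVs into `outdir` and listed, with MD5
#' checksums, in the returned manifest.
#'
#' @param config either a nested list or a YAML file path. Recognised top
#'   level entries: `simulate` (a list of [landscapeConfig()] arguments) OR
#'   `input` (list with `vcf`, `env` and optionally `gff` paths); `seed`;
#'   any of the [pipelineDefaults()] entries to override; `exclude_samples`
#'   (ids dropped before analysis).
#' @param outdir output directory for the result TSVs.
#' @param seed overrides `config$seed` when given.
#' @return list: `manifest` (data.frame file/path/md5), `tables` (the result
#'   objects, invisibly large), `params` (the merged parameter list).
#' @export
runPipeline <- function(config, outdir, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  params <- .mergeConfig(pipelineDefaults(),
                         config[setdiff(names(config),
                                        c("simulate", "input", "seed",
                                          "exclude_samples"))])
  seed <- as.integer(seed %||% config$seed %||% 1L)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)

  # --- inputs -------------------------------------------------------------
  if (!is.null(config$simulate)) {
    .logmsg("simulating landscape dataset (seed ", seed, ")")
    simargs <- config$simulate
    if (isTRUE(simargs)) simargs <- list()
    cfg <- do.call(landscapeConfig, utils::modifyList(simargs, list(seed = seed)))
    sim <- simulateLandscape(cfg)
    g <- sim$genotypes; env <- sim$env; truth <- sim$truth
    chrom_lengths <- stats::setNames(cfg$chrom_lengths, paste0(1:7, "H"))
    genes <- .syntheticGenes(truth, as.list(chrom_lengths), seed = cfg$seed)
    utils::write.table(truth, file.path(outdir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    inp <- config$input
    for (f in c("vcf", "env"))
      if (is.null(inp[[f]])) stop("config$input$", f, " is required")
    for (f in c("vcf", "env"))
      if (!file.exists(inp[[f]])) stop("input file not found: ", inp[[f]])
    .logmsg("reading ", inp$vcf)
    g <- readGenotypes(inp$vcf)
    env <- readEnvTable(inp$env)
    genes <- if (!is.null(inp$gff)) readGenes(inp$gff) else NULL
    truth <- NULL
    chrom_lengths <- tapply(GenomicRanges::start(loci(g)),
                            as.character(GenomicRanges::seqnames(loci(g))), max)
  }
  if (!is.null(config$exclude_samples)) {
    keep <- !sampleIds(g) %in% config$exclude_samples
    .logmsg("excluding ", sum(!keep), " samples")
    g <- g[keep, ]
    sel <- sampleIds(env) %in% sampleIds(g)
    env <- envData(sampleIds(env)[sel], envCoords(env)[sel, ],
                   envVars(env)[sel, , drop = FALSE],
                   site = if (length(envSites(env))) envSites(env)[sel]
                          else integer())
  }
  stopifnot(identical(sampleIds(g), sampleIds(env)))

  tsv <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  files <- character()

  # --- QC + filters -------------------------------------------------------
  qc <- qcReport(g)
  files["qc"] <- tsv(qc, "qc_report.tsv")
  fs <- params$filter$structure
  g_struct <- filterLoci(g, "structure", fs$maf_min, fs$het_max, fs$miss_max)
  fo <- params$filter$outlier
  g_out <- filterLoci(g, "outlier", fo$maf_min, fo$het_max, fo$miss_max)
  .logmsg(nLoci(g), " loci -> structure set ", nLoci(g_struct),
          ", outlier set ", nLoci(g_out))
  pr <- params$prune
  g_pruned <- ldPrune(g_struct, pr$window_snps, pr$step_snps, pr$r2_max)
  .logmsg("LD pruning: ", nLoci(g_struct), " -> ", nLoci(g_pruned), " loci")

  g_pruned_i <- imputeModal(g_pruned)
  g_out_i <- imputeModal(g_out)

  # --- structure ----------------------------------------------------------
  pca <- genotypePCA(g_pruned_i)
  files["pca"] <- tsv(data.frame(sample = rownames(pca$scores),
                                 pca$scores[, 1:min(10, ncol(pca$scores))]),
                      "pca_scores.tsv")
  cl <- inferClusters(pca, k_max = min(params$cluster$k_max,
                                       nSamples(g) - 1),
                      n_axes = params$cluster$n_axes, seed = seed)
  .logmsg("inferred k = ", cl$k, " clusters")
  files["clusters"] <- tsv(data.frame(sample = sampleIds(g),
                                      cluster = cl$labels), "clusters.tsv")
  fst <- if (cl$k >= 2 && min(table(cl$labels)) >= 2)
    pairwiseFst(g_pruned_i, cl$labels) else NULL
  if (!is.null(fst))
    files["fst"] <- tsv(data.frame(group = rownames(fst), fst),
                        "fst_matrix.tsv")
  am <- if (cl$k >= 2) amova(g_pruned_i, cl$labels,
                             n_perm = params$amova$n_perm, seed = seed)
        else NULL
  if (!is.null(am))
    files["amova"] <- tsv(data.frame(sigma_among = am$sigma_among,
                                     sigma_within = am$sigma_within,
                                     pct_among = am$pct_among,
                                     pct_within = am$pct_within,
                                     phi_st = am$phi_st, p_perm = am$p_perm),
                          "amova.tsv")

  # --- climate ------------------------------------------------------------
  envz <- standardizeEnv(env)
  fsel <- forwardSelect(g_pruned_i, envz, alpha = params$forward$alpha,
                        n_perm = params$forward$n_perm, seed = seed)
  .logmsg("forward selection: ", length(fsel$selected), " variables [",
          paste(fsel$selected, collapse = ", "), "]")
  files["selection"] <- tsv(fsel$trace, "selection_trace.tsv")
  clim_vars <- fsel$selected
  if (length(clim_vars) < 4) {
    # too few selected for a K-axis outlier scan: top up with the variables
    # of highest marginal genotype R2 (deterministic)
    Yc <- scale(dosage(g_pruned_i), scale = FALSE)
    tot <- sum(Yc^2)
    r2m <- vapply(colnames(envVars(envz)), function(v) {
      u <- envVars(envz)[, v]
      sum(crossprod(Yc, u)^2) / sum(u^2) / tot
    }, numeric(1))
    extra <- setdiff(names(sort(r2m, decreasing = TRUE)), clim_vars)
    clim_vars <- c(clim_vars, utils::head(extra, 6 - length(clim_vars)))
    .logmsg("climate block topped up to [", paste(clim_vars, collapse = ", "), "]")
  }
  climate <- envVars(envz)[, clim_vars, drop = FALSE]
  geography <- as.matrix(envCoords(env)[, c("lat", "lon")])
  struct_pcs <- pca$scores[, seq_len(params$structure_pcs), drop = FALSE]

  # --- partial RDA --------------------------------------------------------
  vp <- variancePartition(g_pruned_i, climate, geography, struct_pcs)
  files["varpart"] <- tsv(
    data.frame(component = c("full_model", "pure_structure", "pure_geography",
                             "pure_climate", "confounded", "unexplained"),
               fraction = unlist(vp[c("full_model", "pure_structure",
                                      "pure_geography", "pure_climate",
                                      "confounded", "unexplained")])),
    "variance_partition.tsv")
  prda <- fitRDA(g_pruned_i, climate, Z = struct_pcs)
  files["rda"] <- tsv(data.frame(r2 = prda$r2, adj_r2 = prda$adj_r2,
                                 t(prda$eig[seq_len(min(6, length(prda$eig)))])),
                      "rda_summary.tsv")
  prda_scan <- fitRDA(g_pruned_i, climate, Z = struct_pcs,
                      scale_loci = params$rdadapt$scale_loci)
  K <- min(params$rdadapt$K, length(prda_scan$eig))
  set.seed(seed + 17L)
  rout <- rdaOutlierScan(prda_scan, K = K, df_mode = params$rdadapt$df_mode,
                         bonferroni_alpha = params$rdadapt$bonferroni_alpha,
                         robust = params$rdadapt$robust)
  lt_pr <- lociTable(g_pruned_i)
  rout2 <- cbind(rout, lt_pr[match(rout$snp, lt_pr$locus), c("chrom", "pos")])
  files["rda_outliers"] <- tsv(rout2, "rda_outliers.tsv")
  rda_sig <- rout2[rout2$bonferroni_flag, c("snp", "chrom", "pos")]
  .logmsg("RDA outliers (Bonferroni ", params$rdadapt$bonferroni_alpha, "): ",
          nrow(rda_sig))

  # --- LFMM ---------------------------------------------------------------
  lf <- lfmmScan(g_out_i, env, K = params$lfmm$K, n_runs = params$lfmm$n_runs,
                 fdr = params$lfmm$fdr, mode = params$lfmm$mode, seed = seed)
  files["lfmm"] <- tsv(lf$results, "lfmm_results.tsv")
  lt_out <- lociTable(g_out_i)
  lf_sig <- unique(merge(lf$consensus,
                         lt_out[, c("locus", "chrom", "pos")],
                         by.x = "snp", by.y = "locus"))
  .logmsg("LFMM consensus hits: ", nrow(lf_sig))

  # --- EnvGWAS ------------------------------------------------------------
  pc_grid <- params$envgwas$pc_grid
  eg <- envAssocScan(g_out_i, env, pca$scores, pc_grid = pc_grid,
                     alpha = params$envgwas$alpha, fdr = params$envgwas$fdr)
  files["envgwas"] <- tsv(eg$results, "envgwas_results.tsv")
  eg_sig0 <- eg$results[eg$results$bonferroni_flag & eg$results$fdr_flag, ]
  eg_sig <- merge(eg_sig0[, c("snp", "variable")],
                  lt_out[, c("locus", "chrom", "pos")],
                  by.x = "snp", by.y = "locus")
  .logmsg("EnvGWAS hits (Bonferroni & FDR): ", nrow(eg_sig))

  # --- diversity windows + LD decay --------------------------------------
  win <- makeWindows(chrom_lengths, params$windows$size, params$windows$step)
  ws <- windowStats(g_out, win)
  ld <- ldDecay(g_out_i, max_dist = params$ld$max_dist, bin = params$ld$bin)
  files["ld_decay"] <- tsv(ld$bins, "ld_decay.tsv")
  files["decay_distances"] <- tsv(ld$decay, "decay_distances.tsv")

  # --- candidates + consensus --------------------------------------------
  cons <- consensusPleiotropy(list(
    rda = if (nrow(rda_sig)) rda_sig else NULL,
    lfmm = if (nrow(lf_sig)) lf_sig else NULL,
    envgwas = if (nrow(eg_sig)) eg_sig else NULL))
  files["consensus"] <- tsv(if (nrow(cons$snps)) cons$snps else
                              data.frame(snp = character()), "consensus.tsv")
  dd <- stats::setNames(ld$decay$decay_distance, ld$decay$chrom)
  dd[is.na(dd)] <- params$ld$max_dist / 2
  civ <- if (nrow(cons$snps))
    candidateIntervals(cons$snps, dd, chrom_lengths) else NULL
  if (!is.null(civ))
    files["intervals"] <- tsv(civ, "candidate_intervals.tsv")
  cw <- compareCandidateWindows(ws, civ)
  ws$candidate_flag <- cw$candidate_flag
  files["windows"] <- tsv(ws, "window_stats.tsv")
  files["window_comparison"] <- tsv(cw$summary, "window_comparison.tsv")
  gh <- if (!is.null(civ) && !is.null(genes) && nrow(civ)) mapGenes(civ, genes)
        else NULL
  if (!is.null(gh)) files["gene_hits"] <- tsv(gh, "gene_hits.tsv")
  .logmsg("consensus loci: ", nrow(cons$snps), " (",
          sum(cons$snps$pleiotropic %||% FALSE), " pleiotropic)")

  manifest <- data.frame(file = names(files), path = unname(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(outdir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(manifest = manifest,
                 tables = list(qc = qc, pca = pca, clusters = cl, fst = fst,
                               amova = am, selection = fsel, varpart = vp,
                               rda = prda, rda_outliers = rout2, lfmm = lf,
                               envgwas = eg, windows = ws, ld = ld,
                               consensus = cons, intervals = civ,
                               gene_hits = gh, truth = truth),
                 params = params, seed = seed))
}
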