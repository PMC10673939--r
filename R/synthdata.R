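#' Configuration for the synthetic landscape generator
#'
#' Bundles every knob of the landscape simulator: a set of geo-referenced
#' sampling sites carrying spatially structured, partially collinear monthly
#' climate variables; diploid individuals drawn from hierarchically structured
#' genetic groups (Balding-Nichols model parameterised by Fst); and a known
#' subset of adaptive loci whose site-level allele frequencies follow logistic
#' clines along one climate variable.
#'
#' Defaults emulate a diversity panel of landraces sampled across a plateau
#' landscape: 200 individuals from 20 sites in 4 genetic groups, 5,000
#' biallelic SNPs on 7 chromosomes, group differentiation Fst = 0.2, 2%
#' adaptive loci with cline slope 1.5 on the standardized driver variable,
#' 6 climate variables with pairwise collinearity 0.8, and 5% missing calls.
#'
#' @param n_sites number of sampling sites (>= 2).
#' @param n_individuals number of diploid individuals.
#' @param n_groups number of genetic groups.
#' @param n_loci number of biallelic SNPs.
#' @param n_adaptive number of adaptive (cline-following) loci.
#' @param fst_groups Balding-Nichols differentiation parameter, in (0, 1).
#' @param f_is within-population inbreeding coefficient in [0, 1):
#'   with probability `f_is` an individual's two alleles at a locus are
#'   identical by descent (one Bernoulli(p) draw doubled), otherwise
#'   Hardy-Weinberg Binomial(2, p). The default 0.9 emulates a predominantly
#'   selfing crop, whose low heterozygosity is what makes a het-rate filter
#'   at 0.2 retain most loci; `f_is = 0` gives random mating.
#' @param cline_effect logistic cline slope beta on the standardized driver
#'   variable (dimensionless).
#' @param n_env_vars number of climate variables (default 30: five monthly
#'   series - tmax, prec, srad, tavg, tmin - over the April-September growing
#'   season; nonredundant subsets are meant to emerge from forward selection,
#'   not from the generator).
#' @param env_collinearity target absolute pairwise correlation achieved by at
#'   least two variable pairs, in [0, 1).
#' @param env_noise_sd standard deviation of the site-level noise added to each
#'   climate gradient (0 gives exact functions of the coordinates).
#' @param group_assignment `"latitude"` (default) blocks sites into groups by
#'   latitude, confounding genetic structure with geography and climate the
#'   way a real landscape does; `"random"` assigns sites to groups at random,
#'   giving structure orthogonal (in expectation) to the environment.
#' @param driver_var optional climate-variable name: when set, every adaptive
#'   locus clines on this single variable; by default each adaptive locus
#'   draws its driver at random.
#' @param missing_rate fraction of genotype calls set missing, in [0, 0.5].
#' @param seed integer seed; every simulation function resets the RNG from it.
#' @param chrom_lengths lengths in bp of the 7 chromosomes.
#' @return A list of class `LandscapeConfig`.
#' @export
landscapeConfig <- function(n_sites = 20, n_individuals = 200, n_groups = 4,
                            n_loci = 5000, n_adaptive = 100,
                            fst_groups = 0.2, f_is = 0.9, cline_effect = 1.5,
                            n_env_vars = 30, env_collinearity = 0.8,
                            env_noise_sd = 0.3, driver_var = NULL,
                            group_assignment = c("latitude", "random"),
                            missing_rate = 0.05, seed = 1L,
                            chrom_lengths = rep(500000L, 7)) {
  cfg <- list(n_sites = as.integer(n_sites),
              n_individuals = as.integer(n_individuals),
              n_groups = as.integer(n_groups), n_loci = as.integer(n_loci),
              n_adaptive = as.integer(n_adaptive),
              fst_groups = fst_groups, f_is = f_is,
              cline_effect = cline_effect,
              n_env_vars = as.integer(n_env_vars),
              env_collinearity = env_collinearity,
              env_noise_sd = env_noise_sd, driver_var = driver_var,
              group_assignment = match.arg(group_assignment),
              missing_rate = missing_rate, seed = as.integer(seed),
              chrom_lengths = as.integer(chrom_lengths))
  if (cfg$n_adaptive > cfg$n_loci) stop("n_adaptive must be <= n_loci")
  if (cfg$fst_groups <= 0 || cfg$fst_groups >= 1)
    stop("fst_groups must lie in (0, 1)")
  if (cfg$f_is < 0 || cfg$f_is >= 1) stop("f_is must lie in [0, 1)")
  if (cfg$env_collinearity < 0 || cfg$env_collinearity >= 1)
    stop("env_collinearity must lie in [0, 1)")
  if (cfg$missing_rate < 0 || cfg$missing_rate > 0.5)
    stop("missing_rate must lie in [0, 0.5]")
  if (any(cfg$chrom_lengths <= 0)) stop("chrom_lengths must be positive")
  if (length(cfg$chrom_lengths) != 7) stop("expected 7 chromosome lengths")
  class(cfg) <- "LandscapeConfig"
  cfg
}

# pool of monthly climate variable names (growing season, months 4-9)
.envVarNames <- function(n) {
  pool <- as.vector(outer(c("tmax", "prec", "srad", "tavg", "tmin"),
                          4:9, paste0))
  if (n > length(pool)) pool <- c(pool, paste0("env", seq_len(n - length(pool))))
  pool[seq_len(n)]
}

#' Simulate geo-referenced sites and climate variables
#'
#' Places `n_sites` sites on a latitude/longitude grid, assigns individuals to
#' sites round-robin, and generates climate variables as linear or
#' Gaussian-bump functions of the coordinates plus independent site-level
#' noise. Altitude is a linear function of the coordinates. Two variable pairs
#' are post-adjusted so their realized correlation is exactly
#' `env_collinearity` (to exercise forward selection against collinear
#' predictors).
#'
#' @param config a [landscapeConfig()].
#' @return An [EnvData-class] with one row per individual (site-level values
#'   replicated within site) and raw (unstandardized) variables.
#' @export
simulateSitesEnv <- function(config) {
  stopifnot(inherits(config, "LandscapeConfig"))
  if (config$n_sites < 2) stop("n_sites must be >= 2: no spatial gradient definable")
  set.seed(config$seed)
  ns <- config$n_sites
  # grid over a plateau-like window, jittered so no two sites coincide
  side <- ceiling(sqrt(ns))
  gx <- (seq_len(ns) - 1) %% side
  gy <- (seq_len(ns) - 1) %/% side
  lat <- 29 + 10 * (gy + stats::runif(ns, 0.1, 0.9)) / side
  lon <- 90 + 13 * (gx + stats::runif(ns, 0.1, 0.9)) / side
  latz <- as.numeric(scale(lat))
  lonz <- as.numeric(scale(lon))
  alt <- 3500 + 250 * latz - 180 * lonz + stats::rnorm(ns, 0, 30)

  nv <- config$n_env_vars
  nms <- .envVarNames(nv)
  vars <- matrix(NA_real_, ns, nv, dimnames = list(NULL, nms))
  half <- ceiling(nv / 2)
  for (j in seq_len(nv)) {
    base <- if (j <= half) latz else lonz
    if (j %% 3 == 0) {
      # Gaussian bump centred inside the sampling window
      cx <- mean(lat) + diff(range(lat)) * 0.15
      cy <- mean(lon) - diff(range(lon)) * 0.1
      w <- diff(range(lat)) / 2
      base <- as.numeric(scale(exp(-((lat - cx)^2 + (lon - cy)^2) / (2 * w^2))))
    }
    vars[, j] <- base + config$env_noise_sd * stats::rnorm(ns)
  }
  # force two pairs to the exact target correlation (empirical orthogonalization)
  rho <- config$env_collinearity
  mkpair <- function(a, b) {
    x <- as.numeric(scale(vars[, a]))
    e <- stats::residuals(stats::lm(vars[, b] ~ x))
    if (stats::sd(e) < 1e-12) e <- stats::rnorm(ns)
    e <- as.numeric(scale(e))
    vars[, b] <<- rho * x + sqrt(1 - rho^2) * e
  }
  if (nv >= 2 && rho > 0) mkpair(1, 2)
  if (nv >= 4 && rho > 0) mkpair(3, 4)

  # round-robin assignment of individuals to sites
  site <- rep(seq_len(ns), length.out = config$n_individuals)
  samples <- sprintf("ind%03d", seq_len(config$n_individuals))
  envData(samples,
          data.frame(lat = lat[site], lon = lon[site], alt = alt[site]),
          vars[site, , drop = FALSE], site = site)
}

#' Simulate structured genotypes with planted adaptive clines
#'
#' Neutral loci follow the Balding-Nichols model: an ancestral frequency
#' p0 ~ Uniform(0.1, 0.9) and per-group frequencies drawn from
#' Beta(p0(1-F)/F, (1-p0)(1-F)/F) with F = `fst_groups`; genotypes are
#' Binomial(2, group frequency). Adaptive loci ignore group structure and take
#' site-level frequencies logistic(logit(p0) + beta * z), where z is the
#' standardized driver variable at the individual's site and beta =
#' `cline_effect` with random sign. Missing calls are set uniformly at random.
#' Loci sit at sorted uniform positions across the 7 chromosomes.
#'
#' Genetic groups are blocks of sites contiguous in latitude, which confounds
#' structure with geography the way a real landscape does.
#'
#' @param config a [landscapeConfig()].
#' @param env the [EnvData-class] from [simulateSitesEnv()].
#' @return A list with elements `genotypes` ([GenotypeData-class]), `truth`
#'   (data.frame: locus, chrom, pos, is_adaptive, driver, beta, p0) and
#'   `groups` (integer group label per sample).
#' @export
simulateGenotypes <- function(config, env) {
  stopifnot(inherits(config, "LandscapeConfig"), is(env, "EnvData"))
  if (config$fst_groups <= 0 || config$fst_groups >= 1)
    stop("fst_groups must lie in (0, 1)")
  set.seed(config$seed + 1L)
  n <- length(sampleIds(env))
  site <- envSites(env)
  ns <- max(site)
  # contiguous-latitude site blocks -> groups
  site_lat <- vapply(seq_len(ns), function(s) envCoords(env)$lat[match(s, site)],
                     numeric(1))
  grp_of_site <- if (identical(config$group_assignment, "random"))
    sample(rep_len(seq_len(config$n_groups), ns))
  else
    as.integer(cut(rank(site_lat, ties.method = "first"),
                   breaks = config$n_groups, labels = FALSE))
  groups <- grp_of_site[site]

  L <- config$n_loci
  Fst <- config$fst_groups
  p0 <- stats::runif(L, 0.1, 0.9)
  adaptive <- rep(FALSE, L)
  if (config$n_adaptive > 0)
    adaptive[sample.int(L, config$n_adaptive)] <- TRUE

  vars <- envVars(env)
  drivers <- rep(NA_character_, L)
  beta <- rep(0, L)
  if (any(adaptive)) {
    drivers[adaptive] <- if (!is.null(config$driver_var)) {
      stopifnot(config$driver_var %in% colnames(vars))
      config$driver_var
    } else sample(colnames(vars), sum(adaptive), replace = TRUE)
    beta[adaptive] <- config$cline_effect * sample(c(-1, 1), sum(adaptive),
                                                   replace = TRUE)
  }

  geno <- matrix(NA_integer_, n, L)
  shape_scale <- (1 - Fst) / Fst
  zvars <- scale(vars)
  fis <- config$f_is
  draw_geno <- function(pf) {
    # selfing-aware genotype draw: identical alleles with probability f_is
    ibd <- stats::runif(n) < fis
    out <- integer(n)
    out[ibd] <- 2L * stats::rbinom(sum(ibd), 1L, pf[ibd])
    out[!ibd] <- stats::rbinom(sum(!ibd), 2L, pf[!ibd])
    out
  }
  for (l in seq_len(L)) {
    if (adaptive[l]) {
      z <- zvars[, drivers[l]]
      pf <- stats::plogis(stats::qlogis(p0[l]) + beta[l] * z)
      geno[, l] <- draw_geno(pf)
    } else {
      pg <- stats::rbeta(config$n_groups, p0[l] * shape_scale,
                         (1 - p0[l]) * shape_scale)
      # Beta draws can hit 0/1 numerically at extreme F; keep frequencies proper
      pg <- pmin(pmax(pg, 1e-9), 1 - 1e-9)
      geno[, l] <- draw_geno(pg[groups])
    }
  }
  if (config$missing_rate > 0) {
    miss <- stats::runif(n * L) < config$missing_rate
    geno[miss] <- NA_integer_
  }

  # sorted uniform positions across 7 chromosomes, loci spread by length
  chrom_names <- paste0(seq_len(7), "H")
  nchr <- stats::rmultinom(1, L, config$chrom_lengths / sum(config$chrom_lengths))[, 1]
  chrom <- rep(chrom_names, nchr)
  pos <- unlist(lapply(seq_len(7), function(k) {
    sort(sample.int(config$chrom_lengths[k], nchr[k]))
  }))
  rownames(geno) <- sampleIds(env)
  g <- genotypeData(geno, chrom, pos)
  # genotypeData sorts loci; recover the permutation to align the truth table
  ids <- paste(chrom, pos, sep = "_")
  perm <- match(S4Vectors::mcols(loci(g))$id, ids)
  truth <- data.frame(locus = ids[perm], chrom = chrom[perm], pos = pos[perm],
                      is_adaptive = adaptive[perm], driver = drivers[perm],
                      beta = beta[perm], p0 = p0[perm],
                      stringsAsFactors = FALSE)
  list(genotypes = g, truth = truth, groups = groups)
}

#' Simulate a complete landscape dataset
#'
#' Convenience wrapper running [simulateSitesEnv()] then [simulateGenotypes()].
#' @param config a [landscapeConfig()].
#' @return list with `genotypes`, `env`, `truth`, `groups`.
#' @export
simulateLandscape <- function(config) {
  env <- simulateSitesEnv(config)
  sim <- simulateGenotypes(config, env)
  list(genotypes = sim$genotypes, env = env, truth = sim$truth,
       groups = sim$groups)
}

#' Write a simulated dataset to disk
#'
#' Emits a GT-only VCF 4.2, the environment TSV, the truth TSV, and a GFF3 of
#' synthetic genes: one gene within 50 kb of every adaptive locus plus
#' regularly spaced background genes. A manifest of files and the seed is
#' returned and written alongside.
#'
#' @param g a [GenotypeData-class].
#' @param env an [EnvData-class].
#' @param truth truth data.frame from [simulateGenotypes()].
#' @param outdir output directory (created if needed).
#' @param config optional [landscapeConfig()]; supplies chromosome lengths and
#'   the seed recorded in the manifest.
#' @return data.frame manifest (file, path, md5), invisibly also written to
#'   `manifest.tsv`.
#' @export
emitDataset <- function(g, env, truth, outdir, config = NULL) {
  stopifnot(identical(sampleIds(g), sampleIds(env)))
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  }
  vcf <- file.path(outdir, "genotypes.vcf")
  writeGenotypesVCF(g, vcf)
  envp <- file.path(outdir, "env.tsv")
  writeEnvTable(env, envp)
  truthp <- file.path(outdir, "truth.tsv")
  utils::write.table(truth, truthp, sep = "\t", quote = FALSE, row.names = FALSE)

  gffp <- file.path(outdir, "genes.gff3")
  chrom_lengths <- if (is.null(config)) {
    tapply(GenomicRanges::start(loci(g)),
           as.character(GenomicRanges::seqnames(loci(g))), max)
  } else stats::setNames(config$chrom_lengths, paste0(seq_len(7), "H"))
  genes <- .syntheticGenes(truth, chrom_lengths,
                           seed = if (is.null(config)) 1L else config$seed)
  rtracklayer::export(genes, gffp, format = "gff3")

  files <- c(vcf = vcf, env = envp, truth = truthp, gff = gffp)
  manifest <- data.frame(file = names(files), path = unname(files),
                         md5 = unname(tools::md5sum(files)),
                         seed = if (is.null(config)) NA_integer_ else config$seed,
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(outdir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

# one gene (1-3 kb) within 50 kb of each adaptive locus + background genes
# every ~60 kb; deterministic given the seed
.syntheticGenes <- function(truth, chrom_lengths, seed = 1L) {
  set.seed(seed + 2L)
  rows <- list()
  k <- 0L
  ad <- truth[truth$is_adaptive, , drop = FALSE]
  for (i in seq_len(nrow(ad))) {
    len <- sample(1000:3000, 1)
    offset <- sample(-45000:45000, 1)
    clen <- chrom_lengths[[ad$chrom[i]]]
    start <- min(max(1, ad$pos[i] + offset - len %/% 2), max(1, clen - len + 1))
    end <- min(clen, start + len - 1)
    k <- k + 1L
    rows[[k]] <- data.frame(chrom = ad$chrom[i], start = start, end = end,
                            strand = sample(c("+", "-"), 1),
                            id = sprintf("GENE_A%04d", i))
  }
  for (chr in names(chrom_lengths)) {
    starts <- seq(20000, chrom_lengths[[chr]] - 5000, by = 60000)
    for (s in starts) {
      k <- k + 1L
      rows[[k]] <- data.frame(chrom = chr, start = s,
                              end = s + sample(1000:4000, 1),
                              strand = sample(c("+", "-"), 1),
                              id = sprintf("GENE_B%s_%07d", chr, s))
    }
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- df$id
  S4Vectors::mcols(gr)$source <- "landgea"
  gr
}
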