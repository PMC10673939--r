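#' Read a VCF into a GenotypeData object
#'
#' Reads diploid GT calls from a VCF (4.x) via \pkg{vcfR} and converts them to
#' alternate-allele dosages: `0/0` -> 0, `0/1`/`1/0` -> 1, `1/1` -> 2,
#' `./.` -> missing. Phased separators (`|`) are accepted. Multiallelic or
#' non-SNP records are skipped (with a count) or rejected, per `multiallelic`.
#' Loci are returned sorted by (chromosome, position) regardless of input
#' order.
#'
#' @param path VCF file path (plain or bgzipped).
#' @param multiallelic `"skip"` (default) drops multiallelic / non-SNP records
#'   with a message; `"error"` aborts on the first one.
#' @return A [GenotypeData-class].
#' @export
readGenotypes <- function(path, multiallelic = c("skip", "error")) {
  multiallelic <- match.arg(multiallelic)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  bad <- grepl(",", alt) | nchar(ref) != 1 | nchar(alt) != 1 |
    !ref %in% c("A", "C", "G", "T") | !alt %in% c("A", "C", "G", "T")
  if (any(bad)) {
    if (multiallelic == "error")
      stop(sum(bad), " multiallelic/non-SNP records present")
    message("skipping ", sum(bad), " multiallelic/non-SNP records")
  }
  keep <- which(!bad)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  gt2 <- gsub("|", "/", gt, fixed = TRUE)
  dos <- matrix(NA_integer_, nrow(gt2), ncol(gt2))
  dos[gt2 == "0/0"] <- 0L
  dos[gt2 == "0/1" | gt2 == "1/0"] <- 1L
  dos[gt2 == "1/1"] <- 2L
  unknown <- !is.na(gt2) & is.na(dos) & gt2 != "./."
  if (any(unknown))
    stop("unparseable GT entries, e.g. ", gt2[which(unknown)[1]])
  dmat <- t(dos)
  rownames(dmat) <- colnames(gt2)
  genotypeData(dmat,
               chrom = fix[keep, "CHROM"],
               pos = as.integer(fix[keep, "POS"]),
               id = ifelse(is.na(fix[keep, "ID"]) | fix[keep, "ID"] == ".",
                           paste(fix[keep, "CHROM"], fix[keep, "POS"], sep = "_"),
                           fix[keep, "ID"]),
               ref = ref[keep], alt = alt[keep])
}

#' Write a GenotypeData object as a GT-only VCF 4.2
#'
#' @param g a [GenotypeData-class].
#' @param path output path (plain text).
#' @return the path, invisibly.
#' @export
writeGenotypesVCF <- function(g, path) {
  lt <- lociTable(g)
  d <- dosage(g)
  gt <- matrix("./.", ncol(d), nrow(d))
  gt[t(d) == 0L] <- "0/0"
  gt[t(d) == 1L] <- "0/1"
  gt[t(d) == 2L] <- "1/1"
  header <- c("##fileformat=VCFv4.2",
              "##source=landgea",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(d)), collapse = "\t"))
  body <- paste(lt$chrom, lt$pos, lt$locus, lt$ref, lt$alt, ".", "PASS", ".",
                "GT", apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Per-locus QC statistics
#'
#' Computes, over non-missing calls only: minor allele frequency
#' `maf = min(p, 1 - p)` with `p = sum(dosage) / (2 * n_nonmissing)`;
#' heterozygosity rate `n_het / n_nonmissing`; and the missing-call rate
#' `n_missing / n_samples`. Loci with zero non-missing calls get `NA`
#' statistics.
#'
#' @param g a [GenotypeData-class].
#' @return data.frame: locus, chrom, pos, maf, het_rate, missing_rate, n_called.
#' @export
locusQC <- function(g) {
  d <- dosage(g)
  ncall <- colSums(!is.na(d))
  p <- colSums(d, na.rm = TRUE) / (2 * ncall)
  p[ncall == 0] <- NA_real_
  het <- colSums(d == 1L, na.rm = TRUE) / ncall
  het[ncall == 0] <- NA_real_
  cbind(lociTable(g)[, c("locus", "chrom", "pos")],
        data.frame(maf = pmin(p, 1 - p), het_rate = het,
                   missing_rate = 1 - ncall / nrow(d), n_called = ncall))
}

#' Filter loci by QC thresholds
#'
#' Two named filter sets mirror the usual dual filtering of a GBS panel:
#' * `"structure"` (keeps) - `missing_rate <= miss_max`, `het_rate <= het_max`,
#'   `maf >= maf_min`, defaults 0.2 / 0.2 / 0.1. Used for population structure
#'   and partial RDA.
#' * `"outlier"` (removals phrased as strict keeps) - `maf > maf_min` (default
#'   0.05), `het_rate < het_max` (0.2), `missing_rate < miss_max` (0.2). Used
#'   for the association scans.
#'
#' @param g a [GenotypeData-class].
#' @param set `"structure"` or `"outlier"`.
#' @param maf_min,het_max,miss_max optional threshold overrides.
#' @return a [GenotypeData-class] with surviving loci in genomic order;
#'   genotype values untouched. An empty result triggers a warning, not an
#'   error.
#' @export
filterLoci <- function(g, set = c("structure", "outlier"),
                       maf_min = NULL, het_max = NULL, miss_max = NULL) {
  set <- match.arg(set)
  qc <- locusQC(g)
  if (set == "structure") {
    if (is.null(maf_min)) maf_min <- 0.1
    if (is.null(het_max)) het_max <- 0.2
    if (is.null(miss_max)) miss_max <- 0.2
    keep <- !is.na(qc$maf) & qc$missing_rate <= miss_max &
      qc$het_rate <= het_max & qc$maf >= maf_min
  } else {
    if (is.null(maf_min)) maf_min <- 0.05
    if (is.null(het_max)) het_max <- 0.2
    if (is.null(miss_max)) miss_max <- 0.2
    keep <- !is.na(qc$maf) & qc$maf > maf_min & qc$het_rate < het_max &
      qc$missing_rate < miss_max
  }
  if (!any(keep)) warning("no loci survive the '", set, "' filter")
  g[, which(keep)]
}

#' Modal imputation of missing genotype calls
#'
#' Replaces each missing call with the locus's most frequent observed dosage.
#' Ties between modes are broken toward the dosage nearest the locus mean
#' `2 * p`; a residual tie (equidistant) goes to the lower dosage.
#'
#' @param g a [GenotypeData-class]; every locus needs >= 1 non-missing call.
#' @return a [GenotypeData-class] with no missing values.
#' @export
imputeModal <- function(g) {
  d <- dosage(g)
  if (!anyNA(d)) return(g)
  ncall <- colSums(!is.na(d))
  if (any(ncall == 0))
    stop("all-missing locus: ", colnames(d)[which(ncall == 0)[1]])
  need <- which(colSums(is.na(d)) > 0)
  for (j in need) {
    x <- d[, j]
    cnt <- tabulate(x + 1L, nbins = 3L)  # counts of dosage 0,1,2
    modes <- which(cnt == max(cnt)) - 1L
    if (length(modes) > 1) {
      target <- 2 * sum(x, na.rm = TRUE) / (2 * sum(!is.na(x)))
      dist <- abs(modes - target)
      modes <- modes[dist == min(dist)]
      fill <- min(modes)
    } else fill <- modes
    d[is.na(x), j] <- as.integer(fill)
  }
  new("GenotypeData", dosage = d, loci = loci(g))
}

#' Squared Pearson correlation of two dosage vectors
#'
#' Computed over pairwise-complete samples. Undefined (returns `NA` with a
#' warning suppressed into an attribute) when fewer than 2 complete pairs
#' remain or either locus is monomorphic on the complete pairs.
#'
#' @param x,y dosage vectors of equal length.
#' @return r-squared in [0, 1], or `NA_real_` when undefined.
#' @export
pairwiseR2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 || vy == 0) return(NA_real_)
  r <- stats::cov(x, y) / sqrt(vx * vy)
  r * r
}

#' PLINK-style LD pruning (indep-pairwise semantics)
#'
#' Per chromosome, slides a window of `window_snps` loci advancing by
#' `step_snps`; within each window every remaining pair with r-squared above
#' `r2_max` loses its lower-MAF member (MAF tie: the later position is
#' removed). Whole-chromosome passes repeat until no window contains a
#' violating pair. Windows are indexed on the original locus order, pairs are
#' visited in index order, and r-squared uses pairwise-complete observations,
#' so the procedure is deterministic.
#'
#' @param g a [GenotypeData-class] (loci sorted; enforced by the class).
#' @param window_snps window size in SNPs (default 150).
#' @param step_snps step in SNPs (default 5).
#' @param r2_max r-squared threshold (default 0.5).
#' @return a [GenotypeData-class] of surviving loci in genomic order.
#' @export
ldPrune <- function(g, window_snps = 150, step_snps = 5, r2_max = 0.5) {
  if (window_snps < 2) stop("window_snps must be >= 2")
  d <- dosage(g)
  chrom <- as.character(GenomicRanges::seqnames(loci(g)))
  pos <- GenomicRanges::start(loci(g))
  qc <- locusQC(g)
  keep <- rep(TRUE, ncol(d))
  for (chr in unique(chrom)) {
    idx <- which(chrom == chr)
    repeat {
      removed <- FALSE
      starts <- seq(1, length(idx), by = step_snps)
      for (s in starts) {
        win <- idx[s:min(s + window_snps - 1, length(idx))]
        win <- win[keep[win]]
        if (length(win) < 2) next
        r2 <- suppressWarnings(
          stats::cor(d[, win, drop = FALSE],
                     use = "pairwise.complete.obs"))^2
        alive <- rep(TRUE, length(win))
        for (a in seq_len(length(win) - 1)) {
          if (!alive[a]) next
          for (b in seq((a + 1), length(win))) {
            if (!alive[b]) next
            if (!is.na(r2[a, b]) && r2[a, b] > r2_max) {
              ma <- qc$maf[win[a]]; mb <- qc$maf[win[b]]
              victim <- if (ma < mb) a
                        else if (mb < ma) b
                        else if (pos[win[a]] > pos[win[b]]) a else b
              alive[victim] <- FALSE
              removed <- TRUE
              if (victim == a) break
            }
          }
        }
        keep[win[!alive]] <- FALSE
      }
      if (!removed) break
    }
  }
  g[, which(keep)]
}

#' QC report for both filter sets
#'
#' @param g a [GenotypeData-class].
#' @return data.frame with the per-locus QC statistics plus logical columns
#'   `kept_structure` and `kept_outlier`.
#' @export
qcReport <- function(g) {
  qc <- locusQC(g)
  qc$kept_structure <- !is.na(qc$maf) & qc$missing_rate <= 0.2 &
    qc$het_rate <= 0.2 & qc$maf >= 0.1
  qc$kept_outlier <- !is.na(qc$maf) & qc$maf > 0.05 & qc$het_rate < 0.2 &
    qc$missing_rate < 0.2
  qc
}
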