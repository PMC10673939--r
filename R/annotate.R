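#' Candidate intervals around significant SNPs
#'
#' Flanks each significant SNP by its chromosome's LD decay distance:
#' interval = [pos - d, pos + d], clipped at 1 and at the chromosome end, so
#' the nominal width is `2 d + 1` bp.
#'
#' @param significant_snps data.frame with columns snp, chrom, pos (and
#'   optionally methods, variables, carried through).
#' @param decay_distances named numeric vector, decay distance (bp) per
#'   chromosome; a chromosome missing from it is an error.
#' @param chrom_lengths optional named vector for right-clipping.
#' @return data.frame: snp, chrom, pos, start, end, width plus carried
#'   columns.
#' @export
candidateIntervals <- function(significant_snps, decay_distances,
                               chrom_lengths = NULL) {
  s <- significant_snps
  missing_chr <- setdiff(unique(s$chrom), names(decay_distances))
  if (length(missing_chr))
    stop("no decay distance for chromosome(s): ",
         paste(missing_chr, collapse = ", "))
  d <- round(decay_distances[s$chrom])
  start <- pmax(1, s$pos - d)
  end <- s$pos + d
  if (!is.null(chrom_lengths))
    end <- pmin(end, chrom_lengths[s$chrom])
  out <- data.frame(snp = s$snp, chrom = s$chrom, pos = s$pos,
                    start = as.integer(start), end = as.integer(end),
                    width = as.integer(end - start + 1),
                    stringsAsFactors = FALSE)
  extra <- setdiff(colnames(s), colnames(out))
  if (length(extra)) out <- cbind(out, s[, extra, drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Read gene features from GFF3 or BED
#'
#' @param path GFF3 (`gene` features kept) or BED file.
#' @return `GRanges` with an `ID` metadata column.
#' @export
readGenes <- function(path) {
  gr <- rtracklayer::import(path)
  mc <- S4Vectors::mcols(gr)
  if ("type" %in% colnames(mc)) gr <- gr[as.character(mc$type) == "gene"]
  mc <- S4Vectors::mcols(gr)
  id <- if ("ID" %in% colnames(mc)) mc$ID else
    if ("name" %in% colnames(mc)) mc$name else
      paste0("gene", seq_along(gr))
  S4Vectors::mcols(gr)$ID <- as.character(id)
  gr
}

# relation of a SNP to a gene, resolved on the gene's strand
.snpGeneRelation <- function(pos, gstart, gend, strand) {
  if (pos >= gstart && pos <= gend) return("within")
  before <- pos < gstart   # SNP 5' of gene start in reference orientation
  if (strand == "-") before <- !before
  if (before) "upstream-of-gene" else "downstream-of-gene"
}

#' Map candidate intervals to genes
#'
#' Lists every gene overlapping each interval (distance = bp between SNP and
#' gene, 0 when the SNP lies inside the gene) and, additionally, the nearest
#' gene outside the interval with its distance. The upstream/downstream
#' relation is resolved on the gene's strand: a SNP 5' of the gene start on
#' that strand is `upstream-of-gene`. Intervals on chromosomes absent from
#' the annotation are skipped with a warning.
#'
#' @param intervals data.frame from [candidateIntervals()].
#' @param genes `GRanges` (from [readGenes()]) or a GFF3/BED path.
#' @return data.frame: snp, chrom, pos, gene, gene_start, gene_end, strand,
#'   distance, relation, in_interval.
#' @export
mapGenes <- function(intervals, genes) {
  if (is.character(genes)) genes <- readGenes(genes)
  gchrom <- as.character(GenomicRanges::seqnames(genes))
  unknown <- setdiff(unique(intervals$chrom), unique(gchrom))
  if (length(unknown))
    warning("chromosome(s) absent from annotation skipped: ",
            paste(unknown, collapse = ", "))
  rows <- list()
  for (i in seq_len(nrow(intervals))) {
    iv <- intervals[i, ]
    sel <- which(gchrom == iv$chrom)
    if (!length(sel)) next
    gs <- GenomicRanges::start(genes)[sel]
    ge <- GenomicRanges::end(genes)[sel]
    st <- as.character(GenomicRanges::strand(genes))[sel]
    ids <- S4Vectors::mcols(genes)$ID[sel]
    inside <- ge >= iv$start & gs <= iv$end
    gene_dist <- ifelse(iv$pos >= gs & iv$pos <= ge, 0L,
                        pmin(abs(iv$pos - gs), abs(iv$pos - ge)))
    add <- function(j, in_interval) {
      rows[[length(rows) + 1L]] <<- data.frame(
        snp = iv$snp, chrom = iv$chrom, pos = iv$pos,
        gene = ids[j], gene_start = gs[j], gene_end = ge[j],
        strand = st[j], distance = gene_dist[j],
        relation = .snpGeneRelation(iv$pos, gs[j], ge[j], st[j]),
        in_interval = in_interval, stringsAsFactors = FALSE)
    }
    for (j in which(inside)) add(j, TRUE)
    if (any(!inside)) {
      j <- which(!inside)[which.min(gene_dist[!inside])]
      add(j, FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(snp = character(), chrom = character(), pos = integer(),
               gene = character(), gene_start = integer(),
               gene_end = integer(), strand = character(),
               distance = integer(), relation = character(),
               in_interval = logical())
  rownames(out) <- NULL
  out
}

#' Cross-method consensus and pleiotropy bookkeeping
#'
#' Unifies the significant (SNP, variable) pairs of the three detection
#' methods. A SNP is pleiotropic iff it is associated with >= 2 distinct
#' variables (union across methods). Reports the per-SNP union table,
#' SNPs common to >= 2 methods, and per-chromosome / per-variable counts.
#'
#' @param results named list of data.frames, one per method, each with
#'   columns snp, chrom, pos, variable (variable may be `NA` for methods that
#'   flag loci without a driver, e.g. the RDA scan).
#' @return list of class `ConsensusTable`: `pairs` (snp, variable, methods),
#'   `snps` (snp, chrom, pos, n_variables, pleiotropic, methods),
#'   `common_snps` (ids found by >= 2 methods), `by_chrom`, `by_variable`.
#' @export
consensusPleiotropy <- function(results) {
  stopifnot(is.list(results), !is.null(names(results)))
  long <- do.call(rbind, lapply(names(results), function(m) {
    r <- results[[m]]
    if (is.null(r) || !nrow(r)) return(NULL)
    data.frame(snp = r$snp, chrom = r$chrom, pos = r$pos,
               variable = if ("variable" %in% colnames(r))
                 as.character(r$variable) else NA_character_,
               method = m, stringsAsFactors = FALSE)
  }))
  if (is.null(long) || !nrow(long))
    return(structure(list(pairs = data.frame(), snps = data.frame(),
                          common_snps = character(), by_chrom = table(NULL),
                          by_variable = table(NULL)),
                     class = "ConsensusTable"))
  posmap <- unique(long[, c("snp", "chrom", "pos")])
  if (anyDuplicated(posmap$snp))
    stop("conflicting positions for SNP id(s): ",
         paste(unique(posmap$snp[duplicated(posmap$snp)]), collapse = ", "))

  pairs <- stats::aggregate(method ~ snp + variable, data = long,
                            FUN = function(m) paste(sort(unique(m)), collapse = ","))
  names(pairs)[names(pairs) == "method"] <- "methods"

  per_snp <- split(long, long$snp)
  snps <- do.call(rbind, lapply(per_snp, function(s) {
    vars <- unique(s$variable[!is.na(s$variable)])
    data.frame(snp = s$snp[1], chrom = s$chrom[1], pos = s$pos[1],
               n_variables = length(vars),
               pleiotropic = length(vars) >= 2,
               methods = paste(sort(unique(s$method)), collapse = ","),
               variables = paste(sort(vars), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rownames(snps) <- NULL
  snps <- snps[order(snps$chrom, snps$pos), ]

  meth_per_snp <- vapply(per_snp, function(s) length(unique(s$method)), integer(1))
  common <- names(meth_per_snp)[meth_per_snp >= 2]
  structure(list(pairs = pairs, snps = snps, common_snps = common,
                 by_chrom = table(snps$chrom),
                 by_variable = table(long$variable[!is.na(long$variable)])),
            class = "ConsensusTable")
}

#' @export
print.ConsensusTable <- function(x, ...) {
  cat("ConsensusTable:", nrow(x$snps), "loci,",
      sum(x$snps$pleiotropic), "pleiotropic,",
      length(x$common_snps), "found by >= 2 methods\n")
  invisible(x)
}
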