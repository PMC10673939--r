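#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
NULL

#' GenotypeData: diploid dosage matrix with locus metadata
#'
#' Container for a panel of biallelic SNP genotypes coded as alternate-allele
#' dosages. Rows are samples, columns are loci; values are 0 (homozygous
#' reference), 1 (heterozygous), 2 (homozygous alternate) or `NA` (missing
#' call). Locus metadata (chromosome, 1-based position, alleles, identifier)
#' live in a [GenomicRanges::GRanges] of width-1 ranges, kept sorted by
#' (chromosome, position).
#'
#' @slot dosage integer matrix, samples x loci, values in \{0,1,2,NA\}, with
#'   sample ids as rownames and locus ids as colnames.
#' @slot loci `GRanges` of SNP positions with metadata columns `id`, `ref`,
#'   `alt`.
#'
#' @seealso [genotypeData()], [readGenotypes()], [locusQC()]
#' @export
setClass("GenotypeData",
  representation(dosage = "matrix", loci = "GRanges"))

setValidity("GenotypeData", function(object) {
  msg <- character()
  d <- object@dosage
  if (ncol(d) != length(object@loci))
    msg <- c(msg, "ncol(dosage) must equal length(loci)")
  bad <- d[!is.na(d)]
  if (length(bad) && !all(bad %in% c(0L, 1L, 2L)))
    msg <- c(msg, "dosage values must be 0, 1, 2 or NA")
  if (is.null(rownames(d)))
    msg <- c(msg, "dosage must carry sample ids as rownames")
  if (length(object@loci)) {
    if (any(GenomicRanges::width(object@loci) != 1L))
      msg <- c(msg, "loci must be width-1 SNP positions")
    o <- order(as.factor(GenomicRanges::seqnames(object@loci)),
               GenomicRanges::start(object@loci))
    if (!identical(o, seq_along(object@loci)))
      msg <- c(msg, "loci must be sorted by (chromosome, position)")
    mc <- S4Vectors::mcols(object@loci)
    if (!all(c("id", "ref", "alt") %in% colnames(mc)))
      msg <- c(msg, "loci metadata must include id, ref, alt")
    else if (any(as.character(mc$ref) == as.character(mc$alt)))
      msg <- c(msg, "ref and alt alleles must differ")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeData object
#'
#' @param dosage numeric or integer matrix, samples x loci, values in
#'   \{0,1,2,NA\}.
#' @param chrom character vector of chromosome names, one per locus.
#' @param pos integer vector of 1-based positions.
#' @param id locus identifiers; defaults to `chrom_pos`.
#' @param ref,alt single-base alleles (placeholders by default: the pipeline
#'   only uses dosages).
#' @return A [GenotypeData-class] object with loci sorted by (chromosome,
#'   position); the dosage columns are reordered to match.
#' @examples
#' g <- genotypeData(matrix(c(0, 1, 2, 0), 2, 2,
#'                          dimnames = list(c("s1", "s2"), NULL)),
#'                   chrom = c("1H", "1H"), pos = c(100L, 50L))
#' loci(g)
#' @export
genotypeData <- function(dosage, chrom, pos, id = NULL, ref = "A", alt = "T") {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.null(id)) id <- paste(chrom, pos, sep = "_")
  chrom <- as.character(chrom)
  o <- order(chrom, pos)
  gr <- GenomicRanges::GRanges(
    factor(chrom[o], levels = sort(unique(chrom))),
    IRanges::IRanges(as.integer(pos)[o], width = 1L),
    id = as.character(id)[o],
    ref = rep_len(ref, length(pos))[o],
    alt = rep_len(alt, length(pos))[o])
  dosage <- dosage[, o, drop = FALSE]
  colnames(dosage) <- S4Vectors::mcols(gr)$id
  new("GenotypeData", dosage = dosage, loci = gr)
}

#' @describeIn GenotypeData-class alternate-allele dosage matrix (samples x loci)
#' @param object,x a `GenotypeData`
#' @export
setGeneric("dosage", function(object) standardGeneric("dosage"))

#' @export
setMethod("dosage", "GenotypeData", function(object) object@dosage)

#' @describeIn GenotypeData-class locus `GRanges` with `id`, `ref`, `alt`
#' @export
setGeneric("loci", function(object) standardGeneric("loci"))

#' @export
setMethod("loci", "GenotypeData", function(object) object@loci)

#' @describeIn GenotypeData-class sample identifiers
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))

#' @export
setMethod("sampleIds", "GenotypeData", function(object) rownames(object@dosage))

#' @describeIn GenotypeData-class number of samples
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))

#' @export
setMethod("nSamples", "GenotypeData", function(object) nrow(object@dosage))

#' @describeIn GenotypeData-class number of loci
#' @export
setGeneric("nLoci", function(object) standardGeneric("nLoci"))

#' @export
setMethod("nLoci", "GenotypeData", function(object) ncol(object@dosage))

#' @describeIn GenotypeData-class per-locus data.frame view of the metadata
#' @export
setGeneric("lociTable", function(object) standardGeneric("lociTable"))

#' @export
setMethod("lociTable", "GenotypeData", function(object) {
  gr <- object@loci
  data.frame(locus = S4Vectors::mcols(gr)$id,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             pos = GenomicRanges::start(gr),
             ref = as.character(S4Vectors::mcols(gr)$ref),
             alt = as.character(S4Vectors::mcols(gr)$alt),
             stringsAsFactors = FALSE)
})

#' @export
setMethod("show", "GenotypeData", function(object) {
  d <- object@dosage
  cat("GenotypeData:", nrow(d), "samples x", ncol(d), "loci\n")
  if (ncol(d)) {
    chr <- table(as.character(GenomicRanges::seqnames(object@loci)))
    cat("  chromosomes:", paste0(names(chr), " (", chr, ")", collapse = ", "), "\n")
  }
  miss <- mean(is.na(d))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
})

#' Subset samples and/or loci
#' @param i sample index, @param j locus index
#' @rdname GenotypeData-class
#' @param i,j,...,drop subsetting indices (samples, loci); `drop` is ignored
#' @export
setMethod("[", "GenotypeData", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@dosage))
  if (missing(j)) j <- seq_len(ncol(x@dosage))
  new("GenotypeData", dosage = x@dosage[i, j, drop = FALSE], loci = x@loci[j])
})

#' EnvData: geo-referenced sample environment table
#'
#' Per-sample geography (latitude, longitude, altitude) and named climate
#' variables (e.g. monthly temperature, precipitation, solar radiation).
#' Geography is kept unscaled in its own slot; climate variables may be
#' z-scored via [standardizeEnv()], tracked by the `standardized` flag.
#'
#' @slot samples character vector of sample ids (one row per genotyped sample).
#' @slot coords data.frame with columns `lat`, `lon`, `alt` (degrees, degrees,
#'   metres).
#' @slot site integer site index per sample (which sampling location the
#'   accession came from).
#' @slot vars numeric matrix samples x climate variables.
#' @slot standardized logical: are `vars` z-scored?
#' @export
setClass("EnvData",
  representation(samples = "character", coords = "data.frame",
                 site = "integer", vars = "matrix", standardized = "logical"))

setValidity("EnvData", function(object) {
  msg <- character()
  n <- length(object@samples)
  if (nrow(object@coords) != n) msg <- c(msg, "coords rows must match samples")
  if (nrow(object@vars) != n) msg <- c(msg, "vars rows must match samples")
  if (!all(c("lat", "lon", "alt") %in% colnames(object@coords)))
    msg <- c(msg, "coords must have lat, lon, alt")
  if (length(object@site) && length(object@site) != n)
    msg <- c(msg, "site must match samples")
  if (object@standardized && ncol(object@vars)) {
    mu <- colMeans(object@vars)
    sdv <- apply(object@vars, 2, stats::sd)
    if (any(abs(mu) > 1e-9) || any(abs(sdv - 1) > 1e-9))
      msg <- c(msg, "standardized vars must have mean 0, sd 1 (tol 1e-9)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an EnvData object
#'
#' @param samples sample ids.
#' @param coords data.frame with `lat`, `lon`, `alt`.
#' @param vars numeric matrix of climate variables (samples x variables).
#' @param site optional integer site index per sample.
#' @param standardized logical flag (default `FALSE`).
#' @return An [EnvData-class] object.
#' @export
envData <- function(samples, coords, vars, site = integer(), standardized = FALSE) {
  vars <- as.matrix(vars)
  rownames(vars) <- samples
  new("EnvData", samples = as.character(samples), coords = coords,
      site = as.integer(site), vars = vars, standardized = standardized)
}

#' @describeIn EnvData-class climate-variable matrix
#' @param object an `EnvData`
#' @export
setGeneric("envVars", function(object) standardGeneric("envVars"))

#' @export
setMethod("envVars", "EnvData", function(object) object@vars)

#' @describeIn EnvData-class geographic coordinates (lat, lon, alt), unscaled
#' @export
setGeneric("envCoords", function(object) standardGeneric("envCoords"))

#' @export
setMethod("envCoords", "EnvData", function(object) object@coords)

#' @describeIn EnvData-class site index per sample
#' @export
setGeneric("envSites", function(object) standardGeneric("envSites"))

#' @export
setMethod("envSites", "EnvData", function(object) object@site)

#' @describeIn EnvData-class is the table z-scored?
#' @export
setGeneric("isStandardized", function(object) standardGeneric("isStandardized"))

#' @export
setMethod("isStandardized", "EnvData", function(object) object@standardized)

#' @export
setMethod("sampleIds", "EnvData", function(object) object@samples)

#' @export
setMethod("show", "EnvData", function(object) {
  cat("EnvData:", length(object@samples), "samples,",
      ncol(object@vars), "climate variables",
      if (object@standardized) "(standardized)" else "(raw)", "\n")
  if (length(object@site))
    cat("  sites:", length(unique(object@site)), "\n")
  if (ncol(object@vars))
    cat("  variables:", paste(utils::head(colnames(object@vars), 8), collapse = ", "),
        if (ncol(object@vars) > 8) "..." else "", "\n")
})

#' Write / read an environment table as TSV
#'
#' Plain TSV with header `sample lat lon alt site <var>...`.
#' @param env an [EnvData-class] object.
#' @param path file path.
#' @return `readEnvTable` returns an [EnvData-class]; `writeEnvTable` the path,
#'   invisibly.
#' @export
writeEnvTable <- function(env, path) {
  df <- data.frame(sample = env@samples, env@coords,
                   site = if (length(env@site)) env@site else NA_integer_,
                   env@vars, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEnvTable
#' @export
readEnvTable <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  fixed <- c("sample", "lat", "lon", "alt", "site")
  vars <- as.matrix(df[, setdiff(colnames(df), fixed), drop = FALSE])
  envData(df$sample, df[, c("lat", "lon", "alt")], vars,
          site = if ("site" %in% colnames(df) && !anyNA(df$site))
            as.integer(df$site) else integer())
}
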