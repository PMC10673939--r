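#' Tiling sliding windows over chromosomes
#'
#' Windows start at 1 and advance by `step`; a window extending past the
#' chromosome end is truncated and flagged partial.
#'
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param size window size in bp (default 20000).
#' @param step step size in bp (default 10000; a step larger than the size
#'   warns about gaps).
#' @return data.frame: chrom, start, end (1-based inclusive), partial.
#' @export
makeWindows <- function(chrom_lengths, size = 20000, step = 10000) {
  stopifnot(size >= 1, step >= 1)
  if (step > size) warning("step > size: windows leave gaps")
  rows <- lapply(names(chrom_lengths), function(chr) {
    len <- chrom_lengths[[chr]]
    starts <- seq(1, len, by = step)
    full <- starts[starts + size - 1 <= len]
    if (!length(full)) full <- integer()
    last_end <- if (length(full)) full[length(full)] + size - 1 else 0
    if (last_end < len) {
      nxt <- if (length(full)) full[length(full)] + step else 1
      if (nxt <= len) full <- c(full, nxt)
    }
    ends <- pmin(full + size - 1, len)
    data.frame(chrom = chr, start = full, end = ends,
               partial = ends - full + 1L < size)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Tajima's D constants for sample size (chromosome count) n
.tajimaConstants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Sliding-window diversity statistics
#'
#' Per site, with `n_c` the number of non-missing chromosomes (2 x non-missing
#' individuals) and `p` the alternate-allele frequency, nucleotide diversity
#' is `pi = 2 p (1-p) n_c / (n_c - 1)` (the unbiased pairwise-difference
#' estimator). Per window over its segregating sites: `snp_count = S`;
#' `pi_per_site` = mean per-site pi; `theta_w_per_site = 1 / a1(n)` with n the
#' rounded window-average chromosome count (the per-segregating-site
#' Watterson estimator S/a1 divided by S); and Tajima's
#' `D = (pi_sum - S/a1) / sqrt(e1 S + e2 S (S-1))` with the standard
#' constants at n. Statistics are undefined (`NA`) when S = 0. Sites with
#' fewer than 2 callable chromosomes are skipped and counted.
#'
#' Normalization note: `pi` and `theta_w` are reported per segregating site,
#' not per bp - the convention that matches reduced-representation SNP
#' panels, where invariant sites are unobserved. `per_bp = TRUE` divides the
#' sums by the window width instead.
#'
#' @param g a [GenotypeData-class].
#' @param windows data.frame from [makeWindows()].
#' @param per_bp normalize pi and theta by window width instead of by
#'   segregating site (default `FALSE`).
#' @return the `windows` data.frame with columns snp_count, pi, theta_w,
#'   tajima_d, n_chrom appended; attribute `skipped_sites`.
#' @export
windowStats <- function(g, windows, per_bp = FALSE) {
  d <- dosage(g)
  ncall <- colSums(!is.na(d))
  nchrom <- 2 * ncall
  usable <- nchrom >= 2
  skipped <- sum(!usable)
  p <- colSums(d, na.rm = TRUE) / pmax(nchrom, 1)
  pi_site <- 2 * p * (1 - p) * nchrom / pmax(nchrom - 1, 1)
  seg <- usable & p > 0 & p < 1

  lt <- lociTable(g)
  wg <- GenomicRanges::GRanges(windows$chrom,
                               IRanges::IRanges(windows$start, windows$end))
  sg <- GenomicRanges::GRanges(lt$chrom, IRanges::IRanges(lt$pos, width = 1))
  ov <- GenomicRanges::findOverlaps(wg, sg)
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)

  nW <- nrow(windows)
  S <- integer(nW); pis <- rep(NA_real_, nW)
  theta <- rep(NA_real_, nW); D <- rep(NA_real_, nW)
  nbar_out <- rep(NA_real_, nW)
  for (w in seq_len(nW)) {
    sites <- sh[qh == w]
    sites <- sites[seg[sites]]
    S[w] <- length(sites)
    if (S[w] == 0) next
    pi_sum <- sum(pi_site[sites])
    nbar <- round(mean(nchrom[sites]))
    nbar_out[w] <- nbar
    k <- .tajimaConstants(nbar)
    denom <- if (per_bp) (windows$end[w] - windows$start[w] + 1) else S[w]
    pis[w] <- pi_sum / denom
    theta[w] <- (S[w] / k$a1) / denom
    varD <- k$e1 * S[w] + k$e2 * S[w] * (S[w] - 1)
    D[w] <- if (varD > 0) (pi_sum - S[w] / k$a1) / sqrt(varD) else NA_real_
  }
  out <- windows
  out$snp_count <- S
  out$pi <- pis
  out$theta_w <- theta
  out$tajima_d <- D
  out$n_chrom <- nbar_out
  attr(out, "skipped_sites") <- skipped
  out
}

#' Compare diversity between candidate and non-candidate windows
#'
#' A window is a candidate iff it overlaps at least one candidate interval by
#' >= 1 bp. Reports the mean and sd of snp_count, pi, theta_w and Tajima's D
#' per class; windows with undefined D are excluded from the D summary with
#' their count reported.
#'
#' @param windows filled window data.frame from [windowStats()].
#' @param candidate_intervals data.frame with chrom, start, end (1-based
#'   inclusive), e.g. from [candidateIntervals()].
#' @return list of class `WindowComparison`: `summary` (long data.frame:
#'   class, statistic, mean, sd, n), `candidate_flag` per window, counts of
#'   windows with undefined D, `empty_class` flag.
#' @export
compareCandidateWindows <- function(windows, candidate_intervals) {
  wg <- GenomicRanges::GRanges(windows$chrom,
                               IRanges::IRanges(windows$start, windows$end))
  flag <- rep(FALSE, nrow(windows))
  if (!is.null(candidate_intervals) && nrow(candidate_intervals)) {
    cg <- GenomicRanges::GRanges(candidate_intervals$chrom,
                                 IRanges::IRanges(candidate_intervals$start,
                                                  candidate_intervals$end))
    flag <- GenomicRanges::countOverlaps(wg, cg) > 0
  }
  empty_class <- !any(flag) || all(flag)
  stats_cols <- c("snp_count", "pi", "theta_w", "tajima_d")
  rows <- list()
  for (cls in c(TRUE, FALSE)) {
    sel <- windows[flag == cls, , drop = FALSE]
    for (s in stats_cols) {
      x <- sel[[s]]
      x <- x[!is.na(x)]
      rows[[length(rows) + 1L]] <-
        data.frame(class = if (cls) "candidate" else "noncandidate",
                   statistic = s,
                   mean = if (length(x)) mean(x) else NA_real_,
                   sd = if (length(x) > 1) stats::sd(x) else NA_real_,
                   n = length(x))
    }
  }
  structure(list(summary = do.call(rbind, rows), candidate_flag = flag,
                 n_undefined_d = sum(is.na(windows$tajima_d)),
                 empty_class = empty_class),
            class = "WindowComparison")
}

#' @export
print.WindowComparison <- function(x, ...) {
  print(x$summary, row.names = FALSE)
  if (x$empty_class) cat("  note: one comparison class is empty\n")
  invisible(x)
}

# Hill-Weir expected r^2 at recombination parameter C = rho * d for a sample
# of n chromosomes
.hillWeirE <- function(C, n) {
  ((10 + C) / ((2 + C) * (11 + C))) *
    (1 + ((3 + C) * (12 + 12 * C + C^2)) / (n * (2 + C) * (11 + C)))
}

#' LD decay curve and per-chromosome decay distance
#'
#' Scores every within-chromosome locus pair up to `max_dist` apart with the
#' squared dosage correlation, averages r-squared in distance bins, and fits
#' the Hill-Weir expected-r-squared curve (sample-size-adjusted) by nonlinear
#' least squares on the bin means. The decay distance is the smallest distance
#' at which the fitted curve falls to halfway between its value at d = 0 and
#' its large-distance asymptote (~1/n); a fixed-threshold mode
#' (`fitted r^2 < cutoff`) is also reported.
#'
#' @param g a [GenotypeData-class].
#' @param max_dist maximum pair distance in bp (default 300000).
#' @param bin bin width in bp (default 1000).
#' @param cutoff fixed r-squared cutoff for the threshold mode (default 0.1).
#' @param min_bins minimum populated bins for a fit (default 10; below it the
#'   chromosome's decay distance is `NA`, flagged).
#' @return list of class `LDDecayCurve`: `bins` (chrom, bin_start, mean_r2,
#'   n_pairs), `decay` (chrom, rho, decay_distance, decay_threshold, flagged),
#'   `n_chromosomes_flagged`.
#' @export
ldDecay <- function(g, max_dist = 300000, bin = 1000, cutoff = 0.1,
                    min_bins = 10) {
  d <- dosage(g)
  storage.mode(d) <- "double"
  lt <- lociTable(g)
  nchrom_eff <- 2 * nrow(d)
  binsL <- list(); decL <- list()
  for (chr in unique(lt$chrom)) {
    idx <- which(lt$chrom == chr)
    pos <- lt$pos[idx]
    if (length(idx) < 2) next
    r2m <- suppressWarnings(
      stats::cor(d[, idx, drop = FALSE], use = "pairwise.complete.obs"))^2
    pr <- which(upper.tri(r2m), arr.ind = TRUE)
    dist <- pos[pr[, 2]] - pos[pr[, 1]]
    keep <- dist > 0 & dist <= max_dist & !is.na(r2m[pr])
    dist <- dist[keep]
    r2v <- r2m[pr][keep]
    if (!length(dist)) next
    bidx <- floor((dist - 1) / bin)
    bs <- stats::aggregate(r2v, by = list(bin = bidx), FUN = mean)
    cnt <- as.integer(table(bidx)[as.character(bs$bin)])
    bdf <- data.frame(chrom = chr, bin_start = bs$bin * bin + 1,
                      mid = bs$bin * bin + bin / 2,
                      mean_r2 = bs$x, n_pairs = cnt)
    binsL[[chr]] <- bdf
    flagged <- nrow(bdf) < min_bins
    rho <- NA_real_; dd <- NA_real_; dthr <- NA_real_
    if (!flagged) {
      fit <- try(minpack.lm::nlsLM(
        mean_r2 ~ .hillWeirE(rho * mid, nchrom_eff),
        data = bdf, start = list(rho = 1e-4),
        lower = 1e-12, upper = 1,
        control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
      if (inherits(fit, "try-error")) {
        flagged <- TRUE
      } else {
        rho <- stats::coef(fit)[["rho"]]
        r0 <- .hillWeirE(0, nchrom_eff)
        rfloor <- 1 / nchrom_eff
        target <- (r0 + rfloor) / 2
        fn <- function(dd) .hillWeirE(rho * dd, nchrom_eff) - target
        if (fn(1) <= 0) {
          dd <- 1
        } else if (fn(max_dist) > 0) {
          dd <- max_dist
          flagged <- TRUE
        } else dd <- stats::uniroot(fn, c(1, max_dist))$root
        fc <- function(x) .hillWeirE(rho * x, nchrom_eff) - cutoff
        dthr <- if (fc(1) <= 0) 1
                else if (fc(max_dist) > 0) NA_real_
                else stats::uniroot(fc, c(1, max_dist))$root
      }
    }
    decL[[chr]] <- data.frame(chrom = chr, rho = rho, decay_distance = dd,
                              decay_threshold = dthr, flagged = flagged)
  }
  bins <- do.call(rbind, binsL); rownames(bins) <- NULL
  decay <- do.call(rbind, decL); rownames(decay) <- NULL
  structure(list(bins = bins, decay = decay,
                 n_chromosomes_flagged = sum(decay$flagged)),
            class = "LDDecayCurve")
}

#' @export
print.LDDecayCurve <- function(x, ...) {
  cat("LDDecayCurve:\n")
  print(x$decay, row.names = FALSE)
  invisible(x)
}
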