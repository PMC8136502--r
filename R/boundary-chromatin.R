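## Repeat-density metaprofiles around ChIP-seq peak boundaries, summit/
## repeat overlap bookkeeping, peak-set intersection, and the methylated-
## CpG-count vs binding stratification.

#' Repeat density profile around peak boundaries
#'
#' For every peak start boundary, bins of \code{bin} bases spanning
#' [-window, +window) are laid out oriented into the peak (negative =
#' outside); every peak end boundary is mirrored so that "inside" is
#' always positive. Density per bin is the fraction of bin bases covered
#' by the (reduced) repeat set, aggregated over all boundaries; bins
#' running off a contig contribute only their in-genome bases to the
#' denominator. Background is the genome-wide covered fraction, so uniform
#' repeat placement gives enrichment 1 by construction. Peaks shorter than
#' the window still contribute both boundaries (their interiors overlap,
#' which the per-base oracle reproduces).
#'
#' @param peaks 1-based \code{GRanges} of peaks.
#' @param repeats 1-based \code{GRanges} of the repeat class.
#' @param window half-window in bases (multiple of \code{bin}).
#' @param bin bin width in bases.
#' @param genomeLengths named integer of contig lengths.
#' @return A \linkS4class{BoundaryProfile}.
#' @export
boundaryProfile <- function(peaks, repeats, window = 2000L, bin = 100L,
                            genomeLengths) {
  if (length(peaks) == 0L) stop("empty peak set")
  window <- as.integer(window); bin <- as.integer(bin)
  if (window %% bin != 0L) stop("window must be a multiple of bin")
  contigs <- names(genomeLengths)
  covs <- lapply(contigs, function(ct) {
    r <- IRanges::reduce(GenomicRanges::ranges(
      repeats[GenomicRanges::seqnames(repeats) == ct]))
    IRanges::coverage(r, width = genomeLengths[[ct]])
  })
  names(covs) <- contigs
  nbin <- 2L * window %/% bin
  covered <- numeric(nbin); bases <- numeric(nbin)
  binFrom <- -window + (seq_len(nbin) - 1L) * bin   # signed distance, inside > 0
  for (i in seq_along(peaks)) {
    ct <- as.character(GenomicRanges::seqnames(peaks))[i]
    if (!ct %in% contigs) next
    cov <- covs[[ct]]; L <- genomeLengths[[ct]]
    s0 <- GenomicRanges::start(peaks)[i] - 1L    # 0-based boundary offsets
    e0 <- GenomicRanges::end(peaks)[i]
    for (j in seq_len(nbin)) {
      lo <- binFrom[j]; hi <- lo + bin
      ## start boundary: inside is to the right
      a <- max(0L, s0 + lo); b <- min(L, s0 + hi)
      if (b > a) {
        covered[j] <- covered[j] +
          sum(S4Vectors::window(cov, start = a + 1L, end = b) >= 1L)
        bases[j] <- bases[j] + (b - a)
      }
      ## end boundary, mirrored: inside is to the left
      a <- max(0L, e0 - hi); b <- min(L, e0 - lo)
      if (b > a) {
        covered[j] <- covered[j] +
          sum(S4Vectors::window(cov, start = a + 1L, end = b) >= 1L)
        bases[j] <- bases[j] + (b - a)
      }
    }
  }
  totalCov <- sum(vapply(covs, function(cv) sum(cv >= 1L), 0))
  background <- totalCov / sum(unlist(genomeLengths))
  density <- ifelse(bases > 0, covered / bases, NA_real_)
  new("BoundaryProfile",
      profile = data.frame(binStart = binFrom, binCenter = binFrom + bin / 2,
                           density = density, coveredBases = covered,
                           totalBases = bases,
                           enrichment = density / background),
      background = background, window = window, bin = bin,
      nBoundaries = 2L * length(peaks))
}

#' Count peak summits inside repeats
#'
#' A summit is counted for a repeat iff start0 <= summit0 < end0 in
#' 0-based half-open coordinates (so a summit at the repeat's start
#' coordinate counts, one at its end does not). When a summit lies in
#' several repeats, the highest-score repeat takes it.
#'
#' @param peaks \code{GRanges} with a 0-based \code{summit0} mcol.
#' @param repeats 1-based \code{GRanges} with \code{subfamily} (and
#'   optionally \code{score}) mcols.
#' @return list: \code{bySubfamily} counts, \code{fractions}, \code{nIn},
#'   \code{nSummits}.
#' @export
summitOverlap <- function(peaks, repeats) {
  if (is.null(peaks$summit0)) stop("peaks must carry a summit0 mcol")
  summits <- GenomicRanges::GRanges(GenomicRanges::seqnames(peaks),
                                    IRanges::IRanges(peaks$summit0 + 1L,
                                                     width = 1L))
  ov <- GenomicRanges::findOverlaps(summits, repeats, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  if (length(qh) > 1L && !is.null(repeats$score)) {
    keep <- !duplicated(qh[order(qh, -repeats$score[sh])])
    o <- order(qh, -repeats$score[sh])
    qh <- qh[o][keep]; sh <- sh[o][keep]
  } else if (anyDuplicated(qh)) {
    keep <- !duplicated(qh)
    qh <- qh[keep]; sh <- sh[keep]
  }
  subf <- repeats$subfamily[sh]
  tab <- table(subf)
  list(bySubfamily = tab, fractions = tab / length(peaks),
       nIn = length(qh), nSummits = length(peaks))
}

#' Partition two peak sets by overlap
#'
#' Peaks are shared iff their intervals overlap by at least one base
#' (single-link); the remainder are set-specific. Counts are reported
#' pre-merge: a peak of one set overlapping two of the other contributes
#' once to its own shared count.
#'
#' @param a,b \code{GRanges} peak sets.
#' @param repeats optional \code{GRanges}; when given, the number of peaks
#'   in each partition overlapping a repeat is added.
#' @return list: \code{nSharedA}, \code{nSharedB}, \code{aSpecific},
#'   \code{bSpecific} (GRanges), \code{sharedA}, \code{sharedB} (GRanges),
#'   and per-partition \code{repeatCounts} when repeats are supplied.
#' @export
peakSetOverlap <- function(a, b, repeats = NULL) {
  ov <- GenomicRanges::findOverlaps(a, b, ignore.strand = TRUE)
  inA <- unique(S4Vectors::queryHits(ov))
  inB <- unique(S4Vectors::subjectHits(ov))
  out <- list(nSharedA = length(inA), nSharedB = length(inB),
              sharedA = a[inA], sharedB = b[inB],
              aSpecific = a[setdiff(seq_along(a), inA)],
              bSpecific = b[setdiff(seq_along(b), inB)])
  if (!is.null(repeats)) {
    cnt <- function(p) length(unique(S4Vectors::queryHits(
      GenomicRanges::findOverlaps(p, repeats, ignore.strand = TRUE))))
    out$repeatCounts <- c(sharedA = cnt(out$sharedA),
                          sharedB = cnt(out$sharedB),
                          aSpecific = cnt(out$aSpecific),
                          bSpecific = cnt(out$bSpecific))
  }
  out
}

#' Binding vs methylated-CpG-count stratification
#'
#' Categorizes repeat copies by their number of methylated CpG sites (a
#' CpG counts as methylated iff its pooled level is >= \code{threshold})
#' and tabulates bound vs unbound copies per category, with a chi-square
#' test of association and the direction of the bound-fraction trend.
#'
#' @param repeats named \code{GRanges} of repeat copies.
#' @param cpgCalls data.frame (contig, pos0, methylated, total).
#' @param boundFlags logical vector along \code{repeats}.
#' @param threshold methylated-call threshold on the per-CpG level.
#' @param maxCategory counts above this are pooled into one category.
#' @return list: \code{table} (category x bound), \code{boundFraction},
#'   \code{pValue}, \code{direction} (sign of the count-binding
#'   correlation).
#' @export
bindingVsMethylation <- function(repeats, cpgCalls, boundFlags,
                                 threshold = 0.5, maxCategory = 5L) {
  stopifnot(length(boundFlags) == length(repeats))
  level <- ifelse(cpgCalls$total > 0, cpgCalls$methylated / cpgCalls$total,
                  NA_real_)
  isMeth <- !is.na(level) & level >= threshold
  sites <- GenomicRanges::GRanges(cpgCalls$contig,
                                  IRanges::IRanges(cpgCalls$pos0 + 1L,
                                                   width = 1L))
  ov <- GenomicRanges::findOverlaps(sites[isMeth], repeats,
                                    ignore.strand = TRUE)
  mcount <- integer(length(repeats))
  t2 <- table(S4Vectors::subjectHits(ov))
  mcount[as.integer(names(t2))] <- as.integer(t2)
  cat <- pmin(mcount, maxCategory)
  catf <- factor(cat, levels = 0:maxCategory,
                 labels = c(0:(maxCategory - 1L), paste0(">=", maxCategory)))
  tab <- table(category = catf, bound = factor(boundFlags,
                                               levels = c(FALSE, TRUE)))
  keep <- rowSums(tab) > 0
  p <- if (sum(keep) >= 2 && all(colSums(tab) > 0))
    suppressWarnings(stats::chisq.test(tab[keep, , drop = FALSE])$p.value)
  else NA_real_
  bf <- ifelse(rowSums(tab) > 0, tab[, "TRUE"] / rowSums(tab), NA_real_)
  direction <- if (stats::sd(mcount) > 0 && stats::sd(boundFlags) > 0)
    sign(stats::cor(mcount, as.numeric(boundFlags))) else 0
  list(table = tab, boundFraction = bf, pValue = p, direction = direction)
}
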