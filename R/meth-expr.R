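## Per-locus CpG methylation from call tables and the CpG-count x
## methylation stratified expression analysis, plus bisulfite-PCR style
## clone tables.

#' Per-locus pooled methylation levels
#'
#' Pools per-CpG calls over each locus interval: the locus level is
#' sum(methylated) / sum(total) over the covered CpGs inside the interval
#' (read-weighted pooling, which is robust at low coverage). A locus with
#' no covered CpG has an undefined (NA) level, not zero. The unweighted
#' mean of per-CpG levels is also reported, since the two can differ at
#' uneven coverage.
#'
#' @param cpgCalls data.frame with contig, pos0 (0-based), methylated,
#'   total.
#' @param loci named 1-based \code{GRanges} of locus intervals.
#' @return data.frame: locus, nCpG (sites listed inside the locus),
#'   coveredCpG (total > 0), meanLevel (pooled), meanOfSites.
#' @export
locusMethylation <- function(cpgCalls, loci) {
  stopifnot(all(cpgCalls$total >= cpgCalls$methylated),
            all(cpgCalls$methylated >= 0))
  lociNames <- names(loci)
  if (is.null(lociNames)) lociNames <- sprintf("locus_%d", seq_along(loci))
  sites <- GenomicRanges::GRanges(cpgCalls$contig,
                                  IRanges::IRanges(cpgCalls$pos0 + 1L,
                                                   width = 1L))
  ov <- GenomicRanges::findOverlaps(sites, loci, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  n <- length(loci)
  agg <- function(v) {
    out <- numeric(n)
    s <- tapply(v[qh], sh, sum)
    out[as.integer(names(s))] <- s
    out
  }
  nCpG <- agg(rep(1, nrow(cpgCalls)))
  covered <- agg(as.numeric(cpgCalls$total > 0))
  methSum <- agg(cpgCalls$methylated)
  totSum <- agg(cpgCalls$total)
  perSite <- ifelse(cpgCalls$total > 0, cpgCalls$methylated / cpgCalls$total,
                    NA_real_)
  siteMeanSum <- agg(ifelse(is.na(perSite), 0, perSite))
  data.frame(locus = lociNames, nCpG = as.integer(nCpG),
             coveredCpG = as.integer(covered),
             meanLevel = ifelse(totSum > 0, methSum / totSum, NA_real_),
             meanOfSites = ifelse(covered > 0, siteMeanSum / covered,
                                  NA_real_),
             stringsAsFactors = FALSE)
}

#' Stratify loci by CpG count and methylation level
#'
#' Partitions loci with a defined methylation level into CpG-count bins
#' (default <=2, 3-5, >=6, reflecting the contrast between CpG-poor and
#' CpG-rich copies) and methylation-level bins (left-closed, right-open,
#' except the last bin which includes 1), so a boundary value such as 0.25
#' falls in the upper bin.
#'
#' @param meths data.frame from \code{\link{locusMethylation}}.
#' @param cpgBreaks upper edges of all but the last CpG bin (default
#'   c(2, 5) giving <=2, 3-5, >=6).
#' @param methBreaks increasing level bin edges covering [0, 1].
#' @return data.frame: locus, nCpG, meanLevel, cpgBin, methBin (factors).
#' @export
stratifyLoci <- function(meths, cpgBreaks = c(2, 5),
                         methBreaks = c(0, 0.25, 0.5, 0.75, 1)) {
  if (is.unsorted(methBreaks, strictly = TRUE) ||
      methBreaks[1] > 0 || methBreaks[length(methBreaks)] < 1)
    stop("methBreaks must be strictly increasing and cover [0, 1]")
  if (is.unsorted(cpgBreaks, strictly = TRUE))
    stop("cpgBreaks must be strictly increasing")
  d <- meths[!is.na(meths$meanLevel), , drop = FALSE]
  cpgEdges <- c(-Inf, cpgBreaks, Inf)
  cpgLabels <- c(paste0("<=", cpgBreaks[1]),
                 if (length(cpgBreaks) > 1)
                   paste0(cpgBreaks[-length(cpgBreaks)] + 1, "-",
                          cpgBreaks[-1]),
                 paste0(">=", cpgBreaks[length(cpgBreaks)] + 1))
  d$cpgBin <- cut(d$nCpG, cpgEdges, labels = cpgLabels, right = TRUE)
  mb <- cut(d$meanLevel, methBreaks, right = FALSE,
            labels = paste0("[", methBreaks[-length(methBreaks)], ",",
                            methBreaks[-1], ")"))
  ## last bin is right-closed so the exact upper edge (level 1) is included
  mb[d$meanLevel == methBreaks[length(methBreaks)]] <-
    levels(mb)[length(levels(mb))]
  d$methBin <- mb
  d[, c("locus", "nCpG", "meanLevel", "cpgBin", "methBin")]
}

#' Expression summaries per stratum
#'
#' For every CpG-count x methylation stratum: the five-number summary of
#' log10(rpm + pseudocount) (rpm averaged over the two replicates), the
#' fraction of loci expressed (>= 1 uniquely mapped read in either
#' replicate), and the fractions of expressed loci in RPM bins
#' (<=1, (1,10], (10,100], >100).
#'
#' @param strata data.frame from \code{\link{stratifyLoci}}.
#' @param expr1,expr2 replicate data.frames with locus, count, rpm.
#' @param pseudocount pseudo-RPM added before the log (default 0.5).
#' @return data.frame, one row per non-empty stratum.
#' @export
expressionByStratum <- function(strata, expr1, expr2, pseudocount = 0.5) {
  get <- function(e, what, loci) {
    v <- e[[what]][match(loci, e$locus)]
    ifelse(is.na(v), 0, v)
  }
  rows <- list()
  for (cb in levels(strata$cpgBin)) for (mb in levels(strata$methBin)) {
    loci <- strata$locus[strata$cpgBin == cb & strata$methBin == mb]
    if (length(loci) == 0L) next
    c1 <- get(expr1, "count", loci); c2 <- get(expr2, "count", loci)
    r1 <- get(expr1, "rpm", loci); r2 <- get(expr2, "rpm", loci)
    rpm <- (r1 + r2) / 2
    expressed <- c1 >= 1 | c2 >= 1
    fn <- stats::fivenum(log10(rpm + pseudocount))
    er <- rpm[expressed]
    nE <- length(er)
    rows[[length(rows) + 1L]] <- data.frame(
      cpgBin = cb, methBin = mb, nLoci = length(loci),
      fracExpressed = mean(expressed),
      logRpmMin = fn[1], logRpmQ1 = fn[2], logRpmMedian = fn[3],
      logRpmQ3 = fn[4], logRpmMax = fn[5],
      medianRpm = stats::median(rpm),
      fracRpmLe1 = if (nE) mean(er <= 1) else NA_real_,
      fracRpm1to10 = if (nE) mean(er > 1 & er <= 10) else NA_real_,
      fracRpm10to100 = if (nE) mean(er > 10 & er <= 100) else NA_real_,
      fracRpmGt100 = if (nE) mean(er > 100) else NA_real_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$cpgBin <- factor(out$cpgBin, levels = levels(strata$cpgBin))
  out$methBin <- factor(out$methBin, levels = levels(strata$methBin))
  out
}

#' Bisulfite-clone lollipop table for one locus
#'
#' Rows are sequenced clones, columns CpG sites; entries are 0/1
#' methylation states. Column means give per-CpG levels and the grand mean
#' the locus level.
#'
#' @param locus locus identifier (stored as an attribute).
#' @param clones list of equal-length binary vectors, one per clone.
#' @return list: \code{matrix} (clones x CpGs), \code{siteLevels},
#'   \code{locusLevel}.
#' @export
cloneTable <- function(locus, clones) {
  lens <- lengths(clones)
  if (length(unique(lens)) != 1L) stop("ragged clone vectors")
  m <- do.call(rbind, clones)
  if (!all(m %in% c(0, 1))) stop("clone vectors must be binary")
  structure(list(matrix = m, siteLevels = colMeans(m),
                 locusLevel = mean(m)), locus = locus)
}
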