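## Allele-specific analysis across a polymorphic insertion in F1 hybrids:
## per-SNP allelic fractions with Wilson intervals, pooled region ratios,
## and the chromatin boundary-shift detector.

.wilson_ci <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, center - half), upper = min(1, center + half))
}

#' Per-SNP allelic fractions with Wilson intervals
#'
#' fraction_A = count_A / (count_A + count_B) with a Wilson 95% confidence
#' interval (valid at low counts, unlike the Wald interval). SNPs with zero
#' total are flagged \code{"no-data"}, not dropped.
#'
#' @param counts data.frame with contig, pos0, countA, countB and
#'   optionally region_label.
#' @param conf confidence level (default 0.95).
#' @return the input with fractionA, ciLower, ciUpper, flag columns added.
#' @export
snpAllelicFractions <- function(counts, conf = 0.95) {
  stopifnot(all(counts$countA >= 0), all(counts$countB >= 0))
  n <- counts$countA + counts$countB
  counts$fractionA <- ifelse(n > 0, counts$countA / n, NA_real_)
  ci <- t(vapply(seq_len(nrow(counts)), function(i) {
    if (n[i] == 0) return(c(NA_real_, NA_real_))
    .wilson_ci(counts$countA[i], n[i], conf)
  }, c(0, 0)))
  counts$ciLower <- ci[, 1]; counts$ciUpper <- ci[, 2]
  counts$flag <- ifelse(n > 0, "ok", "no-data")
  counts
}

#' Pooled allelic ratio for a region
#'
#' Pools allele counts across the SNPs of one region and reports the
#' allele-A fraction with its Wilson interval, the fold change of the
#' insertion-free allele over the carrier allele (count_B / count_A, B
#' being the insertion-free strain), a two-sided exact binomial test
#' against 0.5, and a balanced/biased call (biased iff p < 0.01 and fold
#' or its inverse >= 1.5).
#'
#' @param counts data.frame as in \code{\link{snpAllelicFractions}} with a
#'   region_label column.
#' @param region region label to pool.
#' @param conf confidence level for the Wilson interval.
#' @return list: region, nSnps, countA, countB, fractionA, ci, fold,
#'   foldCI, pValue, flag.
#' @export
regionAllelicRatio <- function(counts, region, conf = 0.95) {
  d <- counts[counts$region_label == region, , drop = FALSE]
  d <- d[d$countA + d$countB > 0, , drop = FALSE]
  if (nrow(d) == 0L) stop("empty region: ", region)
  a <- sum(d$countA); b <- sum(d$countB); n <- a + b
  fracA <- a / n
  ci <- .wilson_ci(a, n, conf)
  fold <- b / a
  ## fold CI mapped from the Wilson interval of the B fraction
  ciB <- .wilson_ci(b, n, conf)
  foldCI <- c(lower = ciB[["lower"]] / (1 - ciB[["lower"]]),
              upper = if (ciB[["upper"]] >= 1) Inf else
                ciB[["upper"]] / (1 - ciB[["upper"]]))
  p <- stats::binom.test(a, n, 0.5)$p.value
  biased <- p < 0.01 && max(fold, 1 / fold) >= 1.5
  list(region = region, nSnps = nrow(d), countA = a, countB = b,
       fractionA = fracA, ci = ci, fold = fold, foldCI = foldCI,
       pValue = p, flag = if (biased) "biased" else "balanced")
}

#' Locate a chromatin boundary shift between two allelic profiles
#'
#' Operationalizes "where the modified domain ends": for each allele the
#' plateau is the median coverage of the peak-interior bins (bins at or
#' above half the maximum), and the boundary is the outermost edge of the
#' contiguous above-half-plateau run containing the peak maximum, on the
#' side of the supplied breakpoint. The shift report states whether the
#' carrier allele's (profile A) boundary lies within \code{tolBins} of the
#' breakpoint while the free allele's boundary lies at least
#' \code{minShiftBins} bins beyond it.
#'
#' @param profileA,profileB data.frames with binStart and coverage on a
#'   common binned axis spanning the breakpoint; A is the
#'   insertion-carrying allele.
#' @param breakpoint0 the insertion breakpoint (0-based, profile
#'   coordinates).
#' @param tolBins tolerance on the carrier boundary (default 1 bin).
#' @param minShiftBins minimum free-allele extension (default 3 bins).
#' @return list: per-allele boundary positions, shiftBins,
#'   carrierAtBreakpoint, freeBeyond, shifted.
#' @export
locateBoundaryShift <- function(profileA, profileB, breakpoint0,
                                tolBins = 1L, minShiftBins = 3L) {
  if (!identical(profileA$binStart, profileB$binStart))
    stop("profiles must share a common binned axis")
  bin <- diff(profileA$binStart[1:2])
  edge <- function(prof) {
    cov <- prof$coverage
    if (max(cov) <= 0) stop("profiles without a detectable plateau")
    interior <- cov >= max(cov) / 2
    plateau <- stats::median(cov[interior])
    thr <- plateau / 2
    above <- cov >= thr
    ## contiguous run containing the maximum
    i <- which.max(cov)
    lo <- i; while (lo > 1L && above[lo - 1L]) lo <- lo - 1L
    hi <- i; while (hi < length(cov) && above[hi + 1L]) hi <- hi + 1L
    c(left = prof$binStart[lo], right = prof$binStart[hi] + bin)
  }
  eA <- edge(profileA); eB <- edge(profileB)
  ## work on the boundary nearest the breakpoint in the carrier profile
  side <- if (abs(eA[["left"]] - breakpoint0) < abs(eA[["right"]] - breakpoint0))
    "left" else "right"
  bA <- eA[[side]]; bB <- eB[[side]]
  outward <- if (side == "right") 1 else -1   # direction away from the peak
  shiftBins <- outward * (bB - bA) / bin
  list(side = side, boundaryA = bA, boundaryB = bB,
       breakpoint0 = breakpoint0, bin = bin, shiftBins = shiftBins,
       carrierAtBreakpoint = abs(bA - breakpoint0) <= tolBins * bin,
       freeBeyond = outward * (bB - breakpoint0) >= minShiftBins * bin,
       shifted = abs(bA - breakpoint0) <= tolBins * bin &&
         outward * (bB - breakpoint0) >= minShiftBins * bin)
}
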