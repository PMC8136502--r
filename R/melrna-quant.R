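## melRNA-seq quantification: full-length (3'-adaptor) filtering, repeat
## classification of reads, 5.8S-normalized RPM, exact-unique genome
## mapping, TAP treated/untreated contrast, replicate concordance and
## rank-abundance statistics.

#' Per-class read counts
#'
#' Counts of trimmed reads per consensus-library entry (including the
#' reserved rRNA surrogates), per-family rollups, and pipeline bookkeeping
#' (totals and discarded reads).
#'
#' @slot entryCounts named numeric, reads per library entry plus
#'   "unclassified".
#' @slot familyCounts named numeric, per-family rollups.
#' @slot nTotal integer, reads entering classification.
#' @slot nAdaptorlessDiscarded integer, reads discarded at the trim step.
#' @export
setClass("ClassCounts", representation(
  entryCounts = "numeric", familyCounts = "numeric",
  nTotal = "integer", nAdaptorlessDiscarded = "integer"))

setMethod("show", "ClassCounts", function(object) {
  cat("ClassCounts:", object@nTotal, "classified reads,",
      object@nAdaptorlessDiscarded, "discarded at trimming\n")
  print(sort(object@entryCounts, decreasing = TRUE))
})

#' @describeIn ClassCounts-class per-entry counts.
#' @param x a \code{ClassCounts}.
#' @export
entryCounts <- function(x) x@entryCounts

#' @describeIn ClassCounts-class count of reads classified to the reserved
#'   5.8S surrogate (the RPM denominator).
#' @export
n5p8S <- function(x) unname(x@entryCounts[.RRNA_5P8S_NAME])

#' Retain and trim full-length reads by 3' adaptor
#'
#' A read is retained iff the adaptor occurs in it: either the full adaptor
#' as an exact internal substring, or an exact prefix of the adaptor of at
#' least \code{minOverlap} bases at the very end of the read. Retained
#' reads are trimmed at the adaptor start; trimmed reads shorter than
#' \code{minLen} bases are then dropped (unique exact mapping is
#' meaningless below that). Matching is exact; synthetic reads carry no
#' sequencing errors.
#'
#' @param reads named character vector (or DNAStringSet) of read sequences.
#' @param adaptor3 the 3' adaptor sequence (>= \code{minOverlap} bases).
#' @param minOverlap minimum adaptor prefix length at the read end.
#' @param minLen minimum trimmed length (default 20).
#' @return A list: \code{records} data.frame (id, trimmed) of retained
#'   reads, \code{nInput}, \code{nNoAdaptor}, \code{nTooShort}.
#' @export
trimFilter <- function(reads, adaptor3, minOverlap = 8L, minLen = 20L) {
  adaptor3 <- toupper(as.character(adaptor3))
  if (nchar(adaptor3) < minOverlap)
    stop("adaptor3 must be at least minOverlap bases")
  ids <- names(reads)
  reads <- as.character(reads)
  if (is.null(ids)) ids <- sprintf("read_%d", seq_along(reads))
  n <- length(reads)
  if (n == 0L)
    return(list(records = data.frame(id = character(0),
                                     trimmed = character(0)),
                nInput = 0L, nNoAdaptor = 0L, nTooShort = 0L))
  pos <- regexpr(adaptor3, reads, fixed = TRUE)
  found <- pos > 0L
  trimmedAt <- ifelse(found, pos - 1L, NA_integer_)
  ## adaptor running off the 3' end: exact prefix of >= minOverlap bases
  L <- nchar(reads)
  ks <- if (nchar(adaptor3) - 1L >= minOverlap)
    seq(nchar(adaptor3) - 1L, minOverlap) else integer(0)
  for (k in ks) {
    idx <- which(!found & L >= k)
    if (length(idx) == 0L) break
    hit <- idx[substr(reads[idx], L[idx] - k + 1L, L[idx]) ==
                 substr(adaptor3, 1L, k)]
    trimmedAt[hit] <- L[hit] - k
    found[hit] <- TRUE
  }
  trimmed <- substr(reads, 1L, trimmedAt)
  keep <- found & nchar(trimmed) >= minLen
  list(records = data.frame(id = ids[keep], trimmed = unname(trimmed[keep]),
                            stringsAsFactors = FALSE),
       nInput = n,
       nNoAdaptor = sum(!found),
       nTooShort = sum(found & nchar(trimmed) < minLen))
}

#' Classify trimmed reads against the consensus library
#'
#' Assigns each retained read to its best library entry (or
#' "unclassified"), counting the reserved rRNA surrogates separately, and
#' rolls counts up by family. Identical read sequences are classified once.
#'
#' @param records data.frame from \code{\link{trimFilter}} (columns id,
#'   trimmed).
#' @param lib a \linkS4class{ConsensusLibrary}.
#' @param minScore classification score threshold.
#' @param nDiscarded bookkeeping: reads discarded upstream at trimming.
#' @return A \linkS4class{ClassCounts}.
#' @export
classifyReads <- function(records, lib, minScore = 20, nDiscarded = 0L) {
  if (length(names(lib)) == 0L) stop("empty consensus library")
  entries <- c(names(lib), "unclassified")
  counts <- stats::setNames(numeric(length(entries)), entries)
  if (nrow(records) > 0L) {
    uniq <- unique(records$trimmed)
    cls <- .classify_batch(uniq, lib, minScore, stats = FALSE)
    assign <- ifelse(is.na(cls$subfamily), "unclassified", cls$subfamily)
    tab <- table(assign[match(records$trimmed, uniq)])
    counts[names(tab)] <- as.numeric(tab)
  }
  famOf <- c(lib@family, unclassified = "unclassified")
  fam <- tapply(counts, famOf[entries], sum)
  new("ClassCounts", entryCounts = counts,
      familyCounts = stats::setNames(as.numeric(fam), names(fam)),
      nTotal = as.integer(sum(counts)),
      nAdaptorlessDiscarded = as.integer(nDiscarded))
}

#' Normalize counts to reads per million 5.8S reads (RPM)
#'
#' RPM = count / n5.8S x 1e6, the internal-control normalization: the
#' denominator is the number of reads classified to the reserved 5.8S
#' surrogate. Invariant under uniform library-size scaling.
#'
#' @param x numeric vector of counts, or a data.frame with a \code{count}
#'   column.
#' @param n5p8S number of 5.8S reads (> 0).
#' @return Same shape as \code{x} with rpm values (data.frame input gains
#'   an \code{rpm} column).
#' @export
normalizeRpm <- function(x, n5p8S) {
  if (is.na(n5p8S) || n5p8S <= 0)
    stop("normalization error: n5p8S must be > 0")
  if (is.data.frame(x)) {
    x$rpm <- x$count / n5p8S * 1e6
    return(x)
  }
  x / n5p8S * 1e6
}

#' Map trimmed reads to the genome by exact unique matching
#'
#' A read contributes iff its trimmed sequence occurs at exactly one
#' genomic position across both strands with zero mismatches. Counts are
#' aggregated per annotated repeat locus (any >= 1 base overlap between the
#' match span and the locus interval); multi-mapping and unmapped reads are
#' tallied separately.
#'
#' @param records data.frame from \code{\link{trimFilter}}.
#' @param genome named character vector or DNAStringSet.
#' @param loci 1-based \code{GRanges} of annotated repeat loci (named).
#' @return list: \code{expression} data.frame (locus, count),
#'   \code{nUnique}, \code{nMulti}, \code{nUnmapped}.
#' @export
mapUnique <- function(records, genome, loci) {
  genome <- .as_genome(genome)
  lociNames <- names(loci)
  if (is.null(lociNames)) lociNames <- sprintf("locus_%d", seq_along(loci))
  counts <- stats::setNames(numeric(length(loci)), lociNames)
  nUnique <- 0L; nMulti <- 0L; nUnmapped <- 0L
  if (nrow(records) > 0L) {
    uniqSeq <- unique(records$trimmed)
    mult <- as.numeric(table(records$trimmed)[uniqSeq])
    subj <- lapply(names(genome), function(ct) genome[[ct]])
    names(subj) <- names(genome)
    spanRows <- list()
    for (i in seq_along(uniqSeq)) {
      pat <- Biostrings::DNAString(uniqSeq[i])
      patRc <- Biostrings::reverseComplement(pat)
      nh <- 0L; hitContig <- NA_character_; hitStart <- NA_integer_
      hitEnd <- NA_integer_
      for (contig in names(subj)) {
        for (p in list(pat, patRc)) {
          m <- Biostrings::matchPattern(p, subj[[contig]])
          if (length(m)) {
            nh <- nh + length(m)
            hitContig <- contig
            hitStart <- Biostrings::start(m)[1]
            hitEnd <- Biostrings::end(m)[1]
          }
          if (nh > 1L) break
        }
        if (nh > 1L) break
      }
      if (nh == 0L) { nUnmapped <- nUnmapped + mult[i]; next }
      if (nh > 1L) { nMulti <- nMulti + mult[i]; next }
      nUnique <- nUnique + mult[i]
      spanRows[[length(spanRows) + 1L]] <- data.frame(
        contig = hitContig, start = hitStart, end = hitEnd, mult = mult[i])
    }
    if (length(spanRows)) {
      spans <- do.call(rbind, spanRows)
      gr <- GenomicRanges::GRanges(spans$contig,
                                   IRanges::IRanges(spans$start, spans$end))
      ov <- GenomicRanges::findOverlaps(gr, loci, ignore.strand = TRUE)
      qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
      add <- tapply(spans$mult[qh], sh, sum)
      counts[as.integer(names(add))] <- counts[as.integer(names(add))] +
        as.numeric(add)
    }
  }
  list(expression = data.frame(locus = lociNames, count = unname(counts),
                               stringsAsFactors = FALSE),
       nUnique = as.numeric(nUnique), nMulti = as.numeric(nMulti),
       nUnmapped = as.numeric(nUnmapped))
}

#' TAP treated vs untreated enrichment contrast
#'
#' Per-class enrichment ratio of 5.8S-normalized counts:
#' (count_treated / n5.8S_treated) / (count_untreated / n5.8S_untreated).
#' A class with zero normalized untreated count gets an infinite ratio with
#' a flag; classes absent from both libraries are flagged undefined.
#'
#' @param treated,untreated \linkS4class{ClassCounts} of the two libraries.
#' @return data.frame (class, ratio, flag).
#' @export
tapContrast <- function(treated, untreated) {
  ntT <- n5p8S(treated); ntU <- n5p8S(untreated)
  if (is.na(ntT) || ntT <= 0 || is.na(ntU) || ntU <= 0)
    stop("both libraries must contain 5.8S reads")
  classes <- union(names(treated@entryCounts), names(untreated@entryCounts))
  ct <- treated@entryCounts[classes]; cu <- untreated@entryCounts[classes]
  ct[is.na(ct)] <- 0; cu[is.na(cu)] <- 0
  ratio <- (ct / ntT) / (cu / ntU)
  flag <- rep("ok", length(classes))
  flag[ct == 0 & cu == 0] <- "undefined"
  flag[ct > 0 & cu == 0] <- "infinite"
  ratio[flag == "undefined"] <- NA_real_
  data.frame(class = classes, ratio = unname(ratio), flag = flag,
             stringsAsFactors = FALSE)
}

#' Replicate concordance of expression estimates
#'
#' Pearson correlation of log10(rpm + pseudocount) across the union of
#' labels of two replicate runs.
#'
#' @param runA,runB data.frames with \code{locus} (or \code{label}) and
#'   \code{rpm} columns.
#' @param pseudocount added before the log (default 0.5 RPM).
#' @return Pearson correlation; \code{NA} with a warning on zero-variance
#'   input.
#' @export
replicateConcordance <- function(runA, runB, pseudocount = 0.5) {
  key <- function(d) if ("locus" %in% names(d)) d$locus else d$label
  labels <- union(key(runA), key(runB))
  if (length(labels) < 3L) stop("need at least 3 labels")
  a <- runA$rpm[match(labels, key(runA))]; a[is.na(a)] <- 0
  b <- runB$rpm[match(labels, key(runB))]; b[is.na(b)] <- 0
  if (sum(a) == 0 || sum(b) == 0) stop("need labels with nonzero totals")
  la <- log10(a + pseudocount); lb <- log10(b + pseudocount)
  if (stats::sd(la) == 0 || stats::sd(lb) == 0) {
    warning("degenerate (zero-variance) input; concordance undefined")
    return(NA_real_)
  }
  stats::cor(la, lb)
}

#' Rank-abundance table of locus expression
#'
#' Sorts loci by decreasing RPM and counts loci with RPM strictly below 1
#' and strictly above 1000 (the tails of the power-law profile).
#'
#' @param expressions data.frame with \code{locus} and \code{rpm}.
#' @return list: \code{table} data.frame (rank, locus, rpm),
#'   \code{nBelow1}, \code{nAbove1000}.
#' @export
rankAbundance <- function(expressions) {
  if (nrow(expressions) == 0L)
    return(list(table = data.frame(rank = integer(0), locus = character(0),
                                   rpm = numeric(0)),
                nBelow1 = 0L, nAbove1000 = 0L))
  o <- order(-expressions$rpm)
  tab <- data.frame(rank = seq_along(o), locus = expressions$locus[o],
                    rpm = expressions$rpm[o], stringsAsFactors = FALSE)
  list(table = tab, nBelow1 = sum(expressions$rpm < 1),
       nAbove1000 = sum(expressions$rpm > 1000))
}
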