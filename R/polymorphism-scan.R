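## Strain-pair insertional-polymorphism detection: minimum-gap alignment,
## internal-gap extraction (120-300 bp, well-aligned flanks), repeat
## classification of the gapped region, and the strict >80% occupancy rule.

#' Extract internal gap candidates from a pairwise alignment
#'
#' Scans an alignment for internal (non-terminal) gaps of
#' \code{minLen}-\code{maxLen} bases whose flanking regions are well
#' aligned. The flank rule, made concrete here: within the
#' \code{2 * minFlank} alignment columns on each side there must be at
#' least \code{minFlank} aligned (both-non-gap) base pairs at identity
#' \code{>= minFlankIdentity}. The carrier is the strain whose sequence
#' contains the extra bases. Gaps are leftmost-normalized: a gap flanked by
#' a target-site duplication is slid left as far as sequence identity
#' allows, and the slack is reported as \code{tsdLen}.
#'
#' @param aln a \code{"pairAlignment"} from \code{\link{alignMinGap}} or
#'   \code{\link{alignSeeded}}; the query is strain A, the subject strain B.
#' @param minLen,maxLen gap length bounds in bases (default 120-300).
#' @param minFlank minimum aligned flank bases each side (default 50).
#' @param minFlankIdentity minimum flank identity (default 0.9).
#' @return data.frame of gap candidates: carrier ("A"/"B"), 0-based
#'   half-open \code{gapStart0}/\code{gapEnd0} on the carrier sequence,
#'   \code{gapLen}, flank statistics, \code{tsdLen}, \code{otherPos0} (the
#'   breakpoint in the gap-free strain's coordinates) and \code{gapSeq}.
#' @export
extractInternalGaps <- function(aln, minLen = 120L, maxLen = 300L,
                                minFlank = 50L, minFlankIdentity = 0.9) {
  qv <- strsplit(aln$qaln, "", fixed = TRUE)[[1]]
  sv <- strsplit(aln$saln, "", fixed = TRUE)[[1]]
  n <- length(qv)
  qpos <- cumsum(qv != "-")  # 1-based position on query at each column
  spos <- cumsum(sv != "-")
  out <- list()
  for (side in c("q", "s")) {
    gapv <- if (side == "q") qv == "-" else sv == "-"
    carrierv <- if (side == "q") sv else qv
    carrier <- if (side == "q") "B" else "A"
    r <- rle(gapv)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    for (k in runs) {
      a <- starts[k]; b <- ends[k]
      if (a == 1L || b == n) next                     # terminal gap
      len <- b - a + 1L
      if (len < minLen || len > maxLen) next
      flankOK <- TRUE; fstats <- numeric(4)
      for (dir in 1:2) {
        cols <- if (dir == 1L) max(1L, a - 2L * minFlank):(a - 1L)
                else (b + 1L):min(n, b + 2L * minFlank)
        paired <- cols[qv[cols] != "-" & sv[cols] != "-"]
        nPair <- length(paired)
        ident <- if (nPair) sum(qv[paired] == sv[paired]) / nPair else 0
        fstats[c(dir, dir + 2L)] <- c(nPair, ident)
        if (nPair < minFlank || ident < minFlankIdentity) flankOK <- FALSE
      }
      if (!flankOK) next
      ## carrier-coordinate gap interval (0-based half-open)
      cpos <- if (side == "q") spos else qpos
      opos <- if (side == "q") qpos else spos
      gs0 <- cpos[a] - 1L; ge0 <- cpos[b]
      other0 <- opos[a - 1L]           # bases of the gap-free strain before gap
      gapSeq <- paste(carrierv[a:b], collapse = "")
      ## leftmost normalization across a possible target-site duplication:
      ## slide the gap left while the base before the gap equals its last base
      carrSeq <- if (side == "q") aln$saln else aln$qaln
      shift <- 0L
      full <- gsub("-", "", carrSeq, fixed = TRUE)
      while (shift < 100L && gs0 - shift > 0L &&
             substr(full, gs0 - shift, gs0 - shift) ==
             substr(full, ge0 - shift, ge0 - shift)) shift <- shift + 1L
      if (shift > 0L) {
        gs0 <- gs0 - shift; ge0 <- ge0 - shift
        other0 <- other0 - shift
        gapSeq <- substr(full, gs0 + 1L, ge0)
      }
      out[[length(out) + 1L]] <- data.frame(
        carrier = carrier, gapStart0 = gs0, gapEnd0 = ge0, gapLen = len,
        leftFlankLen = fstats[1], rightFlankLen = fstats[2],
        leftFlankIdentity = fstats[3], rightFlankIdentity = fstats[4],
        tsdLen = shift, otherPos0 = other0, gapSeq = gapSeq,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(carrier = character(0), gapStart0 = integer(0),
                      gapEnd0 = integer(0), gapLen = integer(0),
                      leftFlankLen = numeric(0), rightFlankLen = numeric(0),
                      leftFlankIdentity = numeric(0),
                      rightFlankIdentity = numeric(0), tsdLen = integer(0),
                      otherPos0 = integer(0), gapSeq = character(0)))
  do.call(rbind, out)
}

#' Call polymorphic insertions from gap candidates
#'
#' Classifies each gapped-region sequence against the consensus library and
#' keeps a call iff a repeat hit covers strictly more than
#' \code{minOccupancy} of the gapped region (the published rule is ">80%",
#' read literally: occupancy exactly 0.80 is rejected). Occupancy here is
#' the repeat hit's span on the gap sequence over the gap length.
#'
#' @param cands data.frame from \code{\link{extractInternalGaps}}.
#' @param lib a \linkS4class{ConsensusLibrary}.
#' @param minOccupancy strict lower bound on occupancy (default 0.80).
#' @param minScore classification score threshold.
#' @return data.frame of insertion calls: candidate fields plus
#'   \code{subfamily}, \code{divergence}, \code{occupancy}, \code{score},
#'   \code{strand}.
#' @export
callInsertions <- function(cands, lib, minOccupancy = 0.80, minScore = 20) {
  if (nrow(cands) == 0L) {
    res <- cbind(cands, subfamily = character(0), divergence = numeric(0),
                 occupancy = numeric(0), score = numeric(0),
                 strand = character(0))
    res$gapSeq <- NULL
    return(res)
  }
  rows <- lapply(seq_len(nrow(cands)), function(i) {
    hit <- tryCatch(classifySequence(cands$gapSeq[i], lib,
                                     minScore = minScore,
                                     queryId = sprintf("gap_%d", i)),
                    error = function(e) NULL)
    if (is.null(hit)) return(NULL)
    occ <- (hit@qend - hit@qstart) / cands$gapLen[i]
    if (!(occ > minOccupancy)) return(NULL)
    cbind(cands[i, , drop = FALSE],
          data.frame(subfamily = hit@subfamily, divergence = hit@divergence,
                     occupancy = occ, score = hit@score, strand = hit@strand,
                     stringsAsFactors = FALSE))
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) {
    res <- cbind(cands[0, ], data.frame(subfamily = character(0),
                                        divergence = numeric(0),
                                        occupancy = numeric(0),
                                        score = numeric(0),
                                        strand = character(0)))
    res$gapSeq <- NULL
    return(res)
  }
  res <- do.call(rbind, rows)
  res$gapSeq <- NULL
  rownames(res) <- NULL
  res
}

#' Scan a strain genome pair for polymorphic SINE insertions
#'
#' End-to-end strain comparison: seeded minimum-gap alignment of the two
#' genomes (contig by contig), internal-gap extraction with the 120-300 bp
#' and flank rules, and classification with the strict >80% occupancy rule.
#'
#' @param genomeA,genomeB named sequences (character or DNAStringSet);
#'   contigs are matched by name.
#' @param lib a \linkS4class{ConsensusLibrary}.
#' @param minLen,maxLen,minFlank,minFlankIdentity gap rules; see
#'   \code{\link{extractInternalGaps}}.
#' @param minOccupancy see \code{\link{callInsertions}}.
#' @return data.frame of calls with a \code{contig} column; carrier "A"
#'   means the extra sequence is present in \code{genomeA} only.
#' @export
scanPolymorphisms <- function(genomeA, genomeB, lib, minLen = 120L,
                              maxLen = 300L, minFlank = 50L,
                              minFlankIdentity = 0.9, minOccupancy = 0.80) {
  gA <- .as_genome(genomeA); gB <- .as_genome(genomeB)
  shared <- intersect(names(gA), names(gB))
  res <- list()
  for (contig in shared) {
    aln <- alignSeeded(as.character(gA[[contig]]), as.character(gB[[contig]]))
    cands <- extractInternalGaps(aln, minLen = minLen, maxLen = maxLen,
                                 minFlank = minFlank,
                                 minFlankIdentity = minFlankIdentity)
    calls <- callInsertions(cands, lib, minOccupancy = minOccupancy)
    if (nrow(calls)) {
      calls$contig <- contig
      res[[contig]] <- calls
    }
  }
  if (length(res) == 0L) {
    empty <- callInsertions(extractInternalGaps(
      structure(list(qaln = "A", saln = "A", score = 1),
                class = "pairAlignment")), lib)
    empty$contig <- character(0)
    return(empty)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Summarize polymorphism calls
#'
#' Cross-tabulates calls by carrier strain and subfamily and bins the gap
#' lengths into a histogram.
#'
#' @param calls data.frame from \code{\link{callInsertions}} or
#'   \code{\link{scanPolymorphisms}}.
#' @param lengthBreaks histogram breaks for gap lengths.
#' @return list with \code{table} (carrier x subfamily counts) and
#'   \code{lengthHist} (histogram counts).
#' @export
summarizePolymorphisms <- function(calls,
                                   lengthBreaks = seq(100, 350, by = 25)) {
  tab <- table(factor(calls$carrier, levels = c("A", "B")),
               calls$subfamily)
  h <- graphics::hist(pmin(pmax(calls$gapLen,
                                min(lengthBreaks)), max(lengthBreaks)),
                      breaks = lengthBreaks, plot = FALSE)
  list(table = tab,
       lengthHist = data.frame(mid = h$mids, count = h$counts))
}
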