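## Pairwise alignment layer.
##
## Two scoring schemes are used throughout the package:
##  * "min-gap" (match +1, mismatch -1, gap open 0, gap extend -1): a gap of
##    length L costs L, so long insertions align as single gaps. This is the
##    scheme for strain-pair comparison (BLAST -gapopen 0 -gapextend 1).
##  * "classify" (match +1, mismatch -1, gap open -2, gap extend -1, the
##    opening base paying the open cost): a gap of length L costs L + 1.
##    Used for repeat classification.
## Both are expressed through Biostrings::pairwiseAlignment, whose gap cost
## for a length-L gap is gapOpening + L * gapExtension.

.submat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                           baseOnly = FALSE)
}

.pa_strings <- function(pa) {
  list(q = as.character(Biostrings::alignedPattern(pa)),
       s = as.character(Biostrings::alignedSubject(pa)))
}

#' Minimum-gap-penalty global alignment
#'
#' Globally aligns two sequences under match +1, mismatch -1, zero gap
#' opening and unit gap extension, so that a gap of length L costs exactly
#' L. Under this scoring a 120-300 bp insertion aligns as a single internal
#' gap, which is what the strain-pair polymorphism scan relies on.
#'
#' For inputs whose length product exceeds \code{dpBudget} the quadratic DP
#' is refused with an error of class \code{"dpBudgetExceeded"}; callers
#' should then use the anchor-seeded route \code{\link{alignSeeded}}.
#'
#' @param query,subject character or \link[Biostrings]{DNAString} sequences.
#' @param dpBudget maximum allowed product of sequence lengths.
#' @return A list of class \code{"pairAlignment"} with elements \code{qaln},
#'   \code{saln} (equal-length gapped strings) and \code{score}.
#' @examples
#' aln <- alignMinGap("ACGTACGT", "ACGTTTACGT")
#' aln$score
#' @export
alignMinGap <- function(query, subject, dpBudget = 2.5e7) {
  query <- toupper(as.character(query)); subject <- toupper(as.character(subject))
  nq <- nchar(query); ns <- nchar(subject)
  if (nq == 0L || ns == 0L) stop("both sequences must be non-empty")
  if (as.numeric(nq) * ns > dpBudget) {
    stop(structure(class = c("dpBudgetExceeded", "error", "condition"),
                   list(message = paste0(
                     "sequence length product ", format(as.numeric(nq) * ns),
                     " exceeds the DP budget (", format(dpBudget),
                     "); use alignSeeded() for anchor-seeded alignment"),
                     call = sys.call(-1))))
  }
  ## The optimum under zero gap opening is massively degenerate: splitting a
  ## long gap into pieces costs nothing, and the traceback may scatter it.
  ## The score is taken from the exact zero-opening problem; the reported
  ## alignment uses an epsilon opening cost that breaks those ties in favor
  ## of contiguous gaps (the structure BLAST reports in practice).
  sc <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query), Biostrings::DNAString(subject),
    type = "global", substitutionMatrix = .submat(),
    gapOpening = 0, gapExtension = 1, scoreOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query), Biostrings::DNAString(subject),
    type = "global", substitutionMatrix = .submat(),
    gapOpening = 0.001, gapExtension = 1)
  st <- .pa_strings(pa)
  structure(list(qaln = st$q, saln = st$s, score = sc),
            class = "pairAlignment")
}

## Recompute the min-gap score of a stitched gapped pair (used by
## alignSeeded, where the score is assembled from pieces).
.mingap_score <- function(qaln, saln) {
  qv <- strsplit(qaln, "", fixed = TRUE)[[1]]
  sv <- strsplit(saln, "", fixed = TRUE)[[1]]
  gap <- qv == "-" | sv == "-"
  sum(ifelse(qv[!gap] == sv[!gap], 1, -1)) - sum(gap)
}

#' Anchor-seeded minimum-gap alignment of long sequences
#'
#' Aligns two long, largely collinear sequences (two strain genomes) by
#' chaining exact k-mer anchors that are unique in both sequences and
#' running the quadratic minimum-gap DP only between consecutive anchors.
#' Suitable when the sequences differ by local insertions/deletions without
#' rearrangement, which is the regime of the strain-pair polymorphism scan.
#'
#' @param query,subject sequences (character or DNAString).
#' @param k anchor k-mer length; must be long enough that anchors are
#'   effectively unique (default 31).
#' @param dpBudget passed to the piecewise \code{\link{alignMinGap}} calls.
#' @return A \code{"pairAlignment"} list as \code{\link{alignMinGap}}.
#' @export
alignSeeded <- function(query, subject, k = 31L, dpBudget = 2.5e7) {
  query <- toupper(as.character(query)); subject <- toupper(as.character(subject))
  nq <- nchar(query); ns <- nchar(subject)
  if (nq < k || ns < k) return(alignMinGap(query, subject, dpBudget))
  kq <- substring(query, seq_len(nq - k + 1L), seq_len(nq - k + 1L) + k - 1L)
  ks <- substring(subject, seq_len(ns - k + 1L), seq_len(ns - k + 1L) + k - 1L)
  uq <- !(duplicated(kq) | duplicated(kq, fromLast = TRUE))
  us <- !(duplicated(ks) | duplicated(ks, fromLast = TRUE))
  m <- match(kq, ks)
  ok <- which(uq & !is.na(m))
  ok <- ok[us[m[ok]]]
  if (length(ok) == 0L) return(alignMinGap(query, subject, dpBudget))
  qpos <- ok; spos <- m[ok]
  ## collapse runs on the same diagonal into blocks; a k-mer unique in each
  ## sequence can still pair two different planted copies, so blocks off the
  ## true chain exist and are removed by a weighted collinear-chain DP below
  diag <- spos - qpos
  newblk <- c(TRUE, diff(diag) != 0L | diff(qpos) != 1L)
  first <- which(newblk)
  last <- c(first[-1] - 1L, length(qpos))
  bq1 <- qpos[first]; bq2 <- qpos[last] + k - 1L
  bs1 <- spos[first]; bs2 <- spos[last] + k - 1L
  w <- last - first + 1L
  nbAll <- length(first)
  ## heaviest chain of blocks, strictly increasing in both coordinates
  ## (anchor-length overlaps tolerated; trimmed during stitching)
  best <- as.numeric(w); prev <- integer(nbAll)
  for (i in seq_len(nbAll)) {
    for (j in seq_len(i - 1L)) {
      if (bq2[j] <= bq1[i] + k && bs2[j] <= bs1[i] + k &&
          best[j] + w[i] > best[i]) {
        best[i] <- best[j] + w[i]
        prev[i] <- j
      }
    }
  }
  sel <- integer(0); i <- which.max(best)
  while (i > 0L) { sel <- c(i, sel); i <- prev[i] }
  bq1 <- bq1[sel]; bq2 <- bq2[sel]; bs1 <- bs1[sel]; bs2 <- bs2[sel]
  nb <- length(sel)
  qpieces <- character(0); spieces <- character(0)
  ## leading unanchored ends
  addseg <- function(qs, qe, ss, se) {
    qseg <- if (qe >= qs) substr(query, qs, qe) else ""
    sseg <- if (se >= ss) substr(subject, ss, se) else ""
    if (nchar(qseg) == 0L && nchar(sseg) == 0L) return(NULL)
    if (nchar(qseg) == 0L)
      return(list(q = strrep("-", nchar(sseg)), s = sseg))
    if (nchar(sseg) == 0L)
      return(list(q = qseg, s = strrep("-", nchar(qseg))))
    a <- alignMinGap(qseg, sseg, dpBudget)
    list(q = a$qaln, s = a$saln)
  }
  pieces <- list()
  p <- addseg(1L, bq1[1] - 1L, 1L, bs1[1] - 1L)
  if (!is.null(p)) pieces[[length(pieces) + 1L]] <- p
  for (i in seq_len(nb)) {
    pieces[[length(pieces) + 1L]] <-
      list(q = substr(query, bq1[i], bq2[i]),
           s = substr(subject, bs1[i], bs2[i]))
    if (i < nb) {
      ## trim potential anchor overlap on either side
      qs <- bq2[i] + 1L; qe <- bq1[i + 1L] - 1L
      ss <- bs2[i] + 1L; se <- bs1[i + 1L] - 1L
      if (qe < qs - 1L || se < ss - 1L) {
        ## overlapping anchors (possible around tandem duplications):
        ## shrink the earlier block
        shrink <- max(qs - 1L - qe, ss - 1L - se)
        lastp <- pieces[[length(pieces)]]
        pieces[[length(pieces)]] <- list(
          q = substr(lastp$q, 1L, nchar(lastp$q) - shrink),
          s = substr(lastp$s, 1L, nchar(lastp$s) - shrink))
        qs <- qs - shrink; ss <- ss - shrink
      }
      p <- addseg(qs, qe, ss, se)
      if (!is.null(p)) pieces[[length(pieces) + 1L]] <- p
    }
  }
  p <- addseg(bq2[nb] + 1L, nq, bs2[nb] + 1L, ns)
  if (!is.null(p)) pieces[[length(pieces) + 1L]] <- p
  qaln <- paste(vapply(pieces, `[[`, "", "q"), collapse = "")
  saln <- paste(vapply(pieces, `[[`, "", "s"), collapse = "")
  stopifnot(nchar(qaln) == nchar(saln))
  structure(list(qaln = qaln, saln = saln,
                 score = .mingap_score(qaln, saln)),
            class = "pairAlignment")
}

#' @export
print.pairAlignment <- function(x, ...) {
  cat("pairAlignment: ", nchar(x$qaln), " columns, score ", x$score, "\n",
      sep = "")
  invisible(x)
}
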