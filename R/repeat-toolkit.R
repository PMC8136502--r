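## Repeat classification and subfamily phylogenetics: simplified,
## exhaustively testable stand-ins for the RepeatMasker / Clustal / MEGA
## steps of the original analysis chain.

.CLASSIFY_GAP_OPEN <- 1   # Biostrings parameterization: gap of length L
.CLASSIFY_GAP_EXT <- 1    # costs open + L*ext = L + 1 ("open -2, extend -1")

.age_rank <- function(a) {
  r <- match(a, c("young", "old"))
  r[is.na(r)] <- 3L
  r
}

.local_align <- function(q, s) {
  Biostrings::pairwiseAlignment(q, s, type = "local",
                                substitutionMatrix = .submat(),
                                gapOpening = .CLASSIFY_GAP_OPEN,
                                gapExtension = .CLASSIFY_GAP_EXT)
}

## divergence / occupancy / span statistics of a local alignment
.hit_stats <- function(pa, queryLen) {
  st <- .pa_strings(pa)
  qv <- strsplit(st$q, "", fixed = TRUE)[[1]]
  sv <- strsplit(st$s, "", fixed = TRUE)[[1]]
  gap <- qv == "-" | sv == "-"
  mism <- sum(!gap & qv != sv)
  gapEvents <- sum(rle(gap)$values)
  cols <- length(qv)
  qs <- Biostrings::start(Biostrings::pattern(pa))  # 1-based on query
  qe <- Biostrings::end(Biostrings::pattern(pa))
  list(divergence = (mism + gapEvents) / cols,
       occupancy = sum(qv != "-") / queryLen,
       qstart0 = qs - 1L, qend0 = qe)
}

#' Classify a sequence against a consensus library
#'
#' Locally aligns the sequence (both strands) against every library entry
#' under match +1, mismatch -1, gap open -2, gap extend -1 and returns the
#' maximal-score hit, with divergence (mismatches plus gap events per
#' aligned column; each gap counts as one event, in the spirit of
#' Kimura-style repeat divergence), occupancy (aligned query bases over
#' query length) and the 0-based half-open query span. Ties between entries
#' at equal score are broken by younger age class first, then by name.
#'
#' @param seq character or DNAString, length >= 20.
#' @param lib a \linkS4class{ConsensusLibrary}.
#' @param minScore minimum reportable alignment score (default 20, which
#'   suppresses chance hits on random background).
#' @param queryId identifier stored in the hit.
#' @return A \linkS4class{RepeatHit}, or \code{NULL} if no entry reaches
#'   \code{minScore}.
#' @export
classifySequence <- function(seq, lib, minScore = 20, queryId = "query") {
  if (length(names(lib)) == 0L) stop("empty consensus library")
  seq <- toupper(as.character(seq))
  if (nchar(seq) < 20L) stop("query sequence must be >= 20 bases")
  q <- Biostrings::DNAString(seq)
  qrc <- Biostrings::reverseComplement(q)
  entries <- names(lib)
  best <- NULL; bestKey <- NULL
  for (i in seq_along(entries)) {
    s <- lib@seqs[[i]]
    for (strand in c("+", "-")) {
      pa <- .local_align(if (strand == "+") q else qrc, s)
      sc <- Biostrings::score(pa)
      if (sc < minScore) next
      key <- c(-sc, .age_rank(lib@ageClass[[i]]))
      if (is.null(best) || key[1] < bestKey[1] ||
          (key[1] == bestKey[1] && key[2] < bestKey[2]) ||
          (key[1] == bestKey[1] && key[2] == bestKey[2] &&
           entries[i] < best$entry)) {
        best <- list(entry = entries[i], pa = pa, strand = strand, score = sc)
        bestKey <- key
      }
    }
  }
  if (is.null(best)) return(NULL)
  stats <- .hit_stats(best$pa, nchar(seq))
  if (best$strand == "-") {
    n <- nchar(seq)
    tmp <- stats
    stats$qstart0 <- n - tmp$qend0
    stats$qend0 <- n - tmp$qstart0
  }
  new("RepeatHit", queryId = queryId, subfamily = best$entry,
      qstart = as.integer(stats$qstart0), qend = as.integer(stats$qend0),
      strand = best$strand, divergence = stats$divergence,
      occupancy = stats$occupancy, score = best$score)
}

## Batched classification: score many sequences against the library in one
## pairwiseAlignment call per entry/strand, then refine only the winners.
## Returns a data.frame with one row per input sequence (NA subfamily when
## below minScore).
.classify_batch <- function(seqs, lib, minScore = 20, stats = TRUE) {
  n <- length(seqs)
  if (n == 0L)
    return(data.frame(subfamily = character(0), score = numeric(0),
                      divergence = numeric(0), occupancy = numeric(0),
                      strand = character(0)))
  dna <- Biostrings::DNAStringSet(toupper(seqs))
  rc <- Biostrings::reverseComplement(dna)
  entries <- names(lib)
  scores <- array(-Inf, dim = c(n, length(entries), 2L))
  for (i in seq_along(entries)) {
    s <- lib@seqs[[i]]
    scores[, i, 1L] <- Biostrings::pairwiseAlignment(
      dna, s, type = "local", substitutionMatrix = .submat(),
      gapOpening = .CLASSIFY_GAP_OPEN, gapExtension = .CLASSIFY_GAP_EXT,
      scoreOnly = TRUE)
    scores[, i, 2L] <- Biostrings::pairwiseAlignment(
      rc, s, type = "local", substitutionMatrix = .submat(),
      gapOpening = .CLASSIFY_GAP_OPEN, gapExtension = .CLASSIFY_GAP_EXT,
      scoreOnly = TRUE)
  }
  ageR <- .age_rank(lib@ageClass)
  out <- data.frame(subfamily = rep(NA_character_, n), score = NA_real_,
                    divergence = NA_real_, occupancy = NA_real_,
                    strand = NA_character_)
  for (j in seq_len(n)) {
    sc <- pmax(scores[j, , 1L], scores[j, , 2L])
    top <- max(sc)
    if (top < minScore) next
    cand <- which(sc == top)
    cand <- cand[order(ageR[cand], entries[cand])]
    i <- cand[1L]
    strand <- if (scores[j, i, 1L] >= scores[j, i, 2L]) "+" else "-"
    out$subfamily[j] <- entries[i]
    out$score[j] <- top
    out$strand[j] <- strand
    if (stats) {
      pa <- .local_align(if (strand == "+") dna[[j]] else rc[[j]],
                         lib@seqs[[i]])
      st <- .hit_stats(pa, nchar(seqs[j]))
      out$divergence[j] <- st$divergence
      out$occupancy[j] <- st$occupancy
    }
  }
  out
}

#' Annotate a genome with repeat hits
#'
#' Seeded scan: exact k-mer seeds shared between the genome and any library
#' consensus (both strands) define candidate windows, each window is
#' classified by local alignment, and overlapping hits are resolved in
#' favor of the higher score. The result is a non-overlapping, strand-aware
#' annotation in 1-based \link[GenomicRanges]{GRanges} coordinates.
#'
#' @param genome named character vector or \link[Biostrings]{DNAStringSet}
#'   of contigs.
#' @param lib a \linkS4class{ConsensusLibrary}.
#' @param seedLen seed k-mer length (default 12).
#' @param minScore minimum reportable hit score.
#' @return A \code{GRanges} with mcols \code{subfamily}, \code{divergence},
#'   \code{occupancy}, \code{score}.
#' @export
annotateGenome <- function(genome, lib, seedLen = 12L, minScore = 20) {
  genome <- .as_genome(genome)
  maxW <- max(Biostrings::width(lib@seqs))
  kmers <- unique(unlist(lapply(seq_along(lib@seqs), function(i) {
    s <- as.character(lib@seqs[[i]])
    src <- as.character(Biostrings::reverseComplement(lib@seqs[[i]]))
    c(substring(s, seq_len(nchar(s) - seedLen + 1L),
                seq_len(nchar(s) - seedLen + 1L) + seedLen - 1L),
      substring(src, seq_len(nchar(src) - seedLen + 1L),
                seq_len(nchar(src) - seedLen + 1L) + seedLen - 1L))
  })))
  kmers <- kmers[!grepl("N", kmers, fixed = TRUE)]
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(kmers))
  res <- list()
  for (contig in names(genome)) {
    subj <- genome[[contig]]
    hits <- Biostrings::matchPDict(pd, subj)
    starts <- unlist(lapply(hits, Biostrings::start), use.names = FALSE)
    if (length(starts) == 0L) next
    win <- IRanges::reduce(IRanges::IRanges(start = starts, width = seedLen) +
                             maxW)
    win <- IRanges::restrict(win, start = 1L, end = length(subj))
    seqs <- as.character(Biostrings::extractAt(subj, win))
    cls <- .classify_batch(seqs, lib, minScore)
    keep <- which(!is.na(cls$subfamily))
    if (length(keep) == 0L) next
    ## refine window hits to genomic spans via single classification
    rows <- lapply(keep, function(i) {
      hit <- classifySequence(seqs[i], lib, minScore)
      if (is.null(hit)) return(NULL)
      data.frame(contig = contig,
                 start = IRanges::start(win)[i] + hit@qstart,  # 1-based
                 end = IRanges::start(win)[i] + hit@qend - 1L,
                 strand = hit@strand, subfamily = hit@subfamily,
                 divergence = hit@divergence, occupancy = hit@occupancy,
                 score = hit@score)
    })
    res[[contig]] <- do.call(rbind, rows)
  }
  if (length(res) == 0L)
    return(GenomicRanges::GRanges(subfamily = character(0),
                                  divergence = numeric(0),
                                  occupancy = numeric(0), score = numeric(0)))
  df <- do.call(rbind, res)
  gr <- GenomicRanges::GRanges(df$contig,
                               IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  S4Vectors::mcols(gr) <- df[, c("subfamily", "divergence", "occupancy",
                                 "score")]
  ## higher score wins overlaps
  gr <- gr[order(-gr$score)]
  keep <- rep(TRUE, length(gr))
  ov <- GenomicRanges::findOverlaps(gr, ignore.strand = TRUE,
                                    drop.self = TRUE, drop.redundant = TRUE)
  for (h in seq_along(ov)) {
    a <- S4Vectors::queryHits(ov)[h]; b <- S4Vectors::subjectHits(ov)[h]
    if (keep[a] && keep[b]) keep[max(a, b)] <- FALSE
  }
  sort(gr[keep], ignore.strand = TRUE)
}

#' Rebuild a majority-rule consensus from aligned copies
#'
#' Each copy is pairwise-aligned to the anchor consensus; for every anchor
#' column the majority base over all aligned copies is emitted. Columns
#' where a gap is the strict majority are dropped; ties between bases are
#' resolved by the fixed order A < C < G < T, and a base always beats a tied
#' gap.
#'
#' @param copies character vector or DNAStringSet of >= 2 copy sequences.
#' @param anchor the anchor consensus sequence.
#' @return The rebuilt consensus as a single character string.
#' @export
buildConsensus <- function(copies, anchor) {
  copies <- toupper(as.character(copies))
  if (length(copies) < 2L) stop("need at least 2 copies")
  anchor <- toupper(as.character(anchor))
  La <- nchar(anchor)
  mat <- matrix("-", nrow = length(copies), ncol = La)
  for (i in seq_along(copies)) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(copies[i]), Biostrings::DNAString(anchor),
      type = "global", substitutionMatrix = .submat(),
      gapOpening = .CLASSIFY_GAP_OPEN, gapExtension = .CLASSIFY_GAP_EXT)
    st <- .pa_strings(pa)
    qv <- strsplit(st$q, "", fixed = TRUE)[[1]]
    sv <- strsplit(st$s, "", fixed = TRUE)[[1]]
    apos <- cumsum(sv != "-")
    sel <- sv != "-"
    mat[i, apos[sel]] <- qv[sel]
  }
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (j in seq_len(La)) {
    col <- mat[, j]
    cnt <- vapply(bases, function(b) sum(col == b), 0L)
    gapN <- sum(col == "-")
    bestBase <- bases[which.max(cnt)]    # ties: A < C < G < T by order
    if (gapN > max(cnt)) next            # strict gap majority: drop column
    out <- c(out, bestBase)
  }
  paste(out, collapse = "")
}

#' Pairwise p-distance matrix
#'
#' Globally aligns every pair and computes the p-distance: mismatches over
#' aligned (both-non-gap) sites, in substitutions per site.
#'
#' @param seqs named character vector or DNAStringSet of >= 2 sequences.
#' @return A symmetric numeric matrix with zero diagonal.
#' @export
pDistanceMatrix <- function(seqs) {
  nm <- names(seqs)
  seqs <- stats::setNames(toupper(as.character(seqs)), nm)
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  if (any(nchar(seqs) == 0L)) stop("empty sequence")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(seqs[i]), Biostrings::DNAString(seqs[j]),
      type = "global", substitutionMatrix = .submat(),
      gapOpening = .CLASSIFY_GAP_OPEN, gapExtension = .CLASSIFY_GAP_EXT)
    st <- .pa_strings(pa)
    qv <- strsplit(st$q, "", fixed = TRUE)[[1]]
    sv <- strsplit(st$s, "", fixed = TRUE)[[1]]
    both <- qv != "-" & sv != "-"
    d[i, j] <- d[j, i] <- sum(qv[both] != sv[both]) / sum(both)
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou-Nei neighbor joining (via \link[ape]{nj}). On additive
#' input distances the tree's path lengths reproduce the matrix exactly.
#' Negative branch lengths are clamped to zero; the total clamped deficit
#' is recorded in the \code{"clampedDeficit"} attribute.
#'
#' @param d symmetric distance matrix with >= 3 labels.
#' @return An unrooted \link[ape]{ape} \code{phylo} tree.
#' @export
njTree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("need at least 3 labels")
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("non-symmetric matrix")
  tree <- ape::nj(d)
  deficit <- -sum(pmin(tree$edge.length, 0))
  if (deficit > 0)
    message(sprintf("njTree: clamped negative branch lengths (deficit %.6g)",
                    deficit))
  tree$edge.length <- pmax(tree$edge.length, 0)
  attr(tree, "clampedDeficit") <- deficit
  tree
}

## Coerce a genome argument to a named DNAStringSet.
.as_genome <- function(genome) {
  if (is(genome, "DNAStringSet")) {
    if (is.null(names(genome)))
      names(genome) <- paste0("contig", seq_along(genome))
    return(genome)
  }
  if (is(genome, "DNAString"))
    return(Biostrings::DNAStringSet(stats::setNames(as.character(genome),
                                                    "contig1")))
  g <- stats::setNames(toupper(as.character(genome)), names(genome))
  if (is.null(names(g))) names(g) <- paste0("contig", seq_along(g))
  Biostrings::DNAStringSet(g)
}
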