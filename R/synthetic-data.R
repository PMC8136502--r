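## Seeded synthetic-data generator. One SimConfig (one seed) determines all
## outputs; each generator stage uses its own fixed offset from the master
## seed so outputs do not depend on the order in which stages are invoked.

.BASES <- c("A", "C", "G", "T")

.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

.stage_seed <- function(cfg, stage, sub = 0L) {
  ## keep well below 2^31 even for large user seeds
  (cfg@seed %% 1000000L) * 1000L + stage * 101L + sub
}

.rand_dna <- function(n) paste(sample(.BASES, n, replace = TRUE), collapse = "")

## random substitutions at a fixed per-site rate
.mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(v)) < rate)
  for (i in hit) v[i] <- sample(setdiff(.BASES, v[i]), 1L)
  paste(v, collapse = "")
}

.strip_cpg <- function(v) {
  ## remove every CG dinucleotide from a base vector (G -> A)
  repeat {
    i <- which(v[-length(v)] == "C" & v[-1] == "G")
    if (length(i) == 0L) break
    v[i + 1L] <- "A"
  }
  v
}

#' Build a synthetic subfamily consensus library
#'
#' Constructs \code{nSubfamilies} consensuses of equal length from a common
#' ancestral sequence: each subfamily carries 15 private diagnostic
#' substitutions (so any two consensuses differ at >= 10 positions), young
#' subfamilies carry 7 CpG sites and old subfamilies 1, mirroring the
#' higher CpG content of evolutionarily young SINE copies. The two fixed
#' rRNA surrogates (158 and 121 bases, the 5.8S/5S length scales) are
#' stored under reserved names.
#'
#' @param cfg a \linkS4class{SimConfig} with \code{nSubfamilies >= 2}.
#' @return A \linkS4class{ConsensusLibrary}.
#' @export
makeConsensusLibrary <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  n <- cfg@nSubfamilies
  if (n < 2L) stop("nSubfamilies must be >= 2")
  L <- cfg@consensusLength
  .with_seed(.stage_seed(cfg, 1L), {
    base <- .strip_cpg(sample(.BASES, L, replace = TRUE))
    ## candidate editable positions, spaced 2 apart, away from the ends
    slots <- seq(3L, L - 3L, by = 2L)
    nPriv <- 15L
    needed <- n * nPriv + 7L
    if (length(slots) < needed)
      stop("consensusLength too short for diagnostic construction")
    pick <- sample(slots, needed)
    priv <- split(pick[seq_len(n * nPriv)], rep(seq_len(n), each = nPriv))
    cpgYoung <- pick[n * nPriv + 1:6]
    cpgOld <- pick[n * nPriv + 7L]
    ageClass <- rep(c("young", "old"), c(ceiling(n / 2), floor(n / 2)))
    seqs <- character(n)
    for (i in seq_len(n)) {
      v <- base
      for (p in priv[[i]]) {
        cand <- setdiff(.BASES, v[p])
        ## avoid creating a CpG with either neighbour
        cand <- cand[!(cand == "G" & v[p - 1L] == "C") &
                       !(cand == "C" & v[p + 1L] == "G")]
        v[p] <- cand[1L]
      }
      sites <- if (ageClass[i] == "young") c(cpgYoung, cpgOld) else cpgOld
      for (p in sites) { v[p] <- "C"; v[p + 1L] <- "G" }
      seqs[i] <- paste(v, collapse = "")
    }
    names(seqs) <- sprintf("SF%02d", seq_len(n))
    allseqs <- c(seqs, stats::setNames(c(.RRNA_5P8S_SEQ, .RRNA_5S_SEQ),
                                       c(.RRNA_5P8S_NAME, .RRNA_5S_NAME)))
    fam <- stats::setNames(c(rep("SINE", n), "rRNA", "rRNA"), names(allseqs))
    age <- stats::setNames(c(ageClass, NA, NA), names(allseqs))
    new("ConsensusLibrary", seqs = Biostrings::DNAStringSet(allseqs),
        family = fam, ageClass = age,
        rRNANames = c(.RRNA_5P8S_NAME, .RRNA_5S_NAME))
  })
}

#' Simulate a strain genome pair with planted SINE insertions
#'
#' Both strains share an i.i.d.-uniform background and a set of shared
#' insertions; each strain additionally carries its own strain-specific
#' insertions. Every planted copy is a 5'-truncated, point-mutated
#' derivative of a subfamily consensus, flanked by a duplicated target site
#' of \code{tsdLength} bases. Breakpoints are recorded leftmost (the
#' target-site duplication makes the exact insertion point ambiguous within
#' the TSD).
#'
#' With \code{plantControls = TRUE} two strain-A negative controls are
#' added: a 110-base insertion (below the 120-bp scan floor) and a gap
#' whose repeat content occupies well under 80 percent of the gapped region.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @param lib the \linkS4class{ConsensusLibrary} built from the same config.
#' @return list with \code{genomeA}, \code{genomeB} (named
#'   \link[Biostrings]{DNAStringSet}, contig "chr1") and \code{truth}
#'   (\linkS4class{GroundTruth}).
#' @export
simulateGenomePair <- function(cfg, lib) {
  G <- cfg@genomeLength
  ilr <- cfg@insertionLengthRange
  if (G < 10L * ilr[2]) stop("genomeLength must be >= 10x max insertion length")
  t <- cfg@tsdLength
  .with_seed(.stage_seed(cfg, 2L), {
    background <- .rand_dna(G)
    nShared <- cfg@nSharedInsertions
    nSpec <- cfg@nSpecificInsertionsPerStrain
    nCtrl <- if (cfg@plantControls) 2L else 0L
    nTot <- nShared + 2L * nSpec + nCtrl
    minSep <- max(600L, ilr[2] + 300L)
    lo <- 3000L; hi <- G - 3000L
    ## jittered grid: spacing 1.5 x minSep with jitter up to 0.5 x minSep
    ## guarantees pairwise separation >= minSep
    grid <- seq(lo, hi, by = as.integer(1.5 * minSep))
    if (length(grid) < nTot)
      stop("could not place insertions without overlap after bounded retries")
    placed <- sort(sample(grid, nTot)) +
      sample.int(as.integer(0.5 * minSep), nTot, replace = TRUE)
    strain <- sample(rep(c("shared", "A", "B", "ctrl"),
                         c(nShared, nSpec, nSpec, nCtrl)))
    ctrlIdx <- which(strain == "ctrl")
    control <- rep("none", nTot)
    if (nCtrl > 0L) {
      strain[ctrlIdx] <- "A"
      control[ctrlIdx] <- c("control_short", "control_occ")
    }
    sf <- sample(sineNames(lib), nTot, replace = TRUE)
    consLen <- cfg@consensusLength
    len <- pmin(sample(seq(ilr[1], ilr[2]), nTot, replace = TRUE), consLen)
    len[control == "control_short"] <- 101L  # 101 + 9 TSD = 110-base event
    len[control == "control_occ"] <- 150L
    copySeq <- character(nTot); content <- character(nTot)
    for (i in seq_len(nTot)) {
      cons <- as.character(lib@seqs[[sf[i]]])
      copySeq[i] <- .mutate_seq(substr(cons, consLen - len[i] + 1L, consLen),
                                cfg@perCopyDivergence)
      content[i] <- if (control[i] == "control_occ")
        paste0(copySeq[i], .rand_dna(60L)) else copySeq[i]
    }
    contentLen <- nchar(content)
    events <- data.frame(
      id = sprintf("ins_%03d", seq_len(nTot)), strain = strain,
      subfamily = sf, p0 = placed - 1L, len = len,
      contentLen = contentLen, tsd = t, control = control,
      copySeq = copySeq, content = content, stringsAsFactors = FALSE)
    buildStrain <- function(which) {
      ev <- events[events$strain %in% c("shared", which), ]
      ev <- ev[order(ev$p0), ]
      off <- c(0L, cumsum(ev$contentLen + t))[seq_len(nrow(ev))]
      ## carrier coordinates (0-based): leftmost gap start and copy interval
      ev$gapStart0 <- ev$p0 + off
      ev$gapEnd0 <- ev$gapStart0 + ev$contentLen + t
      ev$copyStart0 <- ev$p0 + t + off
      ev$copyEnd0 <- ev$copyStart0 + ev$len
      pieces <- character(2L * nrow(ev) + 1L)
      prev <- 1L
      for (i in seq_len(nrow(ev))) {
        p <- ev$p0[i]
        pieces[2L * i - 1L] <- substr(background, prev, p + t)  # incl. TSD
        pieces[2L * i] <- ev$content[i]
        prev <- p + 1L  # TSD duplicated: resume at p+1 (1-based)
      }
      pieces[2L * nrow(ev) + 1L] <- substr(background, prev, G)
      list(seq = paste(pieces, collapse = ""), ev = ev)
    }
    A <- buildStrain("A"); B <- buildStrain("B")
    for (cl in c("gapStart0", "gapEnd0", "copyStart0", "copyEnd0")) {
      events[[paste0(cl, "_A")]] <- A$ev[[cl]][match(events$id, A$ev$id)]
      events[[paste0(cl, "_B")]] <- B$ev[[cl]][match(events$id, B$ev$id)]
    }
    ## breakpoint position in the non-carrier strain's coordinates
    offIn <- function(ev, p) sum(ev$contentLen[ev$p0 < p] + t)
    events$bpOther0 <- NA_integer_
    for (i in seq_len(nTot)) {
      if (events$strain[i] == "A")
        events$bpOther0[i] <- events$p0[i] + offIn(B$ev, events$p0[i])
      else if (events$strain[i] == "B")
        events$bpOther0[i] <- events$p0[i] + offIn(A$ev, events$p0[i])
    }
    events$locus <- ifelse(!is.na(events$copyStart0_A) &
                             events$control == "none",
                           sprintf("locus_%03d", seq_len(nTot)), NA)
    truth <- new("GroundTruth", insertions = events,
                 locusExpression = data.frame(),
                 locusMethylation = data.frame(),
                 peakTruth = data.frame(), snpTable = data.frame())
    list(genomeA = Biostrings::DNAStringSet(c(chr1 = A$seq)),
         genomeB = Biostrings::DNAStringSet(c(chr1 = B$seq)),
         truth = truth)
  })
}

#' Ground-truth repeat loci of one strain as GRanges
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param strain "A" or "B".
#' @return 1-based \code{GRanges} of the planted copies carried by the
#'   strain (controls excluded), named by locus id, with subfamily mcol.
#' @export
truthLoci <- function(truth, strain = "A") {
  ev <- truth@insertions
  col <- paste0("copyStart0_", strain)
  ev <- ev[!is.na(ev[[col]]) & ev$control == "none", ]
  gr <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = ev[[col]] + 1L,
                     end = ev[[paste0("copyEnd0_", strain)]]))
  names(gr) <- ifelse(is.na(ev$locus), ev$id, ev$locus)
  gr$subfamily <- ev$subfamily
  gr$id <- ev$id
  gr
}

## Expected expression shares: power-law base abundance times the
## methylation multiplier (if simulateMethylation has run), scaled to the
## non-rRNA read fraction.
.ensure_expression <- function(cfg, truth) {
  if (nrow(truth@locusExpression) > 0L) return(truth)
  ev <- truth@insertions
  loci <- ev$locus[!is.na(ev$locus)]
  .with_seed(.stage_seed(cfg, 4L), {
    ranks <- sample(seq_along(loci))
    base <- ranks^(-cfg@zipfExponent)
    mult <- rep(1, length(loci))
    if (nrow(truth@locusMethylation) > 0L) {
      m <- match(loci, truth@locusMethylation$locus)
      mult <- truth@locusMethylation$multiplier[m]
    }
    share <- base * mult
    share <- share / sum(share) * (1 - cfg@frac5p8S - cfg@frac5S)
    truth@locusExpression <- data.frame(
      locus = loci, rank = ranks, share = share,
      chemistry = "triP", stringsAsFactors = FALSE)
  })
  truth
}

#' Simulate per-CpG methylation calls with expression coupling
#'
#' Draws a true methylation level per planted locus and plants the
#' methylation-expression coupling the downstream analysis must recover:
#' for CpG-rich copies (>= 3 CpG sites) the expected expression multiplier
#' is \code{exp(-strength * level)}, strictly decreasing in the planted
#' level; for CpG-poor copies (<= 2 sites) the exponent is attenuated by a
#' factor 4, so methylation has much less effect. Per-CpG counts are
#' binomial at Poisson-distributed depth.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @param truth the \linkS4class{GroundTruth} from
#'   \code{\link{simulateGenomePair}}.
#' @return list with \code{calls} (data.frame contig, pos0, methylated,
#'   total, locus) and the updated \code{truth}.
#' @export
simulateMethylation <- function(cfg, truth) {
  stopifnot(cfg@methCouplingStrength >= 0)
  ev <- truth@insertions
  ev <- ev[!is.na(ev$locus), ]
  .with_seed(.stage_seed(cfg, 3L), {
    nC <- vapply(ev$copySeq, function(s)
      length(gregexpr("CG", s, fixed = TRUE)[[1]][
        gregexpr("CG", s, fixed = TRUE)[[1]] > 0]), 0L, USE.NAMES = FALSE)
    level <- stats::runif(nrow(ev))
    w <- ifelse(nC >= 3L, 1, 0.25)
    mult <- exp(-cfg@methCouplingStrength * w * level)
    truth@locusMethylation <- data.frame(
      locus = ev$locus, nCpG = nC, trueLevel = level, multiplier = mult,
      stringsAsFactors = FALSE)
    rows <- lapply(seq_len(nrow(ev)), function(i) {
      off <- gregexpr("CG", ev$copySeq[i], fixed = TRUE)[[1]]
      off <- off[off > 0]
      if (length(off) == 0L) return(NULL)
      total <- stats::rpois(length(off), cfg@cpgDepth)
      data.frame(contig = "chr1",
                 pos0 = ev$copyStart0_A[i] + off - 1L,
                 methylated = stats::rbinom(length(off), total, level[i]),
                 total = total, locus = ev$locus[i],
                 stringsAsFactors = FALSE)
    })
    calls <- do.call(rbind, rows)
    if (is.null(calls))
      calls <- data.frame(contig = character(0), pos0 = integer(0),
                          methylated = integer(0), total = integer(0),
                          locus = character(0))
    list(calls = calls, truth = truth)
  })
}

#' Simulate treated and untreated melRNA-seq libraries
#'
#' Reads are full transcripts (the planted copy, or an rRNA surrogate) plus
#' the 3' adaptor; a \code{fracDegraded} share of molecules is 3'-truncated
#' and lacks the adaptor. 5' chemistry is a per-molecule label: the 5.8S
#' surrogate carries a ligatable monophosphate and enters both libraries;
#' Pol III-class molecules (SINE copies and the 5S surrogate) carry a
#' triphosphate and enter the untreated library only at the leak rate
#' \code{untreatedPol3Inclusion}, but always after TAP/RppH treatment.
#' Locus abundances follow the configured power law times the methylation
#' multiplier.
#'
#' @param cfg a \linkS4class{SimConfig}; \code{adaptor3} must be >= 8 bases.
#' @param genome unused placeholder for the carrier genome (reads are
#'   constructed from the recorded copy sequences).
#' @param truth the \linkS4class{GroundTruth}; methylation truth, if
#'   present, modulates expression.
#' @param replicate integer replicate index; the expression truth is fixed,
#'   only the sampling noise differs between replicates.
#' @return list with \code{treated}, \code{untreated} (named character
#'   vectors of read sequences), \code{classTruth} (true class counts per
#'   library) and the updated \code{truth}.
#' @export
simulateMelReads <- function(cfg, genome, truth, replicate = 1L) {
  if (nchar(cfg@adaptor3) < 8L)
    stop("adaptor3 shorter than 8 bases cannot be anchored")
  truth <- .ensure_expression(cfg, truth)
  expr <- truth@locusExpression
  ev <- truth@insertions
  transcripts <- c(stats::setNames(ev$copySeq[match(expr$locus, ev$locus)],
                                   expr$locus),
                   stats::setNames(c(.RRNA_5P8S_SEQ, .RRNA_5S_SEQ),
                                   c(.RRNA_5P8S_NAME, .RRNA_5S_NAME)))
  classes <- c(expr$locus, .RRNA_5P8S_NAME, .RRNA_5S_NAME)
  probs <- c(expr$share, cfg@frac5p8S, cfg@frac5S)
  monoP <- classes == .RRNA_5P8S_NAME
  .with_seed(.stage_seed(cfg, 5L, sub = 131L * as.integer(replicate)), {
    makeLib <- function(n, treated) {
      if (n == 0L) return(stats::setNames(character(0), character(0)))
      idx <- sample(seq_along(classes), n, replace = TRUE, prob = probs)
      if (!treated) {
        inc <- monoP[idx] |
          (stats::runif(n) < cfg@untreatedPol3Inclusion)
        idx <- idx[inc]
      }
      if (length(idx) == 0L) return(stats::setNames(character(0), character(0)))
      tr <- transcripts[idx]
      degraded <- stats::runif(length(idx)) < cfg@fracDegraded
      reads <- character(length(idx))
      full <- !degraded
      reads[full] <- paste0(tr[full], cfg@adaptor3)
      if (any(degraded)) {
        cut <- sample(5:50, sum(degraded), replace = TRUE)
        newlen <- pmax(15L, nchar(tr[degraded]) - cut)
        reads[degraded] <- substr(tr[degraded], 1L, newlen)
      }
      names(reads) <- sprintf("r%07d|%s|%s", seq_along(reads), classes[idx],
                              ifelse(degraded, "deg", "full"))
      attr(reads, "classCounts") <- table(factor(classes[idx],
                                                 levels = classes))
      reads
    }
    treated <- makeLib(cfg@nReads, TRUE)
    untreated <- makeLib(cfg@nReads, FALSE)
    list(treated = treated, untreated = untreated,
         classTruth = list(treated = attr(treated, "classCounts"),
                           untreated = attr(untreated, "classCounts")),
         truth = truth)
  })
}

#' Simulate ChIP-seq peaks and F1 allelic SNP counts
#'
#' A configurable fraction of peaks is boundary-anchored: in the
#' insertion-carrying strain (A) the peak's right edge coincides exactly
#' with the leftmost breakpoint of a planted strain-A-specific insertion,
#' while in the insertion-free strain (B) the corresponding peak extends
#' \code{peakExtension} bases beyond the breakpoint. Per-SNP allelic read
#' counts inside that extension region are biased by \code{allelicFold}
#' toward the insertion-free (B) allele; elsewhere they are balanced.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @param genomeA,genomeB the strain genomes (for length bookkeeping).
#' @param truth the \linkS4class{GroundTruth}.
#' @return list with \code{peaksA}, \code{peaksB} (1-based \code{GRanges}
#'   with \code{summit0} mcol, 0-based), \code{snpCounts} (data.frame
#'   contig, pos0, countA, countB, region_label) and updated \code{truth}.
#' @export
simulatePeaksAndAllelics <- function(cfg, genomeA, genomeB, truth) {
  stopifnot(cfg@fracBoundaryAnchored >= 0, cfg@fracBoundaryAnchored <= 1)
  ev <- truth@insertions
  cand <- ev[ev$strain == "A" & ev$control == "none", ]
  nAnchor <- round(cfg@fracBoundaryAnchored * cfg@peakCount)
  if (nAnchor > 0L && nrow(cand) == 0L)
    stop("no planted strain-specific insertion available to anchor peaks")
  nAnchor <- min(nAnchor, nrow(cand))
  G <- cfg@genomeLength
  lenA <- Biostrings::width(genomeA)[1]
  lenB <- Biostrings::width(genomeB)[1]
  .with_seed(.stage_seed(cfg, 6L), {
    anchors <- cand[sample(nrow(cand), nAnchor), , drop = FALSE]
    W <- sample(1000:2000, cfg@peakCount, replace = TRUE)
    ext <- cfg@peakExtension
    peakRows <- list()
    for (i in seq_len(nAnchor)) {
      bpA <- anchors$gapStart0_A[i]          # carrier coords, leftmost
      bpB <- anchors$bpOther0[i]             # free-strain coords
      peakRows[[i]] <- data.frame(
        peak = sprintf("peak_%03d", i), anchored = TRUE,
        insertionId = anchors$id[i], p0 = anchors$p0[i],
        startA0 = max(0L, bpA - W[i]), endA0 = bpA,
        startB0 = max(0L, bpB - W[i]), endB0 = min(lenB, bpB + ext),
        stringsAsFactors = FALSE)
    }
    ## non-anchored peaks on insertion-free background
    allp <- ev$p0
    j <- nAnchor
    guard <- 0L
    while (j < cfg@peakCount && guard < 10000L) {
      guard <- guard + 1L
      q <- sample(5000:(G - 5000), 1L)
      w <- W[j + 1L]
      if (any(allp > q - w - 500L & allp < q + w + 500L)) next
      j <- j + 1L
      offA <- sum(ev$contentLen[ev$strain %in% c("shared", "A") & ev$p0 < q] +
                    cfg@tsdLength)
      offB <- sum(ev$contentLen[ev$strain %in% c("shared", "B") & ev$p0 < q] +
                    cfg@tsdLength)
      peakRows[[j]] <- data.frame(
        peak = sprintf("peak_%03d", j), anchored = FALSE,
        insertionId = NA_character_, p0 = q,
        startA0 = q - w + offA, endA0 = q + offA,
        startB0 = q - w + offB, endB0 = q + offB,
        stringsAsFactors = FALSE)
    }
    pt <- do.call(rbind, peakRows)
    mkGR <- function(s0, e0, maxLen) {
      gr <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(start = s0 + 1L, end = pmin(e0, maxLen)))
      names(gr) <- pt$peak
      gr$name <- pt$peak
      gr$anchored <- pt$anchored
      gr$summit0 <- as.integer(floor((s0 + e0) / 2))
      gr
    }
    peaksA <- mkGR(pt$startA0, pt$endA0, lenA)
    peaksB <- mkGR(pt$startB0, pt$endB0, lenB)
    truth@peakTruth <- pt
    ## SNPs on the shared background, reported in strain-A coordinates
    nSnp <- stats::rpois(1L, cfg@snpDensity * G)
    snpBg <- sort(sample(seq_len(G - 1L), min(nSnp, G - 1L)))
    offA <- vapply(snpBg, function(q)
      sum(ev$contentLen[ev$strain %in% c("shared", "A") & ev$p0 < q] +
            cfg@tsdLength), 0)
    inExt <- rep(FALSE, length(snpBg))
    for (i in seq_len(nAnchor)) {
      p <- anchors$p0[i]
      inExt <- inExt | (snpBg >= p & snpBg < p + ext)
    }
    pB <- ifelse(inExt, cfg@allelicFold / (cfg@allelicFold + 1), 0.5)
    total <- stats::rpois(length(snpBg), cfg@snpReadDepth)
    countB <- stats::rbinom(length(snpBg), total, pB)
    snp <- data.frame(contig = "chr1", pos0 = snpBg + offA,
                      countA = total - countB, countB = countB,
                      region_label = ifelse(inExt, "extension", "background"),
                      stringsAsFactors = FALSE)
    seqA <- as.character(genomeA[[1]])
    alleleA <- substring(seqA, snpBg + offA + 1L, snpBg + offA + 1L)
    alleleB <- vapply(alleleA, function(b) sample(setdiff(.BASES, b), 1L),
                      "", USE.NAMES = FALSE)
    truth@snpTable <- data.frame(
      pos0 = snpBg + offA, bgPos0 = snpBg, alleleA = alleleA,
      alleleB = alleleB,
      region_label = ifelse(inExt, "extension", "background"),
      stringsAsFactors = FALSE)
    list(peaksA = peaksA, peaksB = peaksB, snpCounts = snp, truth = truth)
  })
}

#' Simulate allele-resolved coverage profiles across a planted boundary
#'
#' For one boundary-anchored peak, emits binned read-coverage profiles of
#' the two alleles on a common axis (strain-background coordinates) that
#' spans the insertion breakpoint: the carrier allele's coverage plateau
#' ends at the breakpoint, the free allele's plateau extends
#' \code{peakExtension} bases beyond it. Bin counts are Poisson around the
#' plateau depth.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @param truth \linkS4class{GroundTruth} with peak truth filled in.
#' @param peakIndex which anchored peak to profile (default first).
#' @param bin bin width in bases.
#' @param depth plateau read depth per bin.
#' @return list with \code{profileA}, \code{profileB} (data.frames with
#'   \code{binStart}, \code{coverage}), \code{breakpoint0} and \code{bin}.
#' @export
simulateAllelicCoverage <- function(cfg, truth, peakIndex = 1L, bin = 100L,
                                    depth = 30) {
  pt <- truth@peakTruth
  pt <- pt[pt$anchored, , drop = FALSE]
  if (nrow(pt) < peakIndex) stop("no such anchored peak")
  pk <- pt[peakIndex, ]
  bp <- pk$p0                # background coords; A peak is [bp - W, bp)
  W <- pk$endA0 - pk$startA0
  ext <- cfg@peakExtension
  .with_seed(.stage_seed(cfg, 7L, sub = peakIndex), {
    lo <- bp - (ceiling((W + 1000) / bin)) * bin
    hi <- bp + (ceiling((ext + 1000) / bin)) * bin
    binStart <- seq(lo, hi - bin, by = bin)
    insideA <- binStart >= bp - W & binStart + bin <= bp
    insideB <- binStart >= bp - W & binStart + bin <= bp + ext
    profA <- data.frame(binStart = binStart,
                        coverage = stats::rpois(length(binStart),
                                                ifelse(insideA, depth, 0.2)))
    profB <- data.frame(binStart = binStart,
                        coverage = stats::rpois(length(binStart),
                                                ifelse(insideB, depth, 0.2)))
    list(profileA = profA, profileB = profB, breakpoint0 = bp, bin = bin)
  })
}
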