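#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

## Reserved names for the two rRNA internal-control surrogates carried by
## every consensus library. The sequences are fixed arbitrary 158-nt (5.8S
## scale) and 121-nt (5S scale) strings so that libraries built under
## different seeds still agree on the controls.
.RRNA_5P8S_NAME <- "rRNA_5.8S"
.RRNA_5S_NAME <- "rRNA_5S"
.RRNA_5P8S_SEQ <- paste0(
  "TAATGAGTTTTACCTCTCGGAAAGCTACTCTCTCGGAGCCGCGCGACTGTATTACTACTTAAACCAGT",
  "CGACCGCACAGCAAACATATTTTGTCTGCCTTAACATACGCATAGGGCTTATCTCCTCCCCAGGAGGA",
  "CTTTCGACGGGCAGTCTAGGTC")
.RRNA_5S_SEQ <- paste0(
  "TGTCCTGCAATTTTGGACGTCTACGCATTTCTTCTCTAAAAGTATAGACATCGCTACGACGCACGCGC",
  "TGACACCAAGTGCATACTCCAAAACCGGCTCCCTGTTGGCTTACCAGCACTTG")

#' Simulation configuration
#'
#' An S4 container for every tunable of the synthetic-data generator. One
#' \code{SimConfig} (including its seed) fully determines all generated
#' inputs: genomes, reads, methylation calls, peaks, and allelic counts.
#'
#' @slot seed integer, master seed for all stochastic stages.
#' @slot genomeLength integer, background genome length in bases.
#' @slot nSubfamilies integer, number of SINE subfamily consensuses (>= 2).
#' @slot consensusLength integer, consensus length in bases (default 190,
#'   the B2 RNA length scale).
#' @slot perCopyDivergence numeric, per-site substitution probability applied
#'   to each planted copy.
#' @slot nSharedInsertions integer, insertions present in both strains.
#' @slot nSpecificInsertionsPerStrain integer, strain-private insertions.
#' @slot insertionLengthRange integer(2), planted copy length range in bases
#'   (draws above \code{consensusLength} are clamped; copies are
#'   5'-truncations of the consensus).
#' @slot tsdLength integer, target-site-duplication length in bases.
#' @slot zipfExponent numeric, exponent of the power-law locus expression.
#' @slot nReads integer, reads in the treated library.
#' @slot frac5p8S,frac5S,fracDegraded numeric fractions in [0,1]: expected
#'   5.8S-surrogate, 5S-surrogate, and degraded (adaptor-less) read shares.
#' @slot adaptor3 character, 3' adaptor sequence appended to full-length
#'   reads (>= 8 bases).
#' @slot methCouplingStrength numeric >= 0, strength of the negative
#'   methylation-expression coupling for CpG-rich copies.
#' @slot peakCount integer, number of simulated ChIP-seq peaks.
#' @slot fracBoundaryAnchored numeric fraction of peak edges anchored at a
#'   planted strain-specific insertion breakpoint.
#' @slot allelicFold numeric, fold bias toward the insertion-free allele in
#'   the extension region.
#' @slot snpDensity numeric, per-base SNP rate on the shared background.
#' @slot cpgDepth numeric, mean sequencing depth per CpG site.
#' @slot untreatedPol3Inclusion numeric, probability that a 5'-triphosphate
#'   (Pol III) molecule enters the TAP-untreated library.
#' @slot peakExtension integer, bases by which the insertion-free allele's
#'   peak extends beyond the breakpoint.
#' @slot snpReadDepth numeric, mean allelic read depth per SNP.
#' @slot plantControls logical, whether to plant the two negative-control
#'   events (a 110-bp short insertion and a low-occupancy gap).
#'
#' @export
setClass("SimConfig", representation(
  seed = "integer",
  genomeLength = "integer",
  nSubfamilies = "integer",
  consensusLength = "integer",
  perCopyDivergence = "numeric",
  nSharedInsertions = "integer",
  nSpecificInsertionsPerStrain = "integer",
  insertionLengthRange = "integer",
  tsdLength = "integer",
  zipfExponent = "numeric",
  nReads = "integer",
  frac5p8S = "numeric",
  frac5S = "numeric",
  fracDegraded = "numeric",
  adaptor3 = "character",
  methCouplingStrength = "numeric",
  peakCount = "integer",
  fracBoundaryAnchored = "numeric",
  allelicFold = "numeric",
  snpDensity = "numeric",
  cpgDepth = "numeric",
  untreatedPol3Inclusion = "numeric",
  peakExtension = "integer",
  snpReadDepth = "numeric",
  plantControls = "logical"
))

setValidity("SimConfig", function(object) {
  msgs <- character()
  fr <- c(object@frac5p8S, object@frac5S, object@fracDegraded,
          object@fracBoundaryAnchored, object@untreatedPol3Inclusion)
  if (any(fr < 0 | fr > 1)) msgs <- c(msgs, "all fractions must lie in [0, 1]")
  if (object@frac5p8S + object@frac5S > 1)
    msgs <- c(msgs, "frac5p8S + frac5S must not exceed 1")
  ilr <- object@insertionLengthRange
  if (length(ilr) != 2L || ilr[1] > ilr[2] || ilr[1] < 1L ||
      ilr[2] > object@genomeLength)
    msgs <- c(msgs, "insertionLengthRange must be within [1, genomeLength]")
  if (object@zipfExponent <= 0) msgs <- c(msgs, "zipfExponent must be > 0")
  if (object@nSubfamilies < 2L) msgs <- c(msgs, "nSubfamilies must be >= 2")
  if (object@methCouplingStrength < 0)
    msgs <- c(msgs, "methCouplingStrength must be >= 0")
  if (object@allelicFold <= 0) msgs <- c(msgs, "allelicFold must be > 0")
  if (object@perCopyDivergence < 0 || object@perCopyDivergence > 1)
    msgs <- c(msgs, "perCopyDivergence must be in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Create a simulation configuration
#'
#' Defaults reflect the study conditions the generator emulates: a 190-base
#' consensus scale, 120-300 bp insertions, a 9-bp target-site duplication, a
#' power-law (Zipf, exponent 1) locus expression profile, a 0.1x leak of
#' Pol III transcripts into the untreated library (so the expected
#' treated/untreated enrichment of the 5S surrogate is about 10-20-fold, the
#' magnitude reported for TAP treatment), and a 6-fold allelic bias beyond
#' the planted boundary insertion.
#'
#' @param seed integer master seed.
#' @param genomeLength,nSubfamilies,consensusLength,perCopyDivergence see slots.
#' @param nSharedInsertions,nSpecificInsertionsPerStrain see slots.
#' @param insertionLengthRange,tsdLength,zipfExponent,nReads see slots.
#' @param frac5p8S,frac5S,fracDegraded,adaptor3,methCouplingStrength see slots.
#' @param peakCount,fracBoundaryAnchored,allelicFold,snpDensity see slots.
#' @param cpgDepth,untreatedPol3Inclusion,peakExtension,snpReadDepth see slots.
#' @param plantControls see slots.
#' @return A validated \linkS4class{SimConfig}.
#' @examples
#' cfg <- simConfig(seed = 1, genomeLength = 50000L)
#' @export
simConfig <- function(seed = 1L,
                      genomeLength = 500000L,
                      nSubfamilies = 4L,
                      consensusLength = 190L,
                      perCopyDivergence = 0.02,
                      nSharedInsertions = 30L,
                      nSpecificInsertionsPerStrain = 50L,
                      insertionLengthRange = c(120L, 300L),
                      tsdLength = 9L,
                      zipfExponent = 1,
                      nReads = 200000L,
                      frac5p8S = 0.2,
                      frac5S = 0.02,
                      fracDegraded = 0.3,
                      adaptor3 = "AGATCGGAAGAGCACACGTC",
                      methCouplingStrength = 5,
                      peakCount = 40L,
                      fracBoundaryAnchored = 0.5,
                      allelicFold = 6,
                      snpDensity = 0.002,
                      cpgDepth = 30,
                      untreatedPol3Inclusion = 0.05,
                      peakExtension = 1500L,
                      snpReadDepth = 40,
                      plantControls = FALSE) {
  new("SimConfig",
      seed = as.integer(seed), genomeLength = as.integer(genomeLength),
      nSubfamilies = as.integer(nSubfamilies),
      consensusLength = as.integer(consensusLength),
      perCopyDivergence = perCopyDivergence,
      nSharedInsertions = as.integer(nSharedInsertions),
      nSpecificInsertionsPerStrain = as.integer(nSpecificInsertionsPerStrain),
      insertionLengthRange = as.integer(insertionLengthRange),
      tsdLength = as.integer(tsdLength), zipfExponent = zipfExponent,
      nReads = as.integer(nReads), frac5p8S = frac5p8S, frac5S = frac5S,
      fracDegraded = fracDegraded, adaptor3 = toupper(adaptor3),
      methCouplingStrength = methCouplingStrength,
      peakCount = as.integer(peakCount),
      fracBoundaryAnchored = fracBoundaryAnchored, allelicFold = allelicFold,
      snpDensity = snpDensity, cpgDepth = cpgDepth,
      untreatedPol3Inclusion = untreatedPol3Inclusion,
      peakExtension = as.integer(peakExtension), snpReadDepth = snpReadDepth,
      plantControls = plantControls)
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig (seed ", object@seed, ")\n", sep = "")
  cat("  genome: ", object@genomeLength, " bp, ", object@nSubfamilies,
      " subfamilies, consensus ", object@consensusLength, " bp\n", sep = "")
  cat("  insertions: ", object@nSharedInsertions, " shared + 2 x ",
      object@nSpecificInsertionsPerStrain, " specific, ",
      object@insertionLengthRange[1], "-", object@insertionLengthRange[2],
      " bp, TSD ", object@tsdLength, " bp, divergence ",
      object@perCopyDivergence, "\n", sep = "")
  cat("  reads: ", object@nReads, " (5.8S ", object@frac5p8S, ", 5S ",
      object@frac5S, ", degraded ", object@fracDegraded, ")\n", sep = "")
  cat("  peaks: ", object@peakCount, " (", object@fracBoundaryAnchored,
      " boundary-anchored), allelic fold ", object@allelicFold, "\n", sep = "")
})

#' Repeat subfamily consensus library
#'
#' Named consensus sequences, one per subfamily, with the family and age
#' class of each entry and the reserved names of the two rRNA internal
#' control surrogates. Sequences are stored as a named
#' \link[Biostrings]{DNAStringSet}.
#'
#' @slot seqs \link[Biostrings]{DNAStringSet} of consensus sequences.
#' @slot family named character, family of each entry (e.g. "B2", "rRNA").
#' @slot ageClass named character, "young", "old" or NA per entry.
#' @slot rRNANames character, reserved entry names of the rRNA surrogates.
#' @export
setClass("ConsensusLibrary", representation(
  seqs = "DNAStringSet",
  family = "character",
  ageClass = "character",
  rRNANames = "character"
))

setValidity("ConsensusLibrary", function(object) {
  msgs <- character()
  nm <- names(object@seqs)
  if (length(object@seqs) > 0L) {
    if (is.null(nm) || anyDuplicated(nm))
      msgs <- c(msgs, "entry names must be unique")
    if (any(Biostrings::width(object@seqs) == 0L))
      msgs <- c(msgs, "sequences must be non-empty")
    freq <- Biostrings::alphabetFrequency(object@seqs)
    bad <- rowSums(freq[, !colnames(freq) %in% c("A", "C", "G", "T", "N"),
                        drop = FALSE])
    if (any(bad > 0)) msgs <- c(msgs, "alphabet must be ACGTN")
    if (!all(names(object@family) == nm) ||
        !all(names(object@ageClass) == nm))
      msgs <- c(msgs, "family and ageClass must be named like seqs")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn ConsensusLibrary-class entry names.
#' @param x,object a \code{ConsensusLibrary}.
#' @export
setMethod("names", "ConsensusLibrary", function(x) names(x@seqs))

#' Accessors for ConsensusLibrary
#'
#' @param x a \linkS4class{ConsensusLibrary}.
#' @return \code{librarySequences}: the \link[Biostrings]{DNAStringSet};
#'   \code{libraryFamilies}, \code{libraryAgeClasses}: named character;
#'   \code{sineNames}: names of the non-rRNA (SINE) entries.
#' @export
librarySequences <- function(x) x@seqs

#' @rdname librarySequences
#' @export
libraryFamilies <- function(x) x@family

#' @rdname librarySequences
#' @export
libraryAgeClasses <- function(x) x@ageClass

#' @rdname librarySequences
#' @export
sineNames <- function(x) setdiff(names(x@seqs), x@rRNANames)

setMethod("show", "ConsensusLibrary", function(object) {
  cat("ConsensusLibrary with", length(object@seqs), "entries",
      sprintf("(%d SINE + %d rRNA surrogate)\n",
              length(sineNames(object)), length(object@rRNANames)))
  df <- data.frame(width = Biostrings::width(object@seqs),
                   family = unname(object@family),
                   ageClass = unname(object@ageClass),
                   row.names = names(object@seqs))
  print(df)
})

#' Ground truth of a synthetic run
#'
#' Book-keeping for every planted feature: insertions (with carrier-strain
#' coordinates and breakpoints), per-locus expected expression shares,
#' per-locus true methylation levels, peak anchoring truth, and the SNP
#' table. Filled progressively by the \code{simulate*} functions.
#'
#' @slot insertions data.frame of planted insertions.
#' @slot locusExpression data.frame of per-locus expected transcript shares.
#' @slot locusMethylation data.frame of per-locus true methylation levels.
#' @slot peakTruth data.frame of peaks with boundary-anchoring truth.
#' @slot snpTable data.frame of planted SNPs.
#' @export
setClass("GroundTruth", representation(
  insertions = "data.frame",
  locusExpression = "data.frame",
  locusMethylation = "data.frame",
  peakTruth = "data.frame",
  snpTable = "data.frame"
))

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:\n")
  cat("  insertions:      ", nrow(object@insertions), "\n")
  cat("  locusExpression: ", nrow(object@locusExpression), "\n")
  cat("  locusMethylation:", nrow(object@locusMethylation), "\n")
  cat("  peakTruth:       ", nrow(object@peakTruth), "\n")
  cat("  snpTable:        ", nrow(object@snpTable), "\n")
})

#' @describeIn GroundTruth-class planted insertion table.
#' @param x a \code{GroundTruth}.
#' @export
truthInsertions <- function(x) x@insertions

#' @describeIn GroundTruth-class per-locus expected expression shares.
#' @export
truthExpression <- function(x) x@locusExpression

#' @describeIn GroundTruth-class per-locus true methylation levels.
#' @export
truthMethylation <- function(x) x@locusMethylation

#' @describeIn GroundTruth-class peak anchoring truth.
#' @export
truthPeaks <- function(x) x@peakTruth

#' @describeIn GroundTruth-class planted SNP table.
#' @export
truthSnps <- function(x) x@snpTable

#' A classified repeat hit
#'
#' The best local alignment of a query sequence against a consensus library:
#' subfamily, query span (0-based half-open), strand, divergence
#' (mismatches plus gap events per aligned column), occupancy (aligned query
#' bases over query length) and alignment score.
#'
#' @slot queryId character.
#' @slot subfamily character, winning library entry.
#' @slot qstart,qend integer, 0-based half-open span on the query.
#' @slot strand character, "+" or "-".
#' @slot divergence numeric >= 0.
#' @slot occupancy numeric in [0, 1].
#' @slot score numeric, alignment score.
#' @export
setClass("RepeatHit", representation(
  queryId = "character", subfamily = "character",
  qstart = "integer", qend = "integer", strand = "character",
  divergence = "numeric", occupancy = "numeric", score = "numeric"
))

setValidity("RepeatHit", function(object) {
  msgs <- character()
  if (object@divergence < 0) msgs <- c(msgs, "divergence must be >= 0")
  if (object@occupancy < 0 || object@occupancy > 1)
    msgs <- c(msgs, "occupancy must be in [0, 1]")
  if (object@qstart < 0 || object@qend < object@qstart)
    msgs <- c(msgs, "invalid query span")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "RepeatHit", function(object) {
  cat(sprintf(
    "RepeatHit %s -> %s [%d, %d) strand %s score %.0f div %.3f occ %.3f\n",
    object@queryId, object@subfamily, object@qstart, object@qend,
    object@strand, object@score, object@divergence, object@occupancy))
})

#' Repeat density profile around peak boundaries
#'
#' Aggregated repeat-class base coverage in fixed-width bins of signed
#' distance from ChIP-seq peak boundaries (negative = outside the peak,
#' positive = inside; peak end boundaries are mirrored so that "inside" is
#' always positive), plus the genome-wide background density and per-bin
#' enrichment.
#'
#' @slot profile data.frame with binStart, binCenter, density, enrichment.
#' @slot background numeric, genome-wide covered fraction of the class.
#' @slot window,bin integer, window half-width and bin width in bases.
#' @slot nBoundaries integer, number of boundaries aggregated.
#' @export
setClass("BoundaryProfile", representation(
  profile = "data.frame", background = "numeric",
  window = "integer", bin = "integer", nBoundaries = "integer"
))

setMethod("show", "BoundaryProfile", function(object) {
  cat(sprintf(
    "BoundaryProfile: window +/-%d bp, bin %d bp, %d boundaries, background %.4f\n",
    object@window, object@bin, object@nBoundaries, object@background))
  i <- which.max(object@profile$enrichment)
  cat(sprintf("  max enrichment %.2f at bin [%d, %d)\n",
              object@profile$enrichment[i], object@profile$binStart[i],
              object@profile$binStart[i] + object@bin))
})

#' @describeIn BoundaryProfile-class per-bin profile table.
#' @param x a \code{BoundaryProfile}.
#' @export
profileTable <- function(x) x@profile

#' @describeIn BoundaryProfile-class genome-wide background density.
#' @export
profileBackground <- function(x) x@background
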