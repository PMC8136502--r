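## End-to-end orchestration of the synthetic run, with per-stage logging,
## recovery metrics against the ground truth, and a JSON run report.

#' Compare insertion calls against the planted truth
#'
#' Matches each strain-specific planted insertion (controls excluded) to a
#' call of the same carrier whose leftmost breakpoint lies within
#' \code{tol} bases of the planted one.
#'
#' @param calls data.frame from \code{\link{scanPolymorphisms}}.
#' @param truth a \linkS4class{GroundTruth}.
#' @param tol breakpoint tolerance in bases (default 5).
#' @return list: sensitivity, precision, nTruth, nCalls, nMatched,
#'   breakpointErrors (matched absolute errors), controlCalled (whether any
#'   planted negative control was called).
#' @export
evaluateScan <- function(calls, truth, tol = 5L) {
  ev <- truth@insertions
  spec <- ev[ev$strain %in% c("A", "B") & ev$control == "none", ]
  matchedCall <- rep(FALSE, nrow(calls))
  errors <- numeric(0)
  nMatched <- 0L
  for (i in seq_len(nrow(spec))) {
    bp <- if (spec$strain[i] == "A") spec$gapStart0_A[i] else
      spec$gapStart0_B[i]
    j <- which(!matchedCall & calls$carrier == spec$strain[i] &
                 abs(calls$gapStart0 - bp) <= tol)
    if (length(j)) {
      j <- j[which.min(abs(calls$gapStart0[j] - bp))]
      matchedCall[j] <- TRUE
      nMatched <- nMatched + 1L
      errors <- c(errors, abs(calls$gapStart0[j] - bp))
    }
  }
  ctrl <- ev[ev$control != "none", ]
  ctrlCalled <- FALSE
  for (i in seq_len(nrow(ctrl))) {
    bp <- ctrl$gapStart0_A[i]
    if (any(calls$carrier == "A" & abs(calls$gapStart0 - bp) <= 25L))
      ctrlCalled <- TRUE
  }
  list(sensitivity = if (nrow(spec)) nMatched / nrow(spec) else NA_real_,
       precision = if (nrow(calls)) sum(matchedCall) / nrow(calls)
       else NA_real_,
       nTruth = nrow(spec), nCalls = nrow(calls), nMatched = nMatched,
       breakpointErrors = errors, controlCalled = ctrlCalled)
}

#' A small demonstration configuration
#'
#' A scaled-down \linkS4class{SimConfig} (60 kb genome, 24 insertions,
#' 20k reads, 10 peaks) that exercises every pipeline stage in seconds.
#'
#' @param seed master seed.
#' @return A \linkS4class{SimConfig}.
#' @export
demoConfig <- function(seed = 1L) {
  simConfig(seed = seed, genomeLength = 60000L, nSharedInsertions = 8L,
            nSpecificInsertionsPerStrain = 8L, nReads = 20000L,
            peakCount = 10L, snpDensity = 0.004, peakExtension = 1200L)
}

.stage <- function(name, report, expr) {
  message("[", name, "] running")
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  message(sprintf("[%s] done in %.1fs", name,
                  as.numeric(Sys.time() - t0, units = "secs")))
  res
}

#' Run the full synthetic pipeline
#'
#' Executes simulate, annotate, scan, melquant, methexpr, boundary and
#' allelic stages on one seeded configuration, writes every intermediate
#' file in its standard format under \code{outdir}, and returns (and
#' writes) a JSON report of per-stage record counts, recovery metrics
#' against the ground truth, and md5 checksums of the written files.
#'
#' @param cfg a \linkS4class{SimConfig} (default \code{demoConfig()}).
#' @param outdir output directory (created if needed).
#' @return the run report, invisibly also written to
#'   \code{file.path(outdir, "report.json")}.
#' @export
runAll <- function(cfg = demoConfig(), outdir = tempfile("sineboundary_")) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = cfg@seed, stages = list())
  pth <- function(f) file.path(outdir, f)

  sim <- .stage("simulate", report, {
    lib <- makeConsensusLibrary(cfg)
    gp <- simulateGenomePair(cfg, lib)
    meth <- simulateMethylation(cfg, gp$truth)
    rep1 <- simulateMelReads(cfg, gp$genomeA, meth$truth, replicate = 1L)
    rep2 <- simulateMelReads(cfg, gp$genomeA, rep1$truth, replicate = 2L)
    pa <- simulatePeaksAndAllelics(cfg, gp$genomeA, gp$genomeB, rep2$truth)
    covp <- if (any(pa$truth@peakTruth$anchored))
      simulateAllelicCoverage(cfg, pa$truth) else NULL
    writeConsensusLibrary(lib, pth("library.fa"))
    writeGenomeFasta(gp$genomeA, pth("genomeA.fa"))
    writeGenomeFasta(gp$genomeB, pth("genomeB.fa"))
    writeReadsFastq(rep1$treated, pth("mel_rep1_treated.fq"))
    writeReadsFastq(rep1$untreated, pth("mel_rep1_untreated.fq"))
    writeReadsFastq(rep2$treated, pth("mel_rep2_treated.fq"))
    writeCpgCalls(meth$calls, pth("cpg_calls.tsv"))
    writeBed(pa$peaksA, pth("peaksA.narrowPeak"), narrowPeak = TRUE)
    writeBed(pa$peaksB, pth("peaksB.narrowPeak"), narrowPeak = TRUE)
    writeSnpCounts(pa$snpCounts, pth("snp_counts.tsv"))
    jsonlite::write_json(truthInsertions(pa$truth), pth("truth.json"))
    list(lib = lib, gp = gp, meth = meth, rep1 = rep1, rep2 = rep2,
         pa = pa, covp = covp)
  })
  truth <- sim$pa$truth
  report$stages$simulate <- list(
    complete = TRUE,
    nInsertions = nrow(truthInsertions(truth)),
    nReadsTreated = length(sim$rep1$treated),
    nCpgSites = nrow(sim$meth$calls),
    nPeaks = length(sim$pa$peaksA),
    nSnps = nrow(sim$pa$snpCounts))

  ann <- .stage("annotate", report, {
    a <- annotateGenome(readGenomeFasta(pth("genomeA.fa")), sim$lib)
    writeAnnotationTsv(a, pth("annotationA.tsv"))
    a
  })
  lociA <- truthLoci(truth, "A")
  report$stages$annotate <- list(complete = TRUE, nHits = length(ann),
                                 nTruthLoci = length(lociA))

  scan <- .stage("scan", report, {
    calls <- scanPolymorphisms(readGenomeFasta(pth("genomeA.fa")),
                               readGenomeFasta(pth("genomeB.fa")), sim$lib)
    utils::write.table(calls, pth("insertion_calls.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    calls
  })
  ev <- evaluateScan(scan, truth)
  report$stages$scan <- list(complete = TRUE, nCalls = nrow(scan),
                             sensitivity = ev$sensitivity,
                             precision = ev$precision)

  mq <- .stage("melquant", report, {
    quantify <- function(fq) {
      reads <- readReadsFastq(fq)
      tf <- trimFilter(reads, cfg@adaptor3)
      cc <- classifyReads(tf$records, sim$lib,
                          nDiscarded = tf$nNoAdaptor + tf$nTooShort)
      mp <- mapUnique(tf$records, sim$gp$genomeA, lociA)
      expr <- normalizeRpm(mp$expression, n5p8S(cc))
      list(tf = tf, cc = cc, mp = mp, expr = expr)
    }
    q1 <- quantify(pth("mel_rep1_treated.fq"))
    q2 <- quantify(pth("mel_rep2_treated.fq"))
    q0 <- quantify(pth("mel_rep1_untreated.fq"))
    utils::write.table(q1$expr, pth("locus_expression_rep1.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(q1 = q1, q2 = q2, q0 = q0,
         tap = tapContrast(q1$cc, q0$cc),
         concordance = replicateConcordance(q1$expr, q2$expr),
         rank = rankAbundance(q1$expr))
  })
  report$stages$melquant <- list(
    complete = TRUE,
    nRetainedRep1 = nrow(mq$q1$tf$records),
    n5p8S = n5p8S(mq$q1$cc),
    tap5S = mq$tap$ratio[mq$tap$class == .RRNA_5S_NAME],
    locusConcordance = mq$concordance,
    nBelow1 = mq$rank$nBelow1)

  me <- .stage("methexpr", report, {
    calls <- readCpgCalls(pth("cpg_calls.tsv"))
    lm <- locusMethylation(calls, lociA)
    st <- stratifyLoci(lm)
    tab <- expressionByStratum(st, mq$q1$expr, mq$q2$expr)
    utils::write.table(tab, pth("expression_by_stratum.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(lm = lm, st = st, tab = tab)
  })
  report$stages$methexpr <- list(complete = TRUE,
                                 nLociWithLevel = sum(!is.na(me$lm$meanLevel)),
                                 nStrata = nrow(me$tab))

  bd <- .stage("boundary", report, {
    peaksA <- readBed(pth("peaksA.narrowPeak"), narrowPeak = TRUE)
    peaksB <- readBed(pth("peaksB.narrowPeak"), narrowPeak = TRUE)
    gl <- stats::setNames(Biostrings::width(sim$gp$genomeA), "chr1")
    prof <- boundaryProfile(peaksA, ann, window = 2000L, bin = 100L,
                            genomeLengths = gl)
    utils::write.table(profileTable(prof), pth("boundary_profile.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(prof = prof, summit = summitOverlap(peaksA, ann),
         sets = peakSetOverlap(peaksA, peaksB, repeats = ann))
  })
  report$stages$boundary <- list(
    complete = TRUE, background = profileBackground(bd$prof),
    maxEnrichment = max(profileTable(bd$prof)$enrichment, na.rm = TRUE),
    nSummitsInRepeats = bd$summit$nIn,
    nShared = bd$sets$nSharedA)

  al <- .stage("allelic", report, {
    snp <- readSnpCounts(pth("snp_counts.tsv"))
    frac <- snpAllelicFractions(snp)
    reg <- if (any(snp$region_label == "extension"))
      regionAllelicRatio(snp, "extension") else NULL
    shift <- if (!is.null(sim$covp))
      locateBoundaryShift(sim$covp$profileA, sim$covp$profileB,
                          sim$covp$breakpoint0) else NULL
    if (!is.null(shift))
      jsonlite::write_json(shift, pth("boundary_shift.json"),
                           auto_unbox = TRUE)
    list(frac = frac, reg = reg, shift = shift)
  })
  report$stages$allelic <- list(
    complete = TRUE,
    nSnps = nrow(al$frac),
    extensionFold = if (!is.null(al$reg)) al$reg$fold else NA,
    boundaryShifted = if (!is.null(al$shift)) al$shift$shifted else NA)

  files <- list.files(outdir, full.names = TRUE)
  files <- files[!grepl("report[.]json$", files)]
  report$checksums <- as.list(tools::md5sum(files))
  names(report$checksums) <- basename(files)
  jsonlite::write_json(report, pth("report.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(report)
}
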