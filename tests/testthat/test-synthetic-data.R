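smallCfg <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(seed = seed, genomeLength = 50000L, nSharedInsertions = 5L,
         nSpecificInsertionsPerStrain = 6L, nReads = 5000L, peakCount = 6L),
    list(...))
  do.call(simConfig, args)
}

test_that("the consensus library has diagnostic positions and CpG classes", {
  cfg <- simConfig(seed = 5L, nSubfamilies = 4L)
  lib <- makeConsensusLibrary(cfg)
  seqs <- as.character(librarySequences(lib)[sineNames(lib)])
  expect_length(seqs, 4L)
  expect_true(all(nchar(seqs) == 190L))
  for (i in 1:3) for (j in (i + 1):4) {
    h <- sum(strsplit(seqs[i], "")[[1]] != strsplit(seqs[j], "")[[1]])
    expect_gte(h, 10)
  }
  nCpG <- vapply(seqs, function(s)
    sum(gregexpr("CG", s, fixed = TRUE)[[1]] > 0), 0)
  age <- libraryAgeClasses(lib)[sineNames(lib)]
  expect_true(all(nCpG[age == "young"] >= 5))
  expect_true(all(nCpG[age == "old"] <= 2))
  expect_error(makeConsensusLibrary(simConfig(seed = 1, nSubfamilies = 1L)))
})

test_that("the generator is deterministic under a fixed configuration", {
  cfg <- smallCfg(9L)
  lib1 <- makeConsensusLibrary(cfg); lib2 <- makeConsensusLibrary(cfg)
  expect_identical(as.character(librarySequences(lib1)),
                   as.character(librarySequences(lib2)))
  g1 <- simulateGenomePair(cfg, lib1); g2 <- simulateGenomePair(cfg, lib2)
  expect_identical(as.character(g1$genomeA), as.character(g2$genomeA))
  expect_identical(truthInsertions(g1$truth), truthInsertions(g2$truth))
  m1 <- simulateMethylation(cfg, g1$truth)
  m2 <- simulateMethylation(cfg, g2$truth)
  expect_identical(m1$calls, m2$calls)
  r1 <- simulateMelReads(cfg, g1$genomeA, m1$truth)
  r2 <- simulateMelReads(cfg, g2$genomeA, m2$truth)
  expect_identical(r1$treated, r2$treated)
  expect_identical(r1$untreated, r2$untreated)
})

test_that("genome pair bookkeeping and degenerate settings behave", {
  cfg0 <- smallCfg(2L, nSpecificInsertionsPerStrain = 0L)
  lib <- makeConsensusLibrary(cfg0)
  gp0 <- simulateGenomePair(cfg0, lib)
  expect_identical(as.character(gp0$genomeA), as.character(gp0$genomeB))

  cfg <- smallCfg(3L)
  gp <- simulateGenomePair(cfg, lib)
  tr <- truthInsertions(gp$truth)
  expect_equal(sum(tr$strain == "A"), 6L)
  expect_equal(sum(tr$strain == "B"), 6L)
  expect_equal(sum(tr$strain == "shared"), 5L)
  expect_equal(anyDuplicated(tr$id), 0L)
  # every planted copy interval sits inside its carrier contig
  lenA <- Biostrings::width(gp$genomeA)[1]
  inA <- tr[!is.na(tr$copyStart0_A), ]
  expect_true(all(inA$copyEnd0_A <= lenA & inA$copyStart0_A >= 0))

  # zero divergence: planted copies are exact consensus substrings and sit
  # at their recorded carrier coordinates
  cfgE <- smallCfg(4L, perCopyDivergence = 0)
  libE <- makeConsensusLibrary(cfgE)
  gpE <- simulateGenomePair(cfgE, libE)
  trE <- truthInsertions(gpE$truth)
  gA <- as.character(gpE$genomeA[[1]])
  for (i in which(!is.na(trE$copyStart0_A))) {
    atGenome <- substr(gA, trE$copyStart0_A[i] + 1L, trE$copyEnd0_A[i])
    expect_identical(atGenome, trE$copySeq[i])
    cons <- as.character(librarySequences(libE)[[trE$subfamily[i]]])
    expect_true(grepl(trE$copySeq[i], cons, fixed = TRUE))
  }
})

test_that("read libraries respect chemistry classes and conservation", {
  cfg <- smallCfg(6L)
  lib <- makeConsensusLibrary(cfg)
  gp <- simulateGenomePair(cfg, lib)
  mel <- simulateMelReads(cfg, gp$genomeA, gp$truth)
  expect_length(mel$treated, cfg@nReads)
  # class fractions within 3 binomial SD of the configuration
  n <- cfg@nReads
  for (fr in list(c(cfg@frac5p8S, sum(mel$classTruth$treated["rRNA_5.8S"])),
                  c(cfg@frac5S, sum(mel$classTruth$treated["rRNA_5S"])))) {
    expect_lt(abs(fr[2] - n * fr[1]), 3 * sqrt(n * fr[1] * (1 - fr[1])) + 1)
  }
  # Pol III reads are depleted from the untreated library
  u58 <- mel$classTruth$untreated["rRNA_5.8S"]
  u5S <- mel$classTruth$untreated["rRNA_5S"]
  t58 <- mel$classTruth$treated["rRNA_5.8S"]
  t5S <- mel$classTruth$treated["rRNA_5S"]
  expect_lt((u5S / u58), 0.15 * (t5S / t58) + 0.05)

  # degraded fraction zero: every read ends with the adaptor
  cfgF <- smallCfg(7L, fracDegraded = 0)
  libF <- makeConsensusLibrary(cfgF)
  gpF <- simulateGenomePair(cfgF, libF)
  melF <- simulateMelReads(cfgF, gpF$genomeA, gpF$truth)
  expect_true(all(endsWith(melF$treated, cfgF@adaptor3)))

  expect_length(simulateMelReads(smallCfg(8L, nReads = 0L), gpF$genomeA,
                                 gpF$truth)$treated, 0L)
  expect_error(simulateMelReads(smallCfg(8L, adaptor3 = "ACGTACG"),
                                gpF$genomeA, gpF$truth), "adaptor")
})

test_that("methylation coupling has the planted structure", {
  cfg <- smallCfg(12L, nSharedInsertions = 20L,
                  nSpecificInsertionsPerStrain = 20L,
                  genomeLength = 100000L)
  lib <- makeConsensusLibrary(cfg)
  gp <- simulateGenomePair(cfg, lib)
  meth <- simulateMethylation(cfg, gp$truth)
  lm <- truthMethylation(meth$truth)
  rich <- lm[lm$nCpG >= 3, ]
  # multiplier strictly decreasing in planted level for CpG-rich copies
  expect_true(all(diff(rich$multiplier[order(rich$trueLevel)]) < 0))
  # expected expression ratio between low- and high-methylation groups > 1
  s <- cfg@methCouplingStrength
  expect_gt(exp(-s * 0.1) / exp(-s * 0.9), 1)
  # attenuation for CpG-poor copies: multiplier closer to 1
  poor <- lm[lm$nCpG <= 2, ]
  expect_true(all(poor$multiplier >= exp(-s * 0.25)))
  # zero coupling: all multipliers 1
  cfg0 <- smallCfg(12L, methCouplingStrength = 0)
  m0 <- simulateMethylation(cfg0, gp$truth)
  expect_true(all(truthMethylation(m0$truth)$multiplier == 1))
  # binomial sampling: pooled counts track the planted level
  calls <- meth$calls
  pooled <- tapply(calls$methylated, calls$locus, sum) /
    tapply(calls$total, calls$locus, sum)
  planted <- lm$trueLevel[match(names(pooled), lm$locus)]
  expect_gt(cor(pooled, planted, method = "spearman", use = "complete.obs"),
            0.9)
})

test_that("peaks anchor at planted breakpoints and allelic bias is planted", {
  cfg <- smallCfg(14L, fracBoundaryAnchored = 0.5, snpDensity = 0.01)
  lib <- makeConsensusLibrary(cfg)
  gp <- simulateGenomePair(cfg, lib)
  pa <- simulatePeaksAndAllelics(cfg, gp$genomeA, gp$genomeB, gp$truth)
  pt <- truthPeaks(pa$truth)
  tr <- truthInsertions(pa$truth)
  anch <- pt[pt$anchored, ]
  expect_equal(nrow(anch), round(0.5 * cfg@peakCount))
  for (i in seq_len(nrow(anch))) {
    ins <- tr[tr$id == anch$insertionId[i], ]
    expect_equal(anch$endA0[i], ins$gapStart0_A)     # edge exactly at breakpoint
    expect_gt(anch$endB0[i] - ins$bpOther0, 0)       # free allele extends beyond
  }
  # extension SNPs biased toward the insertion-free allele (fold 6 -> 6/7)
  ext <- pa$snpCounts[pa$snpCounts$region_label == "extension", ]
  expect_gt(nrow(ext), 0)
  fracB <- sum(ext$countB) / sum(ext$countA + ext$countB)
  nTot <- sum(ext$countA + ext$countB)
  expect_lt(abs(fracB - 6 / 7), 3 * sqrt((6 / 7) * (1 / 7) / nTot))
  bg <- pa$snpCounts[pa$snpCounts$region_label == "background", ]
  fracBbg <- sum(bg$countB) / sum(bg$countA + bg$countB)
  expect_lt(abs(fracBbg - 0.5),
            3 * sqrt(0.25 / sum(bg$countA + bg$countB)))

  # fold 1: balanced everywhere
  cfg1 <- smallCfg(15L, allelicFold = 1, snpDensity = 0.01)
  gp1 <- simulateGenomePair(cfg1, makeConsensusLibrary(cfg1))
  pa1 <- simulatePeaksAndAllelics(cfg1, gp1$genomeA, gp1$genomeB, gp1$truth)
  f <- sum(pa1$snpCounts$countB) / sum(pa1$snpCounts$countA +
                                         pa1$snpCounts$countB)
  expect_lt(abs(f - 0.5), 0.02)

  # no anchoring requested: no anchored peaks
  cfg0 <- smallCfg(16L, fracBoundaryAnchored = 0)
  gp0 <- simulateGenomePair(cfg0, makeConsensusLibrary(cfg0))
  pa0 <- simulatePeaksAndAllelics(cfg0, gp0$genomeA, gp0$genomeB, gp0$truth)
  expect_false(any(truthPeaks(pa0$truth)$anchored))
})
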