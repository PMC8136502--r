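melLib <- makeConsensusLibrary(simConfig(seed = 301L))
ADAPT <- "AGATCGGAAGAGCACACGTC"

test_that("the full-length filter retains and trims exactly as specified", {
  set.seed(61)
  transcript <- randomDna(150)
  reads <- c(full = paste0(transcript, ADAPT),          # internal full match
             partial = paste0(transcript, substr(ADAPT, 1, 9)),  # 9-base end
             short = paste0(transcript, substr(ADAPT, 1, 7)),    # < overlap
             none = randomDna(170),
             adaptorOnly = ADAPT)
  tf <- trimFilter(reads, ADAPT)
  expect_setequal(tf$records$id, c("full", "partial"))
  expect_equal(tf$records$trimmed[tf$records$id == "full"], transcript)
  expect_equal(tf$records$trimmed[tf$records$id == "partial"], transcript)
  # conservation: retained + no-adaptor + too-short = input
  expect_equal(nrow(tf$records) + tf$nNoAdaptor + tf$nTooShort, tf$nInput)
  expect_equal(tf$nTooShort, 1L)    # the adaptor-only read
  expect_error(trimFilter(reads, "ACGT", minOverlap = 8L), "minOverlap")
  expect_equal(trimFilter(character(0), ADAPT)$nInput, 0L)
})

test_that("read classification counts classes and rolls up families", {
  r58 <- librarySequences(melLib)[["rRNA_5.8S"]]
  recs <- data.frame(id = sprintf("r%d", 1:100),
                     trimmed = rep(as.character(r58), 100))
  cc <- classifyReads(recs, melLib)
  expect_equal(n5p8S(cc), 100)
  expect_equal(cc@nTotal, 100L)
  expect_equal(unname(cc@familyCounts["rRNA"]), 100)
  empty <- classifyReads(data.frame(id = character(0),
                                    trimmed = character(0)), melLib)
  expect_equal(empty@nTotal, 0L)
  expect_true(all(entryCounts(empty) == 0))
  # rollups plus unclassified account for every read
  expect_equal(sum(cc@familyCounts), cc@nTotal)
})

test_that("RPM normalization follows the 5.8S internal-control definition", {
  expect_equal(normalizeRpm(5, 1e6), 5)
  expect_equal(normalizeRpm(c(10, 0), 2000), c(5000, 0))
  # invariant under uniform library scaling
  expect_equal(normalizeRpm(10 * 7, 10 * 2000), normalizeRpm(7, 2000))
  d <- normalizeRpm(data.frame(locus = "x", count = 3), 3000)
  expect_equal(d$rpm, 1000)
  expect_error(normalizeRpm(5, 0), "normalization")
})

test_that("exact-unique mapping distinguishes unique and multi-mapping reads", {
  set.seed(71)
  copyU <- randomDna(80); copyM <- randomDna(80)
  g <- paste0(randomDna(300), copyU, randomDna(300), copyM, randomDna(300),
              copyM, randomDna(300))
  loci <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(301, 681, 1061), width = 80))
  names(loci) <- c("locU", "locM1", "locM2")
  recs <- data.frame(id = c("u", "m"), trimmed = c(copyU, copyM))
  mp <- mapUnique(recs, c(chr1 = g), loci)
  expect_equal(mp$nUnique, 1)
  expect_equal(mp$nMulti, 1)
  expect_equal(mp$expression$count[mp$expression$locus == "locU"], 1)
  expect_equal(sum(mp$expression$count), 1)
  # a read absent from the genome is unmapped
  mp2 <- mapUnique(data.frame(id = "x", trimmed = randomDna(60)),
                   c(chr1 = g), loci)
  expect_equal(mp2$nUnmapped, 1)
})

test_that("TAP contrast ratios behave at the edges", {
  mk <- function(v) new("ClassCounts", entryCounts = v,
                        familyCounts = v, nTotal = as.integer(sum(v)),
                        nAdaptorlessDiscarded = 0L)
  a <- mk(c(`rRNA_5.8S` = 100, `rRNA_5S` = 50, SF01 = 20, SF02 = 0))
  tap <- tapContrast(a, a)
  expect_true(all(tap$ratio[tap$flag == "ok"] == 1))
  expect_equal(tap$flag[tap$class == "SF02"], "undefined")
  b <- mk(c(`rRNA_5.8S` = 100, `rRNA_5S` = 0, SF01 = 5, SF02 = 0))
  tap2 <- tapContrast(a, b)
  expect_equal(tap2$flag[tap2$class == "rRNA_5S"], "infinite")
  expect_true(is.infinite(tap2$ratio[tap2$class == "rRNA_5S"]))
})

test_that("replicate concordance is 1 on identity and negative on reversal", {
  e <- data.frame(locus = letters[1:6], rpm = c(100, 50, 20, 10, 5, 1))
  expect_equal(replicateConcordance(e, e), 1)
  rev <- data.frame(locus = letters[1:6], rpm = rev(e$rpm))
  expect_lt(replicateConcordance(e, rev), 0)
  flat <- data.frame(locus = letters[1:6], rpm = rep(2, 6))
  expect_warning(r <- replicateConcordance(flat, flat), "degenerate")
  expect_true(is.na(r))
})

test_that("rank-abundance bins use strict thresholds", {
  one <- rankAbundance(data.frame(locus = "a", rpm = 5))
  expect_equal(one$table$rank, 1L)
  expect_equal(one$nBelow1, 0L); expect_equal(one$nAbove1000, 0L)
  e <- data.frame(locus = letters[1:5], rpm = c(2000, 1000, 1, 0.5, 0))
  ra <- rankAbundance(e)
  expect_equal(ra$nAbove1000, 1L)     # 1000 itself is not "> 1000"
  expect_equal(ra$nBelow1, 2L)        # 1 itself is not "< 1"
  expect_equal(ra$table$locus[1], "a")
  expect_equal(nrow(rankAbundance(e[0, ])$table), 0L)
})
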