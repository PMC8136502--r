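test_that("boundary profiles match the per-base oracle and edge cases", {
  set.seed(81)
  L <- 40000L
  peaks <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(sort(sample(3000:35000, 5)), width = 1500))
  reps <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(sample(100:39000, 40), width = 200))
  gl <- c(chr1 = L)
  prof <- boundaryProfile(peaks, reps, window = 1000L, bin = 100L,
                          genomeLengths = gl)
  oracle <- oracleBoundaryProfile(peaks, reps, 1000L, 100L, L)
  expect_equal(profileTable(prof)$density, oracle$density)
  expect_equal(profileTable(prof)$coveredBases, oracle$covered)
  expect_equal(profileTable(prof)$totalBases, oracle$bases)
  expect_equal(profileBackground(prof), oracle$background)
  # conservation of covered bases across the aggregated windows
  expect_equal(sum(profileTable(prof)$coveredBases), sum(oracle$covered))

  none <- boundaryProfile(peaks, reps[0], window = 1000L, bin = 100L,
                          genomeLengths = gl)
  expect_true(all(profileTable(none)$density == 0))
  expect_error(boundaryProfile(peaks[0], reps, 1000L, 100L, gl), "empty")
  expect_error(boundaryProfile(peaks, reps, 1050L, 100L, gl), "multiple")
})

test_that("a repeat placed just outside every peak end dominates one bin", {
  L <- 50000L
  starts <- seq(5000, 45000, by = 5000)
  peaks <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(starts, width = 1000))
  # repeat immediately outside each peak end (0-based end = start+1000-1+1)
  reps <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(starts + 1000L, width = 200L))
  prof <- boundaryProfile(peaks, reps, window = 1000L, bin = 100L,
                          genomeLengths = c(chr1 = L))
  tab <- profileTable(prof)
  firstOutside <- tab[tab$binStart == -100, ]
  expect_equal(max(tab$density), firstOutside$density)
  expect_gte(firstOutside$enrichment, 5)
})

test_that("summit counting respects half-open interval edges", {
  reps <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(101, 501, 901, 1301), width = 100))
  reps$subfamily <- c("B2a", "B2a", "B2b", "B2b")
  reps$score <- c(10, 20, 30, 40)
  # repeat 1 spans 0-based [100, 200): a summit at 100 counts, at 200 not
  summit0 <- c(100, 150, 199,          # inside repeat 1 (start, mid, end-1)
               550, 950, 1350, 1399,   # inside repeats 2-4
               200,                    # exactly at a 0-based end: outside
               2000, 2500)             # far outside
  peaks <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(summit0 + 1L, width = 1L))
  peaks$summit0 <- summit0
  ov <- summitOverlap(peaks, reps)
  expect_equal(ov$nSummits, 10L)
  expect_equal(ov$nIn, 7L)
  atEnd <- GenomicRanges::GRanges("chr1", IRanges::IRanges(201, 201))
  atEnd$summit0 <- 200L       # exactly at the 0-based end: excluded
  expect_equal(summitOverlap(atEnd, reps)$nIn, 0L)
  atStart <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 101))
  atStart$summit0 <- 100L     # exactly at the 0-based start: included
  expect_equal(summitOverlap(atStart, reps)$nIn, 1L)
  # 4 of 10 summits fall in B2a copies, 3 in B2b
  expect_equal(unname(ov$fractions["B2a"]), 0.4)
  expect_equal(unname(ov$fractions["B2b"]), 0.3)
})

test_that("peak-set partitions count shared and specific peaks", {
  a <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(100, 1000, 2000, 3000, 4000), width = 300))
  expect_equal(peakSetOverlap(a, a)$nSharedA, 5L)
  b <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(350, 1200, 5000, 6000, 7000), width = 250))
  # hand-enumerated: a peaks 2 (1000-1299 vs 1200-1449) overlap; a peak 1
  # (100-399) vs b 1 (350-599) overlap; rest disjoint
  res <- peakSetOverlap(a, b)
  expect_equal(res$nSharedA, 2L)
  expect_equal(res$nSharedB, 2L)
  expect_equal(length(res$aSpecific), 3L)
  expect_equal(length(res$bSpecific), 3L)
  disj <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(10000, 20000), width = 100))
  expect_equal(peakSetOverlap(a, disj)$nSharedA, 0L)
})

test_that("binding stratification counts methylated CpGs and tests trends", {
  reps <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(seq(1, 4000, by = 400), width = 200))
  # two methylated CpGs in repeat 1, one unmethylated in repeat 2
  calls <- data.frame(contig = "chr1", pos0 = c(10L, 50L, 410L),
                      methylated = c(9L, 10L, 1L), total = c(10L, 10L, 10L))
  res <- bindingVsMethylation(reps, calls, rep(FALSE, length(reps)))
  expect_true(all(res$boundFraction[!is.na(res$boundFraction)] == 0))
  expect_equal(unname(res$table["2", "FALSE"]), 1L)
  expect_equal(unname(res$table["0", "FALSE"]), length(reps) - 1L)
})
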