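scanLib <- makeConsensusLibrary(simConfig(seed = 201L))

# build an alignment object with one clean internal gap of the given length
mkGapAln <- function(gapLen, flankLen = 200L, gapIn = "q", seed = 1L) {
  set.seed(seed)
  left <- randomDna(flankLen); right <- randomDna(flankLen)
  ins <- randomDna(gapLen)
  if (gapIn == "q")
    structure(list(qaln = paste0(left, strrep("-", gapLen), right),
                   saln = paste0(left, ins, right),
                   score = 2 * flankLen - gapLen), class = "pairAlignment")
  else
    structure(list(qaln = paste0(left, ins, right),
                   saln = paste0(left, strrep("-", gapLen), right),
                   score = 2 * flankLen - gapLen), class = "pairAlignment")
}

test_that("internal gap extraction applies the length and flank rules", {
  expect_equal(nrow(extractInternalGaps(mkGapAln(119L))), 0L)   # below floor
  expect_equal(nrow(extractInternalGaps(mkGapAln(120L))), 1L)
  expect_equal(nrow(extractInternalGaps(mkGapAln(300L))), 1L)
  expect_equal(nrow(extractInternalGaps(mkGapAln(301L))), 0L)   # above ceiling

  g <- extractInternalGaps(mkGapAln(200L))
  expect_equal(g$carrier, "B")        # gap in the query row: B carries it
  expect_equal(g$gapLen, 200L)
  expect_gte(g$leftFlankIdentity, 0.9)
  expect_equal(g$gapStart0, 200L)

  gA <- extractInternalGaps(mkGapAln(200L, gapIn = "s"))
  expect_equal(gA$carrier, "A")

  # terminal gap: excluded
  term <- structure(list(qaln = paste0(randomDna(200), strrep("-", 150)),
                         saln = randomDna(350), score = 0),
                    class = "pairAlignment")
  expect_equal(nrow(extractInternalGaps(term)), 0L)

  # poorly aligned flank: excluded
  set.seed(3)
  left <- randomDna(200); right1 <- randomDna(200); right2 <- randomDna(200)
  bad <- structure(list(
    qaln = paste0(left, strrep("-", 150), right1),
    saln = paste0(left, randomDna(150), right2), score = 0),
    class = "pairAlignment")
  expect_equal(nrow(extractInternalGaps(bad)), 0L)
})

test_that("the occupancy rule is strict at the 0.80 boundary", {
  cons <- as.character(librarySequences(scanLib)[["SF01"]])
  mkCand <- function(gapSeq) data.frame(
    carrier = "B", gapStart0 = 500L, gapEnd0 = 500L + nchar(gapSeq),
    gapLen = nchar(gapSeq), leftFlankLen = 100, rightFlankLen = 100,
    leftFlankIdentity = 1, rightFlankIdentity = 1, tsdLen = 0L,
    otherPos0 = 500L, gapSeq = gapSeq, stringsAsFactors = FALSE)

  # a full-length exact copy occupies the whole gap
  full <- callInsertions(mkCand(cons), scanLib)
  expect_equal(nrow(full), 1L)
  expect_equal(full$occupancy, 1)
  expect_equal(full$subfamily, "SF01")

  # 160 exact bases (ending at the consensus 3' end, so the local hit
  # cannot extend) in a 200-base gap: occupancy exactly 0.80 -> rejected
  chunk160 <- substr(cons, nchar(cons) - 159, nchar(cons))
  filler <- strrep("A", 40)
  at080 <- callInsertions(mkCand(paste0(chunk160, filler)), scanLib)
  expect_equal(nrow(at080), 0L)
  # one more aligned base tips it over the strict threshold
  chunk161 <- substr(cons, nchar(cons) - 160, nchar(cons))
  over <- callInsertions(mkCand(paste0(chunk161, strrep("A", 39))), scanLib)
  expect_equal(nrow(over), 1L)
  expect_gt(over$occupancy, 0.80)

  # 150-base hit in a 200-base gap (0.75): no call
  chunk150 <- substr(cons, nchar(cons) - 149, nchar(cons))
  at075 <- callInsertions(mkCand(paste0(chunk150, strrep("A", 50))), scanLib)
  expect_equal(nrow(at075), 0L)
})

test_that("raising the occupancy threshold never adds calls", {
  cfg <- simConfig(seed = 203L, genomeLength = 60000L,
                   nSharedInsertions = 4L, nSpecificInsertionsPerStrain = 8L)
  lib <- makeConsensusLibrary(cfg)
  gp <- simulateGenomePair(cfg, lib)
  aln <- alignSeeded(as.character(gp$genomeA[[1]]),
                     as.character(gp$genomeB[[1]]))
  cands <- extractInternalGaps(aln)
  n <- vapply(c(0.5, 0.8, 0.9, 0.99), function(occ)
    nrow(callInsertions(cands, lib, minOccupancy = occ)), 0L)
  expect_true(all(diff(n) <= 0))
})

test_that("strain swap exchanges carrier labels but preserves the calls", {
  cfg <- simConfig(seed = 205L, genomeLength = 60000L,
                   nSharedInsertions = 4L, nSpecificInsertionsPerStrain = 6L)
  lib <- makeConsensusLibrary(cfg)
  gp <- simulateGenomePair(cfg, lib)
  fwd <- scanPolymorphisms(gp$genomeA, gp$genomeB, lib)
  rev <- scanPolymorphisms(gp$genomeB, gp$genomeA, lib)
  expect_equal(nrow(fwd), nrow(rev))
  key <- function(d, flip = FALSE) {
    carrier <- if (flip) c(A = "B", B = "A")[d$carrier] else d$carrier
    sort(paste(carrier, d$gapStart0, d$subfamily))
  }
  expect_equal(key(fwd), key(rev, flip = TRUE))
})

test_that("summaries tabulate carriers, subfamilies and lengths", {
  empty <- summarizePolymorphisms(data.frame(carrier = character(0),
                                             subfamily = character(0),
                                             gapLen = integer(0)))
  expect_true(all(empty$table == 0))
  calls <- data.frame(carrier = rep(c("A", "B"), each = 50),
                      subfamily = rep(c("SF01", "SF02"), 50),
                      gapLen = rep(200L, 100))
  s <- summarizePolymorphisms(calls)
  expect_equal(unname(rowSums(s$table)), c(50, 50))
  expect_equal(sum(s$lengthHist$count), 100)
})
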