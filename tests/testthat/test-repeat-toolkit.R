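cfg4 <- simConfig(seed = 101L, nSubfamilies = 4L)
lib4 <- makeConsensusLibrary(cfg4)

test_that("classification recovers exact copies on both strands", {
  cons <- as.character(librarySequences(lib4)[["SF01"]])
  hit <- classifySequence(cons, lib4)
  expect_equal(hit@subfamily, "SF01")
  expect_equal(hit@divergence, 0)
  expect_equal(hit@occupancy, 1)
  expect_equal(hit@strand, "+")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cons)))
  hitRc <- classifySequence(rc, lib4)
  expect_equal(hitRc@subfamily, "SF01")
  expect_equal(hitRc@strand, "-")
  expect_equal(hitRc@score, hit@score)   # strand symmetry
  expect_error(classifySequence(cons, new("ConsensusLibrary",
    seqs = Biostrings::DNAStringSet(), family = character(0),
    ageClass = character(0), rRNANames = character(0))), "empty")
})

test_that("local classification scores match the affine DP oracle", {
  set.seed(21)
  for (i in 1:40) {
    q <- randomDna(sample(20:26, 1))
    s <- randomDna(sample(8:12, 1))
    lib1 <- new("ConsensusLibrary",
                seqs = Biostrings::DNAStringSet(c(X = s)),
                family = c(X = "SINE"), ageClass = c(X = "young"),
                rRNANames = character(0))
    hit <- classifySequence(q, lib1, minScore = -Inf)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(q)))
    expect_equal(hit@score, max(oracleLocalAffine(q, s),
                                oracleLocalAffine(rc, s)),
                 info = paste(q, s))
  }
})

test_that("genome annotation finds planted copies and nothing else", {
  set.seed(31)
  bg <- randomDna(30000)
  cons <- as.character(librarySequences(lib4)[sineNames(lib4)])
  pos <- seq(2000, 28000, length.out = 10)
  g <- bg
  placed <- sample(names(cons), 10, replace = TRUE)
  for (i in 10:1)   # insert right-to-left so earlier positions are stable
    g <- paste0(substr(g, 1, pos[i]), cons[placed[i]],
                substr(g, pos[i] + 1, nchar(g)))
  ann <- annotateGenome(c(chr = g), lib4)
  expect_equal(length(ann), 10L)
  expect_equal(ann$subfamily, placed[order(pos)])
  expect_true(all(ann$divergence == 0))

  # random background alone yields nothing at the default threshold
  for (s in 1:3) {
    set.seed(1000 + s)
    expect_equal(length(annotateGenome(c(chr = randomDna(20000)), lib4)), 0L)
  }
})

test_that("majority consensus rebuilding and its tie-break behave", {
  anchor <- "ACGTACGTACGTACGTACGTACGT"
  expect_equal(buildConsensus(rep(anchor, 10), anchor), anchor)
  expect_error(buildConsensus(anchor, anchor), "at least 2")
  # 2 vs 2 tie at one column resolved by base order A < C < G < T
  v <- strsplit(anchor, "")[[1]]
  mk <- function(b) { w <- v; w[5] <- b; paste(w, collapse = "") }
  out <- buildConsensus(c(mk("G"), mk("G"), mk("T"), mk("T")), anchor)
  expect_equal(substr(out, 5, 5), "G")
})

test_that("consensus rebuilt from diverged copies matches the truth", {
  set.seed(41)
  truthCons <- as.character(librarySequences(lib4)[["SF02"]])
  copies <- vapply(1:50, function(i) {
    v <- strsplit(truthCons, "")[[1]]
    hit <- which(runif(length(v)) < 0.10)
    for (h in hit) v[h] <- sample(setdiff(c("A", "C", "G", "T"), v[h]), 1)
    paste(v, collapse = "")
  }, "")
  rebuilt <- buildConsensus(copies, truthCons)
  expect_equal(nchar(rebuilt), nchar(truthCons))
  ident <- mean(strsplit(rebuilt, "")[[1]] == strsplit(truthCons, "")[[1]])
  expect_gte(ident, 0.99)
})

test_that("p-distances are exact on hand-checked cases", {
  expect_equal(unname(pDistanceMatrix(c("ACGT", "ACGT"))[1, 2]), 0)
  expect_equal(unname(pDistanceMatrix(c("AAAA", "AAAT"))[1, 2]), 0.25)
  d <- pDistanceMatrix(c(a = "ACGTTGCA", b = "ACGTTGCT", c = "TCGTTGCA"))
  expect_true(isSymmetric(unname(d)))
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))
  expect_equal(d["a", "b"], 1 / 8)
  expect_equal(d["a", "c"], 1 / 8)
  expect_equal(d["b", "c"], 2 / 8)
  expect_error(pDistanceMatrix(c("ACGT", "")), "empty")
})

test_that("neighbor joining is exact on additive distances", {
  # 3 taxa: closed-form branch lengths
  d3 <- matrix(c(0, 0.3, 0.5, 0.3, 0, 0.4, 0.5, 0.4, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  tr3 <- njTree(d3)
  bl <- setNames(tr3$edge.length[match(1:3, tr3$edge[, 2])], tr3$tip.label)
  expect_equal(bl[["a"]], (0.3 + 0.5 - 0.4) / 2)
  expect_equal(bl[["b"]], (0.3 + 0.4 - 0.5) / 2)
  expect_equal(bl[["c"]], (0.5 + 0.4 - 0.3) / 2)

  # 4 taxa from a known tree: ((a:1,b:2):3,c:4,d:5)
  tr <- ape::read.tree(text = "((a:1,b:2):3,c:4,d:5);")
  d4 <- ape::cophenetic.phylo(tr)
  rec <- njTree(d4)
  expect_equal(ape::dist.topo(ape::unroot(tr), rec), setNames(0L, "PH85"),
               ignore_attr = TRUE)
  expect_equal(ape::cophenetic.phylo(rec)[rownames(d4), colnames(d4)], d4,
               tolerance = 1e-10)

  # zero matrix: all branch lengths 0
  d0 <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_true(all(njTree(d0)$edge.length == 0))

  dbad <- d3; dbad[1, 2] <- 0.9
  expect_error(njTree(dbad), "symmetric")
})

test_that("subfamily copies cluster as clades in the NJ tree", {
  set.seed(51)
  consA <- as.character(librarySequences(lib4)[["SF01"]])
  consB <- as.character(librarySequences(lib4)[["SF03"]])
  mut <- function(cons, rate) {
    v <- strsplit(cons, "")[[1]]
    hit <- which(runif(length(v)) < rate)
    for (h in hit) v[h] <- sample(setdiff(c("A", "C", "G", "T"), v[h]), 1)
    paste(v, collapse = "")
  }
  seqs <- c(setNames(vapply(1:5, function(i) mut(consA, 0.01), ""),
                     paste0("A", 1:5)),
            setNames(vapply(1:5, function(i) mut(consB, 0.01), ""),
                     paste0("B", 1:5)))
  tr <- njTree(pDistanceMatrix(seqs))
  expect_true(ape::is.monophyletic(tr, paste0("A", 1:5)))
  expect_true(ape::is.monophyletic(tr, paste0("B", 1:5)))
})
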