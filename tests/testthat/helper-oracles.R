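# Independent alignment oracles: straightforward dynamic-programming
# implementations written against the scoring definitions, used to verify
# the package's Biostrings-backed aligners on small instances.

# Global alignment, minimum-gap scoring: match +1, mismatch -1, each gap
# base -1 (gap open 0). Linear gap cost, so a plain 2D recursion suffices.
oracleGlobalMinGap <- function(q, s) {
  qv <- strsplit(q, "")[[1]]; sv <- strsplit(s, "")[[1]]
  n <- length(qv); m <- length(sv)
  D <- matrix(0, n + 1, m + 1)
  D[, 1] <- -(0:n); D[1, ] <- -(0:m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    D[i + 1, j + 1] <- max(D[i, j] + ifelse(qv[i] == sv[j], 1, -1),
                           D[i, j + 1] - 1, D[i + 1, j] - 1)
  }
  D[n + 1, m + 1]
}

# Local alignment, classification scoring: match +1, mismatch -1, a gap of
# length L costs L + 1 (open -2 on the first gap base, -1 thereafter).
# Three-state affine DP with a zero floor.
oracleLocalAffine <- function(q, s, openCost = 2, extCost = 1) {
  qv <- strsplit(q, "")[[1]]; sv <- strsplit(s, "")[[1]]
  n <- length(qv); m <- length(sv)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)   # gap in query (consuming subject)
  Fm <- matrix(-Inf, n + 1, m + 1)  # gap in subject (consuming query)
  best <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    E[i + 1, j + 1] <- max(H[i + 1, j] - openCost, E[i + 1, j] - extCost)
    Fm[i + 1, j + 1] <- max(H[i, j + 1] - openCost, Fm[i, j + 1] - extCost)
    H[i + 1, j + 1] <- max(0,
                           H[i, j] + ifelse(qv[i] == sv[j], 1, -1),
                           E[i + 1, j + 1], Fm[i + 1, j + 1])
    best <- max(best, H[i + 1, j + 1])
  }
  best
}

randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = "")

# Per-base brute-force boundary profile: direct position-by-position
# membership counting against a logical repeat mask.
oracleBoundaryProfile <- function(peaks, repeats, window, bin, L) {
  mask <- logical(L)
  for (i in seq_along(repeats))
    mask[GenomicRanges::start(repeats)[i]:GenomicRanges::end(repeats)[i]] <- TRUE
  nbin <- 2L * window %/% bin
  binFrom <- -window + (seq_len(nbin) - 1L) * bin
  covered <- numeric(nbin); bases <- numeric(nbin)
  for (i in seq_along(peaks)) {
    s0 <- GenomicRanges::start(peaks)[i] - 1L
    e0 <- GenomicRanges::end(peaks)[i]
    for (j in seq_len(nbin)) {
      for (pos0 in (s0 + binFrom[j]):(s0 + binFrom[j] + bin - 1L)) {
        if (pos0 >= 0L && pos0 < L) {
          bases[j] <- bases[j] + 1
          if (mask[pos0 + 1L]) covered[j] <- covered[j] + 1
        }
      }
      for (pos0 in (e0 - binFrom[j] - bin):(e0 - binFrom[j] - 1L)) {
        if (pos0 >= 0L && pos0 < L) {
          bases[j] <- bases[j] + 1
          if (mask[pos0 + 1L]) covered[j] <- covered[j] + 1
        }
      }
    }
  }
  list(density = ifelse(bases > 0, covered / bases, NA_real_),
       covered = covered, bases = bases,
       background = sum(mask) / L)
}
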