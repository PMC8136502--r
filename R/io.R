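## Shared format I/O. Conventions: genomic intervals are 0-based half-open
## on disk (BED and the TSV schemas) and 1-based closed GRanges in memory;
## FASTA is uppercased on read.

#' Genome FASTA I/O
#'
#' @param genome named \link[Biostrings]{DNAStringSet} or character vector.
#' @param path file path.
#' @return \code{readGenomeFasta}: an uppercased \code{DNAStringSet}.
#' @export
writeGenomeFasta <- function(genome, path) {
  Biostrings::writeXStringSet(.as_genome(genome), path)
  invisible(path)
}

#' @rdname writeGenomeFasta
#' @export
readGenomeFasta <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  ## lowercase (soft-masked) bases are uppercased on read
  Biostrings::DNAStringSet(stats::setNames(toupper(as.character(g)),
                                           names(g)))
}

#' Read FASTQ I/O (constant quality on write)
#'
#' Reads are stored as named character vectors in memory. Writing emits a
#' constant quality string; reading validates the 4-line record structure
#' first and reports the offending record on truncation or marker errors.
#'
#' @param reads named character vector of read sequences.
#' @param path file path.
#' @return \code{readReadsFastq}: named character vector.
#' @export
writeReadsFastq <- function(reads, path) {
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read_%d", seq_along(reads))
  qual <- vapply(nchar(reads), function(n) strrep("I", n), "")
  writeLines(rbind(paste0("@", ids), as.character(reads), "+", qual), path)
  invisible(path)
}

#' @rdname writeReadsFastq
#' @export
readReadsFastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L)
    stop(sprintf("truncated FASTQ %s: record %d is incomplete", path,
                 length(lines) %/% 4L + 1L))
  if (length(lines) == 0L) return(stats::setNames(character(0), character(0)))
  heads <- lines[seq(1L, length(lines), by = 4L)]
  plus <- lines[seq(3L, length(lines), by = 4L)]
  bad <- which(!startsWith(heads, "@") | !startsWith(plus, "+"))
  if (length(bad))
    stop(sprintf("malformed FASTQ %s: record %d (line %d)", path, bad[1],
                 (bad[1] - 1L) * 4L + 1L))
  stats::setNames(toupper(lines[seq(2L, length(lines), by = 4L)]),
                  sub("^@", "", heads))
}

#' Consensus library FASTA I/O
#'
#' Header convention: \code{name|family|age_class}.
#'
#' @param lib a \linkS4class{ConsensusLibrary}.
#' @param path file path.
#' @return \code{readConsensusLibrary}: a \code{ConsensusLibrary}.
#' @export
writeConsensusLibrary <- function(lib, path) {
  out <- lib@seqs
  names(out) <- paste(names(lib), lib@family, ifelse(is.na(lib@ageClass),
                                                     "NA", lib@ageClass),
                      sep = "|")
  Biostrings::writeXStringSet(out, path)
  invisible(path)
}

#' @rdname writeConsensusLibrary
#' @export
readConsensusLibrary <- function(path) {
  s <- readGenomeFasta(path)
  parts <- strsplit(names(s), "|", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad))
    stop(sprintf("malformed library header at record %d: %s", bad[1],
                 names(s)[bad[1]]))
  nm <- vapply(parts, `[[`, "", 1L)
  fam <- stats::setNames(vapply(parts, `[[`, "", 2L), nm)
  age <- vapply(parts, `[[`, "", 3L)
  age[age == "NA"] <- NA
  names(s) <- nm
  new("ConsensusLibrary", seqs = s, family = fam,
      ageClass = stats::setNames(age, nm),
      rRNANames = intersect(nm, c(.RRNA_5P8S_NAME, .RRNA_5S_NAME)))
}

.read_tsv_schema <- function(path, cols, types) {
  d <- tryCatch(utils::read.delim(path, header = TRUE,
                                  stringsAsFactors = FALSE),
                error = function(e) stop("cannot read ", path, ": ",
                                         conditionMessage(e)))
  miss <- setdiff(cols, names(d))
  if (length(miss))
    stop(path, ": missing columns ", paste(miss, collapse = ", "))
  for (i in seq_along(cols)) {
    if (types[i] == "integer") {
      v <- suppressWarnings(as.integer(d[[cols[i]]]))
      bad <- which(is.na(v) & !is.na(d[[cols[i]]]))
      if (length(bad))
        stop(sprintf("%s: non-integer value in column %s at line %d",
                     path, cols[i], bad[1] + 1L))
      d[[cols[i]]] <- v
    }
  }
  d
}

#' CpG call table I/O (bismark coverage-style schema)
#'
#' Tab-separated with header: contig, pos0 (0-based site position),
#' methylated, total.
#'
#' @param calls data.frame with those columns.
#' @param path file path.
#' @return \code{readCpgCalls}: the validated data.frame.
#' @export
writeCpgCalls <- function(calls, path) {
  utils::write.table(calls[, c("contig", "pos0", "methylated", "total")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCpgCalls
#' @export
readCpgCalls <- function(path) {
  d <- .read_tsv_schema(path, c("contig", "pos0", "methylated", "total"),
                        c("character", "integer", "integer", "integer"))
  bad <- which(d$methylated > d$total | d$methylated < 0)
  if (length(bad))
    stop(sprintf("%s: methylated > total at line %d", path, bad[1] + 1L))
  d
}

#' SNP allele-count table I/O
#'
#' Tab-separated with header: contig, pos0, countA, countB, region_label.
#'
#' @param counts data.frame with those columns.
#' @param path file path.
#' @return \code{readSnpCounts}: the validated data.frame.
#' @export
writeSnpCounts <- function(counts, path) {
  utils::write.table(counts[, c("contig", "pos0", "countA", "countB",
                                "region_label")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCpgCalls
#' @export
readSnpCounts <- function(path) {
  .read_tsv_schema(path, c("contig", "pos0", "countA", "countB",
                           "region_label"),
                   c("character", "integer", "integer", "integer",
                     "character"))
}

#' BED interval I/O (0-based half-open on disk)
#'
#' Writes BED6 (name, score, strand defaulted when absent) and reads
#' BED3/BED6 and narrowPeak (10th column = summit offset from start,
#' stored as 0-based absolute \code{summit0}).
#'
#' @param gr 1-based \code{GRanges}.
#' @param path file path.
#' @param narrowPeak logical: read/write the BED6+4 narrowPeak dialect.
#' @return \code{readBed}: a \code{GRanges}.
#' @export
writeBed <- function(gr, path, narrowPeak = FALSE) {
  nm <- if (!is.null(gr$name)) gr$name else
    if (!is.null(names(gr))) names(gr) else rep(".", length(gr))
  score <- if (!is.null(gr$score)) gr$score else rep(0, length(gr))
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  d <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                  start = GenomicRanges::start(gr) - 1L,
                  end = GenomicRanges::end(gr), name = nm, score = score,
                  strand = strand)
  if (narrowPeak) {
    summit <- if (!is.null(gr$summit0)) gr$summit0 - d$start else
      floor((d$end - d$start) / 2)
    d <- cbind(d, signalValue = 0, pValue = -1, qValue = -1, peak = summit)
  }
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname writeBed
#' @export
readBed <- function(path, narrowPeak = FALSE) {
  d <- tryCatch(utils::read.delim(path, header = FALSE,
                                  stringsAsFactors = FALSE),
                error = function(e) stop("cannot read ", path, ": ",
                                         conditionMessage(e)))
  if (ncol(d) < 3L) stop(path, ": BED needs at least 3 columns")
  bad <- which(!is.finite(d[[2]]) | !is.finite(d[[3]]) | d[[2]] >= d[[3]])
  if (length(bad))
    stop(sprintf("%s: invalid interval at line %d", path, bad[1]))
  gr <- GenomicRanges::GRanges(d[[1]], IRanges::IRanges(d[[2]] + 1L, d[[3]]),
                               strand = if (ncol(d) >= 6L)
                                 ifelse(d[[6]] %in% c("+", "-"), d[[6]], "*")
                               else "*")
  if (ncol(d) >= 4L) { gr$name <- d[[4]]; names(gr) <- d[[4]] }
  if (ncol(d) >= 5L) gr$score <- d[[5]]
  if (narrowPeak) {
    if (ncol(d) < 10L) stop(path, ": narrowPeak needs 10 columns")
    gr$summit0 <- d[[2]] + d[[10]]
  }
  gr
}

#' Repeat annotation TSV I/O (RepeatMasker-style columns)
#'
#' Columns: contig, start0, end0 (0-based half-open), strand, subfamily,
#' divergence, score.
#'
#' @param gr annotation \code{GRanges} from \code{\link{annotateGenome}}.
#' @param path file path.
#' @return \code{readAnnotationTsv}: a \code{GRanges}.
#' @export
writeAnnotationTsv <- function(gr, path) {
  d <- data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
                  start0 = GenomicRanges::start(gr) - 1L,
                  end0 = GenomicRanges::end(gr),
                  strand = as.character(GenomicRanges::strand(gr)),
                  subfamily = gr$subfamily, divergence = gr$divergence,
                  score = gr$score)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeAnnotationTsv
#' @export
readAnnotationTsv <- function(path) {
  d <- .read_tsv_schema(path, c("contig", "start0", "end0", "strand",
                                "subfamily", "divergence", "score"),
                        c("character", "integer", "integer", "character",
                          "character", "numeric", "numeric"))
  gr <- GenomicRanges::GRanges(d$contig,
                               IRanges::IRanges(d$start0 + 1L, d$end0),
                               strand = d$strand)
  gr$subfamily <- d$subfamily
  gr$divergence <- d$divergence
  gr$score <- d$score
  gr
}

#' Newick tree I/O
#'
#' @param tree an ape \code{phylo}.
#' @param path file path.
#' @return \code{readNewick}: a \code{phylo}.
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(tree, path)
  invisible(path)
}

#' @rdname writeNewick
#' @export
readNewick <- function(path) ape::read.tree(path)
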