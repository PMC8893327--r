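#' @import methods
#' @importFrom stats median quantile rbinom rnorm runif sd setNames pnorm
#' @importFrom utils head write.table read.table
NULL

# ceiling at the d-th significant digit; used for depth-matching fractions
.sigCeiling <- function(x, digits = 4L) {
  stopifnot(is.numeric(x), x > 0)
  scale <- 10^(digits - 1L - floor(log10(x)))
  ceiling(x * scale - 1e-9) / scale
}

.randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# sample k non-overlapping intervals of width w in [0, len), avoiding 'avoid'
# (IRanges); returns sorted IRanges, errors if placement fails
.placeIntervals <- function(k, w, len, avoid = NULL, maxTries = 50L) {
  taken <- if (is.null(avoid)) IRanges::IRanges() else avoid
  out <- IRanges::IRanges()
  for (i in seq_len(k)) {
    placed <- FALSE
    for (t in seq_len(maxTries)) {
      s <- sample.int(len - w, 1L)  # 1-based start
      cand <- IRanges::IRanges(start = s, width = w)
      if (length(IRanges::findOverlaps(cand, taken)) == 0L) {
        taken <- c(taken, cand)
        out <- c(out, cand)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place ", k, " non-overlapping intervals of width ", w,
           " in a sequence of length ", len)
  }
  out[order(IRanges::start(out))]
}

# truncated-normal fragment lengths, lower bound = readLength
.fragLengths <- function(n, mean, sdev, minLen) {
  fl <- round(rnorm(n, mean, sdev))
  pmax(fl, minLen)
}

#' Write a pair of FASTQ files
#'
#' Reads are written with a constant quality string; read order and names are
#' preserved so fixed-seed simulations are byte-identical across runs.
#'
#' @param pair a [ReadPairSet-class]
#' @param prefix file prefix; `<prefix>_1.fastq` and `<prefix>_2.fastq` are
#'   written
#' @return invisibly, the two file paths
#' @export
writeFastqPair <- function(pair, prefix) {
  f1 <- paste0(prefix, "_1.fastq")
  f2 <- paste0(prefix, "_2.fastq")
  .writeFastq(firstReads(pair), f1)
  .writeFastq(secondReads(pair), f2)
  invisible(c(f1, f2))
}

.writeFastq <- function(reads, path) {
  q <- Biostrings::PhredQuality(
    vapply(Biostrings::width(reads), function(w) strrep("I", w), character(1)))
  Biostrings::writeXStringSet(reads, path, format = "fastq", qualities = q)
}

#' Read a pair of FASTQ files into a ReadPairSet
#'
#' @param file1,file2 FASTQ paths for first and second mates
#' @return a [ReadPairSet-class] (without a truth table)
#' @export
readFastqPair <- function(file1, file2) {
  r1 <- Biostrings::readDNAStringSet(file1, format = "fastq")
  r2 <- Biostrings::readDNAStringSet(file2, format = "fastq")
  ReadPairSet(r1, r2)
}
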