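#' Depth-matching fraction, rounded up at the 4th significant digit
#'
#' Computes `mappedLow / mappedDeep` and rounds it up (ceiling) at the
#' fourth significant digit, the convention used when downsampling a deeper
#' library to its shallower cognate: e.g. 0.572135 becomes 0.5722. Nearest
#' rounding is available via `roundUp = FALSE`.
#'
#' @param mappedLow,mappedDeep mapped read counts; `mappedLow <= mappedDeep`
#' @param roundUp ceiling (default) versus nearest rounding
#' @return the fraction with exactly 4 significant digits
#' @export
downsampleFraction <- function(mappedLow, mappedDeep, roundUp = TRUE) {
  if (mappedLow > mappedDeep)
    stop("mappedLow must not exceed mappedDeep")
  r <- mappedLow / mappedDeep
  if (roundUp) .sigCeiling(r, 4L) else signif(r, 4L)
}

#' Randomly keep a fraction of read pairs (pair-atomic, seeded)
#'
#' Each pair is kept independently with probability `fraction`; both mates
#' are kept or dropped together, so no orphan mates are produced. Fixed
#' seeds reproduce the identical kept set.
#'
#' @param pair a [ReadPairSet-class]
#' @param fraction keep probability in (0, 1]
#' @param seed RNG seed
#' @return the downsampled [ReadPairSet-class]
#' @export
downsamplePairs <- function(pair, fraction, seed = 1L) {
  stopifnot(fraction > 0, fraction <= 1)
  if (fraction == 1) return(pair)
  set.seed(seed)
  keep <- runif(length(pair)) < fraction
  tr <- truthTable(pair)
  ReadPairSet(firstReads(pair)[keep], secondReads(pair)[keep],
              if (nrow(tr)) tr[keep, , drop = FALSE] else tr)
}

#' Downsample a deeper library to the mapped depth of a shallower one
#'
#' Thin composition of [downsampleFraction] and [downsamplePairs]: the
#' fraction is computed from mapped-read counts (round-up at 4 significant
#' digits) and applied pair-atomically on the FASTQ-level pairs.
#'
#' @param pair the deeper library's [ReadPairSet-class]
#' @param mappedLow,mappedDeep mapped read counts of the two libraries
#' @param seed RNG seed
#' @return list with `pair` (downsampled set), `fraction` and `seed`
#' @export
downsampleToDepth <- function(pair, mappedLow, mappedDeep, seed = 1L) {
  f <- downsampleFraction(mappedLow, mappedDeep)
  list(pair = downsamplePairs(pair, f, seed), fraction = f, seed = seed)
}
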